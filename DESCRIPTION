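Package: cytorec
Title: Protein Feature Extraction and SVM Evaluation for Cytokine
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts four families of numeric features from protein
    sequences and their auxiliary profiles: weighted n-gram composition
    (420-D), type-I pseudo amino-acid composition (30-D), position-specific
    scoring matrix statistics (20-D column means plus 380-D lagged
    cross-column correlations), and secondary-structure statistics (18-D).
    Provides frozen feature-combination recipes, parsers for multi-record
    FASTA, PSI-BLAST ASCII PSSM and PSI-PRED .ss2 files, a support-vector
    machine evaluation harness (accuracy, sensitivity, specificity,
    F-score, Matthews correlation; stratified k-fold and repeated
    cross-validation; (C, gamma) grid search; ratio-controlled splits),
    and a synthetic-data generator that emits consistent
    sequence/profile/structure fixtures with controllable class
    separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
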
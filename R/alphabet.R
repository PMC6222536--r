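#' Amino-acid alphabets and feature schemas
#'
#' Two fixed residue orderings are used throughout the package:
#'
#' * `AA_ALPHABETICAL` — the 20 standard residues in single-letter
#'   alphabetical order. Used to index n-gram and pseudo amino-acid
#'   composition slots.
#' * `PSSM_RESIDUE_ORDER` — the column order emitted by PSI-BLAST in its
#'   ASCII PSSM files (`A R N D C Q E G H I L K M F P S T W Y V`). Used for
#'   all PSSM-derived features.
#'
#' Features are consumed positionally by the classifier, so any fixed order
#' would do; these two are frozen so that written feature tables are
#' reproducible and self-describing.
#'
#' @format Character vectors of length 20.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_ALPHABETICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabets
#' @export
PSSM_RESIDUE_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

SS_STATES <- c("H", "E", "C")   # helix, sheet, coil
SS2_PROB_ORDER <- c("C", "H", "E")  # column order in .ss2 files

# ---- feature schema registry -------------------------------------------------
# A schema is a frozen, ordered vector of feature names. Composite schemas are
# concatenations of their parts, mirroring the combination recipes.

schema_ngram420 <- function() {
  mono <- paste0("g1.", AA_ALPHABETICAL)
  di <- as.vector(t(outer(AA_ALPHABETICAL, AA_ALPHABETICAL,
                          function(a, b) paste0("g2.", a, b))))
  c(mono, di)
}

schema_pseaac30 <- function() {
  c(paste0("aac.", AA_ALPHABETICAL), paste0("corr.", seq_len(10)))
}

schema_pssm20 <- function() paste0("pssm20.", PSSM_RESIDUE_ORDER)

schema_pssm380 <- function() {
  out <- character(380)
  k <- 0L
  for (s in seq_len(20)) {
    for (t in seq_len(20)) {
      if (s == t) next
      k <- k + 1L
      out[k] <- paste0("pssm380.", PSSM_RESIDUE_ORDER[s], ".",
                       PSSM_RESIDUE_ORDER[t])
    }
  }
  out
}

schema_sss18 <- function() {
  c("comp.H", "comp.E", "comp.C",
    "pos.H", "pos.E", "pos.C",
    "maxrun.H", "maxrun.E", "maxrun.C",
    "tpm.11", "tpm.12", "tpm.21", "tpm.22", "tpm.col1", "tpm.col2",
    "spm.C", "spm.H", "spm.E")
}

#' Registered feature schemas
#'
#' Returns the frozen, ordered feature names for a registered schema, or the
#' names of all registered schemas.
#'
#' Primitive schemas: `ngram420` (420), `pseaac30` (30), `pssm20` (20),
#' `pssm380` (380), `sss18` (18). Composite schemas mirror the combination
#' recipes: `pssm400` = pssm20 + pssm380, `sp48` = sss18 + pseaac30,
#' `psp448` = pssm400 + sp48, `pspn868` = ngram420 + psp448.
#'
#' @param name Schema name, e.g. `"psp448"`.
#' @return `feature_schema()`: character vector of feature names;
#'   `schema_registry()`: character vector of registered schema names.
#' @export
#' @examples
#' length(feature_schema("psp448"))  # 448
feature_schema <- function(name) {
  switch(name,
    ngram420 = schema_ngram420(),
    pseaac30 = schema_pseaac30(),
    pssm20   = schema_pssm20(),
    pssm380  = schema_pssm380(),
    pssm400  = c(schema_pssm20(), schema_pssm380()),
    sss18    = schema_sss18(),
    sp48     = c(schema_sss18(), schema_pseaac30()),
    psp448   = c(feature_schema("pssm400"), feature_schema("sp48")),
    pspn868  = c(schema_ngram420(), feature_schema("psp448")),
    abort_schema(sprintf("unknown feature schema '%s'", name))
  )
}

#' @rdname feature_schema
#' @export
schema_registry <- function() {
  c("ngram420", "pseaac30", "pssm20", "pssm380", "pssm400",
    "sss18", "sp48", "psp448", "pspn868")
}
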
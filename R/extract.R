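# High-level extraction: from sequences + auxiliary inputs to a combined
# feature matrix. Used by the CLI and the pipeline-level tests.

FEATURE_CHOICES <- c("ngram", "pseaac", "pssm20", "pssm380", "pssm", "sss",
                     "sp", "psp", "pspn")

# which primitive families does a feature/recipe name need?
needed_families <- function(features) {
  switch(features,
    ngram = "ngram", pseaac = "pseaac",
    pssm20 = "pssm", pssm380 = "pssm", pssm = "pssm",
    sss = "sss",
    sp = c("sss", "pseaac"),
    psp = c("pssm", "sss", "pseaac"),
    pspn = c("ngram", "pssm", "sss", "pseaac"),
    abort_validation(sprintf("unknown feature set '%s'", features))
  )
}

#' Extract a (combined) feature matrix from in-memory inputs
#'
#' Computes the requested feature family or combination recipe for a set of
#' sequences with matched profiles and structure predictions. Only the
#' inputs a recipe actually needs must be supplied.
#'
#' @param seqs Named character vector of residue strings.
#' @param features One of `"ngram"`, `"pseaac"`, `"pssm20"`, `"pssm380"`,
#'   `"pssm"`, `"sss"`, `"sp"`, `"psp"`, `"pspn"`.
#' @param profiles Named list of `pssm_profile`s (ids matching `seqs`).
#' @param predictions Named list of `structure_prediction`s.
#' @param labels Optional named +1/-1 vector.
#' @param lam,w PseAAC parameters.
#' @return A `feature_matrix` with the corresponding registered schema.
#' @export
extract_features <- function(seqs, features = "psp", profiles = NULL,
                             predictions = NULL, labels = NULL,
                             lam = 10L, w = 0.05) {
  features <- match.arg(features, FEATURE_CHOICES)
  fams <- needed_families(features)
  ids <- names(seqs)
  if (!is.null(labels)) labels <- as.integer(labels[ids])
  if ("pssm" %in% fams) {
    if (is.null(profiles)) abort_validation("this feature set needs profiles")
    missing <- setdiff(ids, names(profiles))
    if (length(missing)) {
      abort_validation(sprintf("no profile for sequence '%s'", missing[1L]))
    }
    profiles <- profiles[ids]
  }
  if ("sss" %in% fams) {
    if (is.null(predictions)) {
      abort_validation("this feature set needs structure predictions")
    }
    missing <- setdiff(ids, names(predictions))
    if (length(missing)) {
      abort_validation(sprintf("no structure prediction for '%s'", missing[1L]))
    }
    predictions <- predictions[ids]
  }

  parts <- list()
  if ("ngram" %in% fams) parts <- c(parts, list(extract_ngram(seqs, labels)))
  if ("pssm" %in% fams) {
    parts <- c(parts, list(extract_pssm(profiles, labels, "pssm20"),
                           extract_pssm(profiles, labels, "pssm380")))
  }
  if ("sss" %in% fams) parts <- c(parts, list(extract_sss(predictions, labels)))
  if ("pseaac" %in% fams) {
    parts <- c(parts, list(extract_pseaac(seqs, labels, lam = lam, w = w)))
  }

  switch(features,
    ngram = parts[[1L]],
    pseaac = parts[[length(parts)]],
    pssm20 = parts[[1L]],
    pssm380 = parts[[2L]],
    pssm = combine_features(parts, "pssm"),
    sss = parts[[1L]],
    sp = combine_features(parts, "sp"),
    psp = combine_features(parts, "psp"),
    pspn = combine_features(parts, "pspn"))
}

#' Load a dataset directory and extract features
#'
#' Reads a directory in the layout written by [gen_dataset()] (or assembled
#' by hand from real PSI-BLAST / PSI-PRED output): a FASTA file, an
#' optional `labels.tsv`, and per-sequence auxiliary files located by the
#' `<id>.pssm` / `<id>.ss2` naming convention. Sequences whose required
#' auxiliary file is missing are skipped with a warning and counted in the
#' attached summary (attribute `skipped`).
#'
#' @param dir Dataset directory.
#' @param features Feature set / recipe name (see [extract_features()]).
#' @param fasta,pssm_dir,ss2_dir,labels_file Overrides for the default
#'   layout (`sequences.fasta`, `pssm/`, `ss2/`, `labels.tsv`).
#' @param lam,w PseAAC parameters.
#' @return A `feature_matrix`; skipped ids in `attr(, "skipped")`.
#' @export
dataset_features <- function(dir, features = "psp",
                             fasta = file.path(dir, "sequences.fasta"),
                             pssm_dir = file.path(dir, "pssm"),
                             ss2_dir = file.path(dir, "ss2"),
                             labels_file = file.path(dir, "labels.tsv"),
                             lam = 10L, w = 0.05) {
  features <- match.arg(features, FEATURE_CHOICES)
  seqs <- read_fasta(fasta)
  fams <- needed_families(features)

  labels <- NULL
  if (!is.null(labels_file) && file.exists(labels_file)) {
    tab <- utils::read.delim(labels_file, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.integer(tab$label), tab$id)
  }

  skipped <- character(0)
  profiles <- NULL
  predictions <- NULL
  if ("pssm" %in% fams) {
    paths <- file.path(pssm_dir, paste0(names(seqs), ".pssm"))
    ok <- file.exists(paths)
    skipped <- union(skipped, names(seqs)[!ok])
  }
  if ("sss" %in% fams) {
    paths <- file.path(ss2_dir, paste0(names(seqs), ".ss2"))
    ok <- file.exists(paths)
    skipped <- union(skipped, names(seqs)[!ok])
  }
  if (length(skipped)) {
    warning(sprintf("skipping %d sequence(s) with missing auxiliary files: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5L), collapse = ", ")))
    seqs <- seqs[setdiff(names(seqs), skipped)]
    if (length(seqs) == 0L) abort_validation("no sequences left after skipping")
  }
  if ("pssm" %in% fams) {
    profiles <- lapply(names(seqs), function(id) {
      parse_pssm(file.path(pssm_dir, paste0(id, ".pssm")), sequence_id = id)
    })
    names(profiles) <- names(seqs)
  }
  if ("sss" %in% fams) {
    predictions <- lapply(names(seqs), function(id) {
      parse_ss2(file.path(ss2_dir, paste0(id, ".ss2")), sequence_id = id)
    })
    names(predictions) <- names(seqs)
  }

  fm <- extract_features(seqs, features, profiles = profiles,
                         predictions = predictions, labels = labels,
                         lam = lam, w = w)
  attr(fm, "skipped") <- skipped
  fm
}
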
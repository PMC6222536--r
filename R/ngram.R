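#' Weighted n-gram composition features (420-D)
#'
#' Counts the single residues (1-grams) and the overlapping adjacent residue
#' pairs (2-grams) of a protein sequence. Each count is normalised by its
#' number of windows (L for monomers, L - 1 for dimers) and multiplied by the
#' per-order weight 20^n / (20 + 20^2), i.e. 20/420 for the monomer block and
#' 400/420 for the dimer block, so that the 420 values sum to exactly 1.
#'
#' Slot order: the 20 monomers in alphabetical order, then the 400 dimers in
#' row-major (first residue, second residue) order.
#'
#' @param seq Residue string (validated against the standard alphabet).
#' @param id Sequence id used in error messages.
#' @return Named numeric vector of length 420 (schema `ngram420`).
#' @export
#' @examples
#' v <- ngram_features(strrep("A", 21))
#' v[["g1.A"]]   # 1/21
#' v[["g2.AA"]]  # 20/21
ngram_features <- function(seq, id = "<unnamed>") {
  seq <- validate_residues(seq, id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) {
    abort_length(sprintf(
      "sequence '%s': length %d < 2; dimer block undefined", id, L))
  }
  w1 <- 20 / 420
  w2 <- 400 / 420

  mono <- table(factor(chars, levels = AA_ALPHABETICAL))
  mono <- w1 * as.vector(mono) / L

  dimers <- paste0(chars[-L], chars[-1L])
  dimer_levels <- as.vector(t(outer(AA_ALPHABETICAL, AA_ALPHABETICAL, paste0)))
  di <- table(factor(dimers, levels = dimer_levels))
  di <- w2 * as.vector(di) / (L - 1L)

  stats::setNames(c(mono, di), schema_ngram420())
}

#' Extract n-gram features for many sequences
#'
#' @param seqs Named character vector of residue strings.
#' @param labels Optional labels (+1/-1) aligned with `seqs`.
#' @return `feature_matrix` with schema `ngram420`.
#' @export
extract_ngram <- function(seqs, labels = NULL) {
  values <- t(vapply(seq_along(seqs),
                     function(i) ngram_features(seqs[[i]], names(seqs)[i]),
                     numeric(420)))
  feature_matrix(values, ids = names(seqs), labels = labels,
                 schema = "ngram420")
}
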
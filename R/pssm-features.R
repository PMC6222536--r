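#' Sigmoid-normalise a PSSM profile
#'
#' Squashes the raw log-odds scores elementwise with the logistic function
#' 1/(1 + exp(-a)), mapping every entry into (0, 1), and records the column
#' means and population standard deviations (divisor L) that the correlation
#' features reuse.
#'
#' @param profile A `pssm_profile`.
#' @return A `normalized_profile`: list with `A` (L x 20 matrix in (0,1)),
#'   `column_means`, `column_sds`, `sequence_id`, `column_order`.
#' @export
sigmoid_normalize <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  A <- 1 / (1 + exp(-profile$scores))
  structure(list(
    sequence_id = profile$sequence_id,
    A = A,
    column_means = colMeans(A),
    column_sds = apply(A, 2L, pop_sd),
    column_order = profile$column_order
  ), class = "normalized_profile")
}

as_normalized_profile <- function(x) {
  if (inherits(x, "normalized_profile")) return(x)
  if (inherits(x, "pssm_profile")) return(sigmoid_normalize(x))
  abort_validation("expected a pssm_profile or normalized_profile")
}

#' PSSM column-mean features (20-D)
#'
#' The mean of each sigmoid-normalised PSSM column: a per-residue summary of
#' the evolutionary profile, ignoring position order.
#'
#' @param profile A `pssm_profile` or `normalized_profile`.
#' @return Named numeric vector of length 20 (schema `pssm20`), values in
#'   (0, 1).
#' @export
pssm20 <- function(profile) {
  np <- as_normalized_profile(profile)
  stats::setNames(as.vector(np$column_means), schema_pssm20())
}

#' PSSM cross-column correlation features (380-D)
#'
#' For every ordered residue-column pair (s, t) with s != t and lag
#' g = |s - t|, the average over positions i = 1..L-g of the standardised
#' product (A\[i,s\] - F_s)(A\[i+g,t\] - F_t) / (sd_s * sd_t), where F and sd
#' are the column means and population standard deviations of the
#' sigmoid-normalised profile. At s = t (g = 0) the same expression is
#' identically 1 for any non-degenerate column — those 20 uninformative
#' diagonal values are dropped, leaving 380 features in lexicographic
#' (s, t) order over the PSI-BLAST residue order.
#'
#' @param profile A `pssm_profile` or `normalized_profile` with L >= 20 rows.
#' @return Named numeric vector of length 380 (schema `pssm380`).
#' @export
pssm380 <- function(profile) {
  np <- as_normalized_profile(profile)
  L <- nrow(np$A)
  if (L < 20L) {
    abort_length(sprintf(
      "profile '%s': %d rows < 20; lag L - g would vanish", np$sequence_id, L))
  }
  zero_sd <- which(np$column_sds == 0)
  if (length(zero_sd) > 0L) {
    abort_degenerate(sprintf(
      "profile '%s': column '%s' is constant (sd = 0)",
      np$sequence_id, np$column_order[zero_sd[1L]]))
  }
  C <- sweep(np$A, 2L, np$column_means)   # centred columns
  out <- numeric(380)
  k <- 0L
  for (s in seq_len(20L)) {
    for (t in seq_len(20L)) {
      if (s == t) next
      k <- k + 1L
      g <- abs(s - t)
      i <- seq_len(L - g)
      out[k] <- mean(C[i, s] * C[i + g, t]) /
        (np$column_sds[s] * np$column_sds[t])
    }
  }
  stats::setNames(out, schema_pssm380())
}

#' Combined PSSM features (400-D)
#'
#' Concatenation of [pssm20()] and [pssm380()] in schema order.
#'
#' @inheritParams pssm380
#' @return Named numeric vector of length 400 (schema `pssm400`).
#' @export
pssm_features <- function(profile) {
  np <- as_normalized_profile(profile)
  c(pssm20(np), pssm380(np))
}

#' Extract PSSM features for many profiles
#'
#' @param profiles List of `pssm_profile` objects (named by sequence id, or
#'   ids are taken from the profiles).
#' @param labels Optional labels (+1/-1) aligned with `profiles`.
#' @param which One of `"pssm20"`, `"pssm380"`, `"pssm400"`.
#' @return `feature_matrix` with the requested schema.
#' @export
extract_pssm <- function(profiles, labels = NULL, which = "pssm400") {
  which <- match.arg(which, c("pssm20", "pssm380", "pssm400"))
  fun <- switch(which, pssm20 = pssm20, pssm380 = pssm380,
                pssm400 = pssm_features)
  d <- switch(which, pssm20 = 20L, pssm380 = 380L, pssm400 = 400L)
  ids <- names(profiles) %||%
    vapply(profiles, function(p) p$sequence_id, character(1))
  values <- t(vapply(profiles, fun, numeric(d)))
  feature_matrix(values, ids = ids, labels = labels, schema = which)
}
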
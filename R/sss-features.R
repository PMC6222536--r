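# Secondary-structure features: 18 values per prediction, assembled from
# state composition, positional sums, maximal run lengths, the alpha/beta
# transition probability matrix and the structure-probability column means.

as_ss_states <- function(sp) {
  if (inherits(sp, "structure_prediction")) return(sp$states)
  if (is.character(sp) && length(sp) == 1L) {
    chars <- strsplit(sp, "", fixed = TRUE)[[1L]]
    bad <- !(chars %in% SS_STATES)
    if (length(chars) == 0L || any(bad)) {
      abort_validation("state string must be non-empty over {H,E,C}")
    }
    return(sp)
  }
  abort_validation("expected a structure_prediction or an H/E/C string")
}

#' Secondary-structure state composition (3 features)
#'
#' Frequencies of H, E and C in the state string; the triple sums to 1.
#'
#' @param sp A `structure_prediction` or an H/E/C state string.
#' @return Numeric vector (H, E, C).
#' @export
composition_features <- function(sp) {
  chars <- strsplit(as_ss_states(sp), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = SS_STATES))
  stats::setNames(as.vector(counts) / length(chars),
                  c("comp.H", "comp.E", "comp.C"))
}

#' Secondary-structure positional features (3 features)
#'
#' For each state, the sum of the 1-based positions at which it occurs,
#' divided by L(L - 1). States concentrated toward the C-terminus score
#' higher; an absent state scores 0.
#'
#' @inheritParams composition_features
#' @return Numeric vector (H, E, C).
#' @export
positional_features <- function(sp) {
  chars <- strsplit(as_ss_states(sp), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) abort_length("positional features need length >= 2")
  vals <- vapply(SS_STATES, function(s) sum(which(chars == s)), numeric(1))
  stats::setNames(vals / (L * (L - 1)), c("pos.H", "pos.E", "pos.C"))
}

#' Longest run of one state
#'
#' Length (in residues) of the longest contiguous block of `state` in the
#' state string; 0 when the state is absent.
#'
#' @inheritParams composition_features
#' @param state One of `"H"`, `"E"`, `"C"`.
#' @return Integer run length.
#' @export
#' @examples
#' max_run_length("EEEEHHEEHHHCC", "H")  # 3
max_run_length <- function(sp, state) {
  stopifnot(state %in% SS_STATES)
  chars <- strsplit(as_ss_states(sp), "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  hit <- r$lengths[r$values == state]
  if (length(hit) == 0L) 0L else as.integer(max(hit))
}

#' Maximal-run features (3 features)
#'
#' Longest contiguous run of each state divided by L, order (H, E, C).
#'
#' @inheritParams composition_features
#' @return Numeric vector (H, E, C).
#' @export
maxrun_features <- function(sp) {
  states <- as_ss_states(sp)
  L <- nchar(states)
  vals <- vapply(SS_STATES, function(s) max_run_length(states, s), integer(1))
  stats::setNames(vals / L, c("maxrun.H", "maxrun.E", "maxrun.C"))
}

#' Helix/sheet segment transition probability matrix
#'
#' Coil positions are removed, maximal H runs collapse to a single alpha
#' token and maximal E runs to a single beta token, giving the segment
#' sequence S0. Adjacent token pairs are counted and the 2 x 2 TPM filled
#' with rows (alpha, beta): row 1 shares denominator T(aa) + T(ab), row 2
#' shares denominator T(bb) + T(ba). A row whose denominator is 0 (fewer
#' than one transition out of that token) is zero-filled, keeping degenerate
#' predictions (no H, no E, or a single segment) total.
#'
#' @inheritParams composition_features
#' @return A `transition_matrix`: list with `tpm` (2 x 2) and `counts`
#'   (named: aa, ab, ba, bb).
#' @export
#' @examples
#' transition_matrix("EEEEHHEEHHHCC")$tpm  # rows (0 1) / (1 0)
transition_matrix <- function(sp) {
  chars <- strsplit(as_ss_states(sp), "", fixed = TRUE)[[1L]]
  chars <- chars[chars != "C"]
  counts <- c(aa = 0, ab = 0, ba = 0, bb = 0)
  if (length(chars) > 0L) {
    tokens <- rle(chars)$values          # "H" -> alpha, "E" -> beta
    if (length(tokens) > 1L) {
      pairs <- paste0(tokens[-length(tokens)], tokens[-1L])
      counts["aa"] <- sum(pairs == "HH")  # cannot occur after rle; kept for clarity
      counts["ab"] <- sum(pairs == "HE")
      counts["ba"] <- sum(pairs == "EH")
      counts["bb"] <- sum(pairs == "EE")
    }
  }
  tpm <- matrix(0, 2L, 2L, dimnames = list(c("alpha", "beta"),
                                           c("alpha", "beta")))
  d1 <- counts["aa"] + counts["ab"]
  if (d1 > 0) tpm[1L, ] <- c(counts["aa"], counts["ab"]) / d1
  d2 <- counts["bb"] + counts["ba"]
  if (d2 > 0) tpm[2L, ] <- c(counts["ba"], counts["bb"]) / d2
  structure(list(tpm = tpm, counts = counts), class = "transition_matrix")
}

#' Transition-matrix features (6 features)
#'
#' The four TPM entries in row-major order followed by the two column
#' averages (TPM(1,1) + TPM(2,1))/2 and (TPM(1,2) + TPM(2,2))/2.
#'
#' @param tpm A `transition_matrix` (or a `structure_prediction`/state
#'   string, converted internally).
#' @return Numeric vector of length 6.
#' @export
tpm_features <- function(tpm) {
  if (!inherits(tpm, "transition_matrix")) tpm <- transition_matrix(tpm)
  m <- tpm$tpm
  stats::setNames(
    c(m[1, 1], m[1, 2], m[2, 1], m[2, 2],
      (m[1, 1] + m[2, 1]) / 2, (m[1, 2] + m[2, 2]) / 2),
    c("tpm.11", "tpm.12", "tpm.21", "tpm.22", "tpm.col1", "tpm.col2"))
}

#' Structure-probability-matrix features (3 features)
#'
#' Column means of the L x 3 per-residue probability matrix, in the .ss2
#' column order (C, H, E). Sums to 1 up to the parsed-file tolerance.
#'
#' @param sp A `structure_prediction`.
#' @return Numeric vector (C, H, E).
#' @export
spm_features <- function(sp) {
  stopifnot(inherits(sp, "structure_prediction"))
  stats::setNames(colMeans(sp$probabilities), c("spm.C", "spm.H", "spm.E"))
}

#' Secondary-structure feature vector (18-D)
#'
#' Concatenates, in frozen schema order: composition (3), positional (3),
#' maximal-run (3), transition-matrix (6) and probability-matrix (3)
#' features.
#'
#' @param sp A `structure_prediction` of length >= 2.
#' @return Named numeric vector of length 18 (schema `sss18`).
#' @export
sss_features <- function(sp) {
  stopifnot(inherits(sp, "structure_prediction"))
  out <- c(composition_features(sp), positional_features(sp),
           maxrun_features(sp), tpm_features(sp), spm_features(sp))
  stats::setNames(out, schema_sss18())
}

#' Extract secondary-structure features for many predictions
#'
#' @param preds List of `structure_prediction` objects (named by sequence
#'   id, or ids are taken from the predictions).
#' @param labels Optional labels (+1/-1) aligned with `preds`.
#' @return `feature_matrix` with schema `sss18`.
#' @export
extract_sss <- function(preds, labels = NULL) {
  ids <- names(preds) %||%
    vapply(preds, function(p) p$sequence_id, character(1))
  values <- t(vapply(preds, sss_features, numeric(18)))
  feature_matrix(values, ids = ids, labels = labels, schema = "sss18")
}
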
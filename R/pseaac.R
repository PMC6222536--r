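#' Physicochemical property table for pseudo amino-acid composition
#'
#' Per-residue hydrophilicity (Hopp-Woods scale), hydrophobicity
#' (Tanford/Chou scale) and side-chain mass for the 20 standard amino acids,
#' the canonical triplet of the type-I pseudo amino-acid composition
#' lineage. Rows are in alphabetical residue order.
#'
#' @return Data frame with columns `residue`, `hydrophilicity`,
#'   `hydrophobicity`, `mass`.
#' @export
pseaac_property_table <- function() {
  data.frame(
    residue = AA_ALPHABETICAL,
    hydrophilicity = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0,
                       -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5,
                       -3.4, -2.3),
    hydrophobicity = c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38,
                       -1.50, 1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18,
                       -0.05, 1.08, 0.81, 0.26),
    mass = c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57, 75, 58, 42, 72, 101,
             31, 45, 43, 130, 107),
    stringsAsFactors = FALSE
  )
}

#' Read a property table from a tab-separated file
#'
#' Expects 20 rows of `residue<TAB>hydrophilicity<TAB>hydrophobicity<TAB>mass`
#' (with a header line), one row per standard amino acid. This is the
#' override point for users who want a different property triplet.
#'
#' @param path Path to the TSV file.
#' @return Data frame in the same layout as [pseaac_property_table()].
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("property table not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophilicity", "hydrophobicity", "mass")
  if (!all(need %in% names(tab))) {
    abort_parse(sprintf("'%s': property table needs columns %s",
                        path, paste(need, collapse = ", ")))
  }
  tab <- tab[match(AA_ALPHABETICAL, tab$residue), need]
  if (anyNA(tab$residue)) {
    abort_validation(sprintf("'%s': property table must cover all 20 residues", path))
  }
  rownames(tab) <- NULL
  tab
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score-normalise a property table
#'
#' Each property column is replaced by (x - mu) / sigma with the population
#' standard deviation over the 20 residues, so that the three scales become
#' dimensionless and comparable before entering the sequence-order
#' correlation factors.
#'
#' @param raw Property table as returned by [pseaac_property_table()].
#' @return The table with normalised property columns (marked with attribute
#'   `normalized`).
#' @export
normalize_properties <- function(raw) {
  tab <- raw
  for (col in c("hydrophilicity", "hydrophobicity", "mass")) {
    x <- as.numeric(tab[[col]])
    if (length(x) != 20L || anyNA(x) || any(!is.finite(x))) {
      abort_validation(sprintf("property '%s': need 20 finite values", col))
    }
    s <- pop_sd(x)
    if (s == 0) {
      abort_degenerate(sprintf("property '%s' is constant (sigma = 0)", col))
    }
    tab[[col]] <- (x - mean(x)) / s
  }
  attr(tab, "normalized") <- TRUE
  tab
}

#' Sequence-order correlation factors
#'
#' For each tier g = 1..lam, the mean over all residue pairs at distance g
#' of the averaged squared differences of the three normalised properties:
#' b_g = (1/(L-g)) * sum_i (1/3) \[ (H1_i - H1_(i+g))^2 + (H2_i - H2_(i+g))^2
#' + (M_i - M_(i+g))^2 \]. Properties are z-scored first (see
#' [normalize_properties()]); every b_g is non-negative.
#'
#' @param seq Residue string.
#' @param table Property table (normalised or raw; raw is normalised here).
#' @param lam Number of correlation tiers; must be < sequence length.
#' @param id Sequence id used in error messages.
#' @return Numeric vector b_1..b_lam.
#' @export
correlation_factors <- function(seq, table = pseaac_property_table(),
                                lam = 10L, id = "<unnamed>") {
  seq <- validate_residues(seq, id)
  if (lam < 1L) abort_validation("lam must be >= 1")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L <= lam) {
    abort_length(sprintf("sequence '%s': length %d must exceed lam = %d",
                         id, L, lam))
  }
  if (!isTRUE(attr(table, "normalized"))) table <- normalize_properties(table)
  props <- as.matrix(table[match(chars, table$residue),
                           c("hydrophilicity", "hydrophobicity", "mass")])
  vapply(seq_len(lam), function(g) {
    d <- props[seq_len(L - g), , drop = FALSE] -
         props[seq.int(g + 1L, L), , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
}

#' Type-I pseudo amino-acid composition (20 + lambda features)
#'
#' The first 20 slots hold the relative residue frequencies f(a) = count/L
#' and the last `lam` slots the weighted correlation factors w * b_g, all
#' divided by the shared denominator sum(f) + w * sum(b), so the vector sums
#' to 1. Defaults lam = 10 and w = 0.05 give the standard 30-D vector.
#'
#' @inheritParams correlation_factors
#' @param w Weight of the sequence-order terms (> 0).
#' @return Named numeric vector of length 20 + lam (schema `pseaac30` when
#'   lam = 10).
#' @export
#' @examples
#' v <- pseaac_features(strrep("A", 21))
#' v[["aac.A"]]  # 1: a homopolymer has zero correlation factors
pseaac_features <- function(seq, table = pseaac_property_table(),
                            lam = 10L, w = 0.05, id = "<unnamed>") {
  if (w <= 0) abort_validation("w must be > 0")
  seq <- validate_residues(seq, id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  f <- as.vector(table(factor(chars, levels = AA_ALPHABETICAL))) / L
  b <- correlation_factors(seq, table, lam = lam, id = id)
  denom <- sum(f) + w * sum(b)
  out <- c(f / denom, w * b / denom)
  names(out) <- c(paste0("aac.", AA_ALPHABETICAL),
                  paste0("corr.", seq_len(lam)))
  out
}

#' Extract pseudo amino-acid composition features for many sequences
#'
#' @param seqs Named character vector of residue strings.
#' @param labels Optional labels (+1/-1) aligned with `seqs`.
#' @inheritParams pseaac_features
#' @return `feature_matrix` with schema `pseaac30` (for the default lam).
#' @export
extract_pseaac <- function(seqs, labels = NULL,
                           table = pseaac_property_table(),
                           lam = 10L, w = 0.05) {
  table <- normalize_properties(table)
  values <- t(vapply(seq_along(seqs),
                     function(i) pseaac_features(seqs[[i]], table, lam, w,
                                                 id = names(seqs)[i]),
                     numeric(20L + lam)))
  feature_matrix(values, ids = names(seqs), labels = labels,
                 schema = if (lam == 10L) "pseaac30" else
                   sprintf("pseaac%d", 20L + lam))
}
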
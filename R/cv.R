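# Cross-validation, repeated cross-validation, grid search and
# ratio-controlled splits.

#' Seeded fold assignment
#'
#' Partitions n labelled items into k folds whose sizes differ by at most 1.
#' With `stratified = TRUE` (the default) each class is shuffled separately
#' and folds are filled by one global round-robin pass, so the class ratio
#' is preserved per fold up to rounding — required to keep folds valid in
#' strongly imbalanced settings such as 1:9.
#'
#' @param labels Integer +1/-1 labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer RNG seed.
#' @param stratified Preserve the class ratio per fold.
#' @return Integer vector of fold ids in 1..k, one per item.
#' @export
cv_folds <- function(labels, k, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k < 2L) abort_validation("k must be >= 2")
  if (k > n) abort_validation(sprintf("k = %d exceeds n = %d", k, n))
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    counts <- table(factor(labels, levels = c(1L, -1L)))
    if (any(counts < k) && any(counts > 0 & counts < k)) {
      small <- names(counts)[counts > 0 & counts < k][1L]
      abort_stratification(sprintf(
        "class %s has %d members, fewer than k = %d folds",
        small, counts[[small]], k))
    }
    ord <- c(sample(which(labels == 1L)), sample(which(labels == -1L)))
  } else {
    ord <- sample(n)
  }
  fold[ord] <- rep_len(seq_len(k), n)
  fold
}

#' k-fold cross-validation of an SVM
#'
#' Randomly partitions the data into k near-equal folds (seeded, stratified
#' by default), trains on k-1 folds and evaluates on the held-out fold, once
#' per fold. The aggregate is the mean of the per-fold metrics (not pooled
#' confusion counts), with the population standard deviation across folds.
#'
#' @param features Labelled `feature_matrix`.
#' @param k Number of folds.
#' @param kernel,C,gamma,scale Passed to [svm_train()].
#' @param seed Fold-assignment seed.
#' @param stratified Preserve class ratio per fold (see [cv_folds()]).
#' @return A `cv_result`: per-fold `evaluation_report`s, `mean` and `sd`
#'   per metric, the fold assignment and the seed.
#' @export
kfold_cv <- function(features, k = 10L, kernel = "linear", C = 1,
                     gamma = NULL, seed = 1L, scale = FALSE,
                     stratified = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels)) abort_validation("cross-validation needs labels")
  fold <- cv_folds(features$labels, k, seed = seed, stratified = stratified)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    model <- svm_train(fm_rows(features, -test_idx), kernel = kernel, C = C,
                       gamma = gamma, scale = scale)
    pred <- predict(model, fm_rows(features, test_idx))
    reports[[f]] <- evaluate_predictions(features$labels[test_idx], pred)
  }
  per_fold <- t(vapply(reports, report_metrics, numeric(6)))
  structure(list(
    folds = reports,
    metrics = per_fold,
    mean = colMeans(per_fold),
    sd = apply(per_fold, 2L, pop_sd),
    fold_assignment = fold,
    k = k, seed = seed, kernel = kernel, C = C, gamma = gamma
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("<cv_result> %d-fold, %s kernel, C=%g (seed %d)\n",
              x$k, x$kernel, x$C, x$seed))
  cat("  mean:", paste(sprintf("%s=%.*f", names(x$mean), digits, x$mean),
                       collapse = " "), "\n")
  cat("  sd:  ", paste(sprintf("%s=%.*f", names(x$sd), digits, x$sd),
                       collapse = " "), "\n")
  invisible(x)
}

#' Repeated k-fold cross-validation
#'
#' Runs [kfold_cv()] `reps` times with independent fold partitions (seeds
#' `base_seed + 1 .. base_seed + reps`). The summary table reports, per
#' repetition, the mean of the fold metrics plus/minus the fold standard
#' deviation; the overall row aggregates the repetition means and their
#' standard deviation across repetitions (both spreads are reported because
#' each answers a different question).
#'
#' @inheritParams kfold_cv
#' @param reps Number of repetitions.
#' @param base_seed Base RNG seed; repetition r uses `base_seed + r`.
#' @return A `repeated_cv_result`: list of `cv_result`s, a per-repetition
#'   summary `table`, `overall_mean` and `between_rep_sd`.
#' @export
repeated_cv <- function(features, k = 10L, reps = 10L, kernel = "linear",
                        C = 1, gamma = NULL, base_seed = 1L, scale = FALSE,
                        stratified = TRUE) {
  results <- lapply(seq_len(reps), function(r) {
    kfold_cv(features, k = k, kernel = kernel, C = C, gamma = gamma,
             seed = base_seed + r, scale = scale, stratified = stratified)
  })
  means <- t(vapply(results, function(x) x$mean, numeric(6)))
  sds <- t(vapply(results, function(x) x$sd, numeric(6)))
  tab <- data.frame(rep = seq_len(reps), means, check.names = FALSE)
  names(tab)[-1L] <- METRIC_NAMES
  for (m in METRIC_NAMES) tab[[paste0(m, "_fold_sd")]] <- sds[, m]
  structure(list(
    results = results, table = tab,
    overall_mean = colMeans(means),
    between_rep_sd = apply(means, 2L, pop_sd),
    k = k, reps = reps, base_seed = base_seed
  ), class = "repeated_cv_result")
}

#' @export
print.repeated_cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("<repeated_cv_result> %d x %d-fold (base seed %d)\n",
              x$reps, x$k, x$base_seed))
  for (m in METRIC_NAMES) {
    cat(sprintf("  %-8s %.*f +/- %.*f (between-rep)\n", m, digits,
                x$overall_mean[m], digits, x$between_rep_sd[m]))
  }
  invisible(x)
}

#' Grid search over (C, gamma)
#'
#' Exhaustive sweep over a lattice of cost and kernel-width values, scoring
#' each cell by inner k-fold cross-validation accuracy with one shared,
#' seeded fold assignment (so cells are compared on identical partitions).
#' The default lattice is the 11 x 11 grid 2^-5 .. 2^5 in both parameters.
#' Ties on the accuracy maximum are broken toward the smaller C, then the
#' smaller gamma.
#'
#' @inheritParams kfold_cv
#' @param C_values,gamma_values Numeric vectors of grid values.
#' @param inner_k Folds of the inner cross-validation (>= 2).
#' @return A `grid_search_result`: accuracy `surface` (C rows x gamma
#'   columns), `best_C`, `best_gamma`, `best_accuracy`.
#' @export
grid_search <- function(features, C_values = 2^(-5:5),
                        gamma_values = 2^(-5:5), inner_k = 3L, seed = 1L,
                        kernel = "gaussian", stratified = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  if (length(C_values) == 0L || length(gamma_values) == 0L) {
    abort_validation("both grid axes must be non-empty")
  }
  if (is.null(features$labels)) abort_validation("grid search needs labels")
  fold <- cv_folds(features$labels, inner_k, seed = seed,
                   stratified = stratified)
  C_values <- sort(C_values)
  gamma_values <- sort(gamma_values)
  surface <- matrix(NA_real_, length(C_values), length(gamma_values),
                    dimnames = list(sprintf("C=%g", C_values),
                                    sprintf("gamma=%g", gamma_values)))
  cell_accuracy <- function(C, gamma) {
    accs <- vapply(seq_len(inner_k), function(f) {
      test_idx <- which(fold == f)
      model <- svm_train(fm_rows(features, -test_idx), kernel = kernel,
                         C = C, gamma = gamma)
      pred <- predict(model, fm_rows(features, test_idx))
      mean(pred == features$labels[test_idx])
    }, numeric(1))
    mean(accs)
  }
  best <- list(acc = -Inf, C = NA_real_, gamma = NA_real_)
  for (i in seq_along(C_values)) {
    for (j in seq_along(gamma_values)) {
      acc <- cell_accuracy(C_values[i], gamma_values[j])
      surface[i, j] <- acc
      if (acc > best$acc) {   # strict: ties keep the smaller (C, gamma)
        best <- list(acc = acc, C = C_values[i], gamma = gamma_values[j])
      }
    }
  }
  structure(list(surface = surface, C_values = C_values,
                 gamma_values = gamma_values, best_C = best$C,
                 best_gamma = best$gamma, best_accuracy = best$acc,
                 inner_k = inner_k, seed = seed, kernel = kernel),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %d x %d cells, inner %d-fold (seed %d)\n",
    length(x$C_values), length(x$gamma_values), x$inner_k, x$seed))
  cat(sprintf("  best: C=%g gamma=%g accuracy=%.4f\n",
              x$best_C, x$best_gamma, x$best_accuracy))
  invisible(x)
}

#' @export
plot.grid_search_result <- function(x, ...) {
  graphics::image(log2(x$C_values), log2(x$gamma_values), x$surface,
                  xlab = "log2 C", ylab = "log2 gamma",
                  main = "Inner-CV accuracy", ...)
  graphics::points(log2(x$best_C), log2(x$best_gamma), pch = 4, cex = 2)
  invisible(x)
}

#' Ratio-controlled train/test split
#'
#' Splits a labelled feature matrix into train and test parts such that both
#' parts have positive fraction `positive_fraction` (within integer
#' rounding) and the test part holds `test_fraction` of all rows. Every row
#' is used, so the dataset's own class totals must already be consistent
#' with the requested ratio; otherwise a composition error is raised.
#'
#' @param features Labelled `feature_matrix`.
#' @param positive_fraction Target fraction of positives in each part (e.g.
#'   0.1 for a 1:9 ratio).
#' @param test_fraction Fraction of all rows assigned to the test part.
#' @param seed RNG seed for the row sampling.
#' @return List with elements `train` and `test` (`feature_matrix`).
#' @export
ratio_split <- function(features, positive_fraction, test_fraction,
                        seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (is.null(features$labels)) abort_validation("ratio_split needs labels")
  if (positive_fraction <= 0 || positive_fraction >= 1 ||
      test_fraction <= 0 || test_fraction >= 1) {
    abort_validation("fractions must lie strictly between 0 and 1")
  }
  n <- length(features$labels)
  n_pos <- sum(features$labels == 1L)
  if (round(positive_fraction * n) != n_pos) {
    abort_composition(sprintf(
      "infeasible ratio: %d positives among %d rows cannot realise positive fraction %g",
      n_pos, n, positive_fraction))
  }
  n_test <- round(test_fraction * n)
  test_pos <- round(positive_fraction * n_test)
  test_neg <- n_test - test_pos
  if (test_pos < 1L || test_neg < 1L || test_pos > n_pos ||
      test_neg > n - n_pos) {
    abort_composition("requested split leaves an empty class in the test part")
  }
  set.seed(seed)
  pos_idx <- sample(which(features$labels == 1L))
  neg_idx <- sample(which(features$labels == -1L))
  test_idx <- sort(c(pos_idx[seq_len(test_pos)], neg_idx[seq_len(test_neg)]))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = fm_rows(features, train_idx),
       test = fm_rows(features, test_idx))
}
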
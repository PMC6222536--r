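# SVM contract, cross-validation, grid search and ratio splits on small
# synthetic feature matrices.

clusters_fm <- function(n = 60, sep = 6, d = 5, seed = 79) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(matrix(rnorm(half * d), half, d),
             matrix(rnorm(half * d, mean = sep), half, d))
  feature_matrix(x, ids = sprintf("s%03d", seq_len(n)),
                 labels = rep(c(1L, -1L), each = half), schema = "toy")
}

test_that("well-separated clusters are fit perfectly by a linear SVM", {
  fm <- clusters_fm()
  model <- svm_train(fm, "linear", C = 1)
  expect_equal(unname(predict(model, fm)), fm$labels)
})

test_that("training contract: labels, both classes, gamma for gaussian", {
  fm <- clusters_fm()
  unlab <- feature_matrix(fm$values, ids = fm$ids, schema = "toy")
  expect_error(svm_train(unlab, "linear"), class = "cytorec_training_error")
  onecls <- fm_subset_test(fm, which(fm$labels == 1L))
  expect_error(svm_train(onecls, "linear"), class = "cytorec_training_error")
  expect_error(svm_train(fm, "gaussian"), class = "cytorec_validation_error")
  model <- svm_train(fm, "gaussian", C = 1, gamma = 0.1)
  expect_s3_class(model, "cytorec_svm")
})

test_that("prediction on a mismatched schema is rejected", {
  fm <- clusters_fm()
  model <- svm_train(fm, "linear")
  other <- feature_matrix(fm$values[, 1:3], ids = fm$ids, schema = "toy3")
  expect_error(predict(model, other), class = "cytorec_schema_error")
})

test_that("duplicating every row leaves held-out predictions unchanged", {
  fm <- clusters_fm(n = 40)
  dup <- feature_matrix(rbind(fm$values, fm$values),
                        ids = c(fm$ids, paste0(fm$ids, "_b")),
                        labels = c(fm$labels, fm$labels), schema = "toy")
  probe <- clusters_fm(n = 20, seed = 97)
  m1 <- svm_train(fm, "linear", C = 1)
  m2 <- svm_train(dup, "linear", C = 1)
  expect_identical(unname(predict(m1, probe)), unname(predict(m2, probe)))
})

test_that("LIBSVM text persistence reproduces e1071 predictions exactly", {
  for (kernel in c("linear", "gaussian")) {
    fm <- clusters_fm(n = 50, sep = 2, seed = 83)
    probe <- clusters_fm(n = 30, sep = 2, seed = 89)
    model <- svm_train(fm, kernel, C = 2,
                       gamma = if (kernel == "gaussian") 0.25)
    f <- withr::local_tempfile(fileext = ".model")
    write_svm_model(model, f)
    reloaded <- read_svm_model(f)
    expect_identical(unname(predict(reloaded, probe)),
                     unname(predict(model, probe)))
  }
})

test_that("fold assignment is balanced, stratified and deterministic", {
  labels <- rep(c(1L, -1L), c(30L, 70L))
  fold <- cv_folds(labels, 10, seed = 5)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  pos_per_fold <- table(fold[labels == 1L])
  expect_true(max(pos_per_fold) - min(pos_per_fold) <= 1)
  expect_identical(fold, cv_folds(labels, 10, seed = 5))
  expect_false(identical(fold, cv_folds(labels, 10, seed = 6)))
  expect_error(cv_folds(rep(c(1L, -1L), c(3L, 97L)), 10),
               class = "cytorec_stratification_error")
})

test_that("10-fold CV on 100 items tests each item exactly once per repetition", {
  fm <- clusters_fm(n = 100)
  res <- kfold_cv(fm, k = 10, seed = 2)
  sizes <- vapply(res$folds, function(r) sum(r$counts), numeric(1))
  expect_equal(unname(sizes), rep(10, 10))
  expect_equal(sum(sizes), 100)
  expect_equal(res$mean[["acc"]], 1)  # separable data
})

test_that("leave-one-out CV tests every item exactly once", {
  fm <- clusters_fm(n = 20)
  res <- kfold_cv(fm, k = 20, seed = 3, stratified = FALSE)
  expect_equal(sum(vapply(res$folds, function(r) sum(r$counts), numeric(1))), 20)
})

test_that("CV is reproducible from its seed", {
  fm <- clusters_fm(n = 40, sep = 1.5)
  r1 <- kfold_cv(fm, k = 5, seed = 11)
  r2 <- kfold_cv(fm, k = 5, seed = 11)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_equal(r1$mean, r2$mean)
})

test_that("shuffled labels give chance-level CV accuracy on balanced data", {
  set.seed(101)
  fm <- clusters_fm(n = 100, sep = 6)
  shuffled <- feature_matrix(fm$values, ids = fm$ids,
                             labels = sample(fm$labels), schema = "toy")
  res <- kfold_cv(shuffled, k = 10, seed = 7)
  # binomial null: acc within 3 SD of 0.5, SD = sqrt(0.25/100)
  expect_lt(abs(res$mean[["acc"]] - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("repeated CV reports per-rep means, fold SDs and is reproducible", {
  fm <- clusters_fm(n = 60)
  res <- repeated_cv(fm, k = 5, reps = 2, base_seed = 19)
  expect_length(res$results, 2L)
  expect_equal(res$table$acc, c(1, 1))       # perfect separation
  expect_equal(unname(res$between_rep_sd["acc"]), 0)
  res2 <- repeated_cv(fm, k = 5, reps = 2, base_seed = 19)
  expect_equal(res$table, res2$table)
})

test_that("rep-to-rep accuracy spread is small on default synthetic data", {
  cfg <- generator_config(seed = 127)  # generator defaults: 100 + 100
  d <- gen_data(cfg)
  fm <- extract_features(d$sequences, "sp", predictions = d$predictions,
                         labels = d$labels)
  res <- repeated_cv(fm, k = 10, reps = 5, base_seed = 127)
  expect_lt(max(res$table$acc) - min(res$table$acc), 0.02)
})

test_that("grid search covers the lattice and breaks ties toward small (C, gamma)", {
  fm <- clusters_fm(n = 40)
  one <- grid_search(fm, C_values = 1, gamma_values = 1, inner_k = 2)
  expect_equal(dim(one$surface), c(1L, 1L))
  expect_equal(c(one$best_C, one$best_gamma), c(1, 1))

  # all-identical rows: every cell ties; smallest C then gamma must win
  const <- feature_matrix(matrix(1, 20, 3),
                          ids = sprintf("c%02d", 1:20),
                          labels = rep(c(1L, -1L), 10), schema = "const")
  flat <- grid_search(const, C_values = c(4, 1, 2), gamma_values = c(8, 2),
                      inner_k = 2, seed = 1)
  expect_true(length(unique(as.vector(flat$surface))) == 1L)
  expect_equal(c(flat$best_C, flat$best_gamma), c(1, 2))

  full <- grid_search(fm, inner_k = 2, seed = 1)
  expect_equal(dim(full$surface), c(11L, 11L))
  expect_equal(sum(!is.na(full$surface)), 121L)
  expect_gte(full$best_accuracy, max(full$surface))
})

test_that("ratio split honours the requested composition", {
  set.seed(3)
  n_pos <- 100; n_neg <- 900
  fm <- feature_matrix(matrix(rnorm((n_pos + n_neg) * 2), ncol = 2),
                       ids = sprintf("r%04d", 1:(n_pos + n_neg)),
                       labels = rep(c(1L, -1L), c(n_pos, n_neg)),
                       schema = "toy2")
  parts <- ratio_split(fm, positive_fraction = 0.1, test_fraction = 0.2,
                       seed = 23)
  expect_equal(nrow(parts$test$values), 200L)
  expect_equal(sum(parts$test$labels == 1L), 20L)
  expect_equal(sum(parts$train$labels == 1L), 80L)
  expect_equal(nrow(parts$train$values), 800L)
  expect_length(intersect(parts$train$ids, parts$test$ids), 0L)
})

test_that("balanced data split at ratio 0.5 is stratified", {
  fm <- clusters_fm(n = 40)
  parts <- ratio_split(fm, 0.5, 0.25, seed = 29)
  expect_equal(sum(parts$test$labels == 1L), 5L)
  expect_equal(nrow(parts$test$values), 10L)
})

test_that("an unrealisable ratio is a composition error", {
  fm <- clusters_fm(n = 20)  # 10 pos + 10 neg
  expect_error(ratio_split(fm, 0.1, 0.2, seed = 1),
               class = "cytorec_composition_error")
})
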
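test_that("generator produces the requested composition and lengths", {
  cfg <- generator_config(n_pos = 3, n_neg = 27, seed = 5)
  sq <- gen_sequences(cfg)
  expect_length(sq$sequences, 30L)
  expect_equal(sum(sq$labels == 1L), 3L)
  lens <- nchar(sq$sequences)
  expect_true(all(lens >= 30 & lens <= 60))
  expect_true(all(vapply(sq$sequences, function(s)
    all(strsplit(s, "")[[1]] %in% AA_ALPHABETICAL), logical(1))))
})

test_that("effect_size 0 makes the classes exchangeable in composition", {
  # two-sample chi-square on pooled residue counts, 100 seeded replicates
  pvals <- vapply(1:100, function(seed) {
    cfg <- generator_config(n_pos = 10, n_neg = 10, effect_size = 0,
                            seed = seed)
    sq <- gen_sequences(cfg)
    count_class <- function(lbl) {
      chars <- unlist(strsplit(sq$sequences[sq$labels == lbl], ""))
      table(factor(chars, levels = AA_ALPHABETICAL))
    }
    suppressWarnings(
      stats::chisq.test(rbind(count_class(1L), count_class(-1L)))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("a large effect size makes n-gram features linearly separable", {
  cfg <- generator_config(n_pos = 50, n_neg = 50, effect_size = 2, seed = 7)
  sq <- gen_sequences(cfg)
  fm <- extract_ngram(sq$sequences, sq$labels)
  res <- kfold_cv(fm, k = 10, kernel = "linear", seed = 7)
  expect_gt(res$mean[["acc"]], 0.9)
})

test_that("noise-free profiles round-trip and reproduce the pssm20 hand formula", {
  s <- "MKVLYACDEFGHIKLMNPQRSTVWY"
  prof <- gen_pssm(s, noise = 0, signal = 5, seed = 1, id = "m")
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(prof, f)
  expect_equal(unname(parse_pssm(f)$scores), unname(prof$scores))
  expect_equal(dim(prof$scores), c(nchar(s), 20L))

  # column mean = (n_j * sigma(signal) + (L - n_j) * sigma(-1)) / L
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  nj <- vapply(PSSM_RESIDUE_ORDER, function(a) sum(chars == a), numeric(1))
  expected <- (nj / (1 + exp(-5)) + (L - nj) / (1 + exp(1))) / L
  expect_equal(unname(pssm20(prof)), unname(expected), tolerance = 1e-12)
})

test_that("synthetic ss2 rows are exactly stochastic and biasable", {
  s <- strrep("ACDEF", 8)
  sp <- gen_ss2(s, structure_bias = 0.5, label = 1L, seed = 9)
  expect_equal(unname(rowSums(sp$probabilities)), rep(1, 40))
  f <- withr::local_tempfile(fileext = ".ss2")
  write_ss2(sp, f)
  expect_identical(parse_ss2(f)$states, sp$states)

  # with stay probability 1 the chain freezes in its initial state
  frozen <- simulate_ss_states(25, bias = 0, stay = 1, seed = 11)
  first <- substr(frozen, 1, 1)
  expect_identical(frozen, strrep(first, 25))
  mr <- maxrun_features(frozen)
  expect_equal(unname(mr[paste0("maxrun.", first)]), 1)
  expect_equal(sum(mr), 1)
})

test_that("zero structure bias leaves class state frequencies matched", {
  cfg <- generator_config(n_pos = 40, n_neg = 40, effect_size = 0,
                          structure_bias = 0, seed = 13)
  d <- gen_data(cfg)
  freq_class <- function(lbl) {
    states <- unlist(strsplit(vapply(
      d$predictions[d$labels == lbl], function(p) p$states, character(1)), ""))
    as.vector(table(factor(states, levels = c("H", "E", "C")))) / length(states)
  }
  expect_lt(max(abs(freq_class(1L) - freq_class(-1L))), 0.06)
})

test_that("gen_dataset writes a complete, byte-identical-by-seed directory", {
  cfg <- generator_config(n_pos = 3, n_neg = 3, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_dataset(cfg, d1)
  gen_dataset(cfg, d2)
  expect_true(file.exists(file.path(d1, "sequences.fasta")))
  expect_length(list.files(file.path(d1, "pssm")), 6L)
  expect_length(list.files(file.path(d1, "ss2")), 6L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  labs <- read.delim(file.path(d1, "labels.tsv"))
  expect_equal(sum(labs$label == 1), 3L)

  rel <- list.files(d1, recursive = TRUE)
  expect_identical(rel, list.files(d2, recursive = TRUE))
  for (fn in rel) {
    expect_identical(readLines(file.path(d1, fn), warn = FALSE),
                     readLines(file.path(d2, fn), warn = FALSE),
                     info = fn)
  }
})

test_that("the dataset directory feeds the extraction pipeline end to end", {
  cfg <- generator_config(n_pos = 4, n_neg = 4, seed = 19)
  dir <- withr::local_tempdir()
  gen_dataset(cfg, dir)
  fm <- dataset_features(dir, "psp")
  expect_equal(dim(fm$values), c(8L, 448L))
  expect_equal(sum(fm$labels == 1L), 4L)

  # a missing auxiliary file skips that sequence with a warning
  unlink(file.path(dir, "pssm", paste0(fm$ids[1], ".pssm")))
  expect_warning(fm2 <- dataset_features(dir, "psp"), "skipping")
  expect_equal(nrow(fm2$values), 7L)
  expect_identical(attr(fm2, "skipped"), fm$ids[1])
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(length_range = c(10, 60)),
               class = "cytorec_validation_error")
  expect_error(generator_config(effect_size = -1),
               class = "cytorec_validation_error")
})
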
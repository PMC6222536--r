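test_that("property z-scoring yields mean 0 and population SD 1", {
  tab <- normalize_properties(pseaac_property_table())
  for (col in c("hydrophilicity", "hydrophobicity", "mass")) {
    x <- tab[[col]]
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-10)
  }
})

test_that("a constant property column is a degenerate-property error", {
  tab <- pseaac_property_table()
  tab$mass <- rep(3, 20)
  expect_error(normalize_properties(tab), class = "cytorec_degenerate_error")
})

test_that("a single-spike property column normalises to mean 0, SD 1", {
  tab <- pseaac_property_table()
  tab$mass <- c(rep(0, 19), 20)
  norm <- normalize_properties(tab)
  expect_lt(abs(mean(norm$mass)), 1e-10)
  expect_lt(abs(sqrt(mean((norm$mass - mean(norm$mass))^2)) - 1), 1e-10)
})

test_that("correlation factors vanish on homopolymers and period-matched lags", {
  expect_equal(correlation_factors(strrep("A", 21), lam = 10), rep(0, 10))
  b <- correlation_factors(strrep("AC", 11), lam = 4)  # period-2 sequence
  expect_equal(b[[2]], 0)
  expect_equal(b[[4]], 0)
  expect_gt(b[[1]], 0)
})

test_that("correlation factors are non-negative", {
  set.seed(9)
  for (i in 1:20) {
    b <- correlation_factors(random_sequence(sample(15:50, 1)), lam = 10)
    expect_true(all(b >= 0))
  }
})

test_that("homopolymer PseAAC puts all mass on its own composition slot", {
  v <- pseaac_features(strrep("A", 21))
  expect_equal(v[["aac.A"]], 1)
  expect_equal(sum(v), 1)
  expect_equal(length(v), 30L)
})

test_that("PseAAC slots are non-negative and sum to 1", {
  set.seed(13)
  for (i in 1:20) {
    v <- pseaac_features(random_sequence(sample(12:60, 1)))
    expect_true(all(v >= 0))
    expect_lt(abs(sum(v) - 1), 1e-9)
    expect_length(v, 30L)
  }
})

test_that("PseAAC equals a straight-line re-evaluation of the formulas", {
  set.seed(21)
  for (i in 1:30) {
    s <- random_sequence(25)
    expect_equal(unname(pseaac_features(s)), unname(naive_pseaac(s)),
                 tolerance = 1e-13)
  }
})

test_that("rescaling raw property columns does not change the output", {
  set.seed(3)
  s <- random_sequence(30)
  tab <- pseaac_property_table()
  tab$hydrophilicity <- tab$hydrophilicity * 7
  tab$hydrophobicity <- tab$hydrophobicity * 0.01
  tab$mass <- tab$mass * 1000
  expect_equal(pseaac_features(s, table = tab), pseaac_features(s))
})

test_that("output dimension tracks lambda and short sequences error", {
  s <- random_sequence(30)
  expect_length(pseaac_features(s, lam = 5L), 25L)
  expect_error(pseaac_features(random_sequence(10), lam = 10L),
               class = "cytorec_length_error")
})

test_that("composition block is permutation-invariant, correlation block is not tied to it", {
  set.seed(31)
  s <- random_sequence(40)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  v1 <- pseaac_features(s)
  v2 <- pseaac_features(perm)
  # raw frequencies identical; slots differ only through the shared denominator
  expect_equal(v1[1:20] / sum(v1[1:20]), v2[1:20] / sum(v2[1:20]))
})

test_that("the shipped property TSV matches the built-in constants", {
  f <- system.file("extdata", "pseaac_properties.tsv", package = "cytorec")
  expect_true(nzchar(f))
  expect_equal(read_property_table(f), pseaac_property_table())
})

test_that("a property table round-trips through its TSV override format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(pseaac_property_table(), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(read_property_table(f), pseaac_property_table())
})
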
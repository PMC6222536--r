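EXAMPLE <- "EEEEHHEEHHHCC"  # 13 states: 4xE, 2xH, 2xE, 3xH, 2xC

test_that("composition features on the worked example", {
  expect_equal(unname(composition_features(EXAMPLE)),
               c(5 / 13, 6 / 13, 2 / 13))
  expect_equal(unname(composition_features("HHHH")), c(1, 0, 0))
})

test_that("composition triple always sums to 1", {
  set.seed(41)
  for (i in 1:20) {
    sp <- random_ss(sample(2:50, 1))
    expect_equal(sum(composition_features(sp)), 1)
  }
})

test_that("positional features on hand-summed strings", {
  expect_equal(unname(positional_features("HC")), c(0.5, 0, 1))
  expect_equal(unname(positional_features(EXAMPLE)),
               c((5 + 6 + 9 + 10 + 11) / 156,
                 (1 + 2 + 3 + 4 + 7 + 8) / 156,
                 (12 + 13) / 156))
  expect_equal(positional_features("HH")[["pos.E"]], 0)
  expect_error(positional_features("H"), class = "cytorec_length_error")
})

test_that("maximal run lengths reproduce the worked example", {
  expect_identical(max_run_length(EXAMPLE, "H"), 3L)
  expect_identical(max_run_length(EXAMPLE, "E"), 4L)
  expect_identical(max_run_length(EXAMPLE, "C"), 2L)
  expect_equal(unname(maxrun_features(EXAMPLE)), c(3, 4, 2) / 13)
  expect_equal(unname(maxrun_features("H")), c(1, 0, 0))
  expect_equal(maxrun_features("HHEE")[["maxrun.C"]], 0)
})

test_that("maxrun is invariant under string reversal", {
  set.seed(43)
  for (i in 1:20) {
    sp <- random_ss(sample(2:40, 1))
    rev_states <- paste(rev(strsplit(sp$states, "")[[1]]), collapse = "")
    expect_equal(maxrun_features(sp$states), maxrun_features(rev_states))
  }
})

test_that("transition matrix collapses segments and fills rows per denominator", {
  tm <- transition_matrix(EXAMPLE)  # S0 = beta alpha beta alpha
  expect_equal(unname(tm$counts), c(0, 1, 2, 0))
  expect_equal(unname(tm$tpm), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(transition_matrix("CCCC")$tpm), matrix(0, 2, 2))
  expect_equal(unname(transition_matrix("HHH")$tpm), matrix(0, 2, 2))
})

test_that("defined TPM rows sum to 1, degenerate rows are zero", {
  set.seed(47)
  for (i in 1:30) {
    tm <- transition_matrix(random_ss(sample(2:40, 1)))
    for (r in 1:2) {
      expect_true(abs(sum(tm$tpm[r, ]) - 1) < 1e-12 ||
                    all(tm$tpm[r, ] == 0))
    }
  }
})

test_that("tpm features order the entries row-major plus column averages", {
  expect_equal(unname(tpm_features(transition_matrix(EXAMPLE))),
               c(0, 1, 1, 0, 0.5, 0.5))
  expect_equal(unname(tpm_features(transition_matrix("CCC"))), rep(0, 6))
  fake <- structure(list(tpm = diag(2), counts = c(aa = 1, ab = 0, ba = 0, bb = 1)),
                    class = "transition_matrix")
  expect_equal(unname(tpm_features(fake)), c(1, 0, 0, 1, 0.5, 0.5))
})

test_that("spm features are the probability column means in C,H,E order", {
  sp <- structure_prediction("HC", rbind(c(1 / 3, 1 / 3, 1 / 3),
                                         c(1 / 3, 1 / 3, 1 / 3)))
  expect_equal(unname(spm_features(sp)), rep(1 / 3, 3))
  sp1 <- structure_prediction("E", matrix(c(0.2, 0.1, 0.7), 1))
  expect_equal(unname(spm_features(sp1)), c(0.2, 0.1, 0.7))
})

test_that("the assembled 18-vector matches the naive oracle and stays in [0,1]", {
  set.seed(53)
  for (i in 1:30) {
    sp <- random_ss(sample(2:60, 1))
    v <- sss_features(sp)
    expect_length(v, 18L)
    expect_identical(names(v), feature_schema("sss18"))
    expect_equal(unname(v), naive_sss(sp$states, sp$probabilities),
                 tolerance = 1e-13)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[1:3]), 1)
    expect_equal(sum(v[16:18]), 1, tolerance = 1e-9)
  }
})

test_that("an all-H prediction forces the degenerate pattern", {
  L <- 10
  probs <- matrix(rep(c(0, 1, 0), each = L), L)
  sp <- structure_prediction(strrep("H", L), probs)
  v <- sss_features(sp)
  expect_equal(unname(v[c("comp.H", "comp.E", "comp.C")]), c(1, 0, 0))
  expect_equal(v[["pos.H"]], sum(1:L) / (L * (L - 1)))
  expect_equal(unname(v[c("maxrun.H", "maxrun.E", "maxrun.C")]), c(1, 0, 0))
  expect_equal(unname(v[10:15]), rep(0, 6))
  expect_equal(unname(v[16:18]), c(0, 1, 0))
})
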
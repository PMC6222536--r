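# Independent, deliberately naive re-implementations of each feature family,
# written straight from the defining formulas. They share only the input data
# and constant tables with the package; every computation path is separate.

random_sequence <- function(L) {
  paste(sample(AA_ALPHABETICAL, L, replace = TRUE), collapse = "")
}

naive_ngram <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (a in AA_ALPHABETICAL) {
    count <- 0
    for (i in 1:L) if (chars[i] == a) count <- count + 1
    out <- c(out, (20 / 420) * count / L)
  }
  for (a in AA_ALPHABETICAL) {
    for (b in AA_ALPHABETICAL) {
      count <- 0
      for (i in 1:(L - 1)) {
        if (chars[i] == a && chars[i + 1] == b) count <- count + 1
      }
      out <- c(out, (400 / 420) * count / (L - 1))
    }
  }
  out
}

naive_pseaac <- function(seq, lam = 10, w = 0.05) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  tab <- pseaac_property_table()
  zscore <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  h1 <- zscore(tab$hydrophilicity)
  h2 <- zscore(tab$hydrophobicity)
  m <- zscore(tab$mass)
  names(h1) <- names(h2) <- names(m) <- tab$residue
  f <- numeric(20)
  for (j in 1:20) f[j] <- sum(chars == AA_ALPHABETICAL[j]) / L
  b <- numeric(lam)
  for (g in 1:lam) {
    acc <- 0
    for (i in 1:(L - g)) {
      a1 <- chars[i]; a2 <- chars[i + g]
      acc <- acc + ((h1[a1] - h1[a2])^2 + (h2[a1] - h2[a2])^2 +
                      (m[a1] - m[a2])^2) / 3
    }
    b[g] <- acc / (L - g)
  }
  D <- sum(f) + w * sum(b)
  c(f / D, w * b / D)
}

naive_pssm20 <- function(scores) {
  L <- nrow(scores)
  out <- numeric(20)
  for (j in 1:20) {
    acc <- 0
    for (i in 1:L) acc <- acc + 1 / (1 + exp(-scores[i, j]))
    out[j] <- acc / L
  }
  out
}

# the lagged cross-column correlation features, straight triple loop;
# with `keep_diagonal` the s = t cells (g = 0) are returned too
naive_pssm380 <- function(scores, keep_diagonal = FALSE) {
  L <- nrow(scores)
  A <- 1 / (1 + exp(-scores))
  Fbar <- numeric(20)
  V <- numeric(20)
  for (j in 1:20) {
    Fbar[j] <- sum(A[, j]) / L
    V[j] <- sqrt(sum((A[, j] - Fbar[j])^2) / L)
  }
  out <- numeric(0)
  for (s in 1:20) {
    for (t in 1:20) {
      if (s == t && !keep_diagonal) next
      g <- abs(s - t)
      acc <- 0
      for (i in 1:(L - g)) {
        acc <- acc + (A[i, s] - Fbar[s]) * (A[i + g, t] - Fbar[t]) /
          (V[s] * V[t])
      }
      out <- c(out, acc / (L - g))
    }
  }
  unname(out)
}

naive_sss <- function(states, probs) {
  chars <- strsplit(states, "")[[1]]
  L <- length(chars)
  comp <- c(sum(chars == "H"), sum(chars == "E"), sum(chars == "C")) / L
  pos <- c(sum(which(chars == "H")), sum(which(chars == "E")),
           sum(which(chars == "C"))) / (L * (L - 1))
  longest <- function(st) {
    best <- 0; run <- 0
    for (ch in chars) {
      run <- if (ch == st) run + 1 else 0
      best <- max(best, run)
    }
    best
  }
  maxrun <- c(longest("H"), longest("E"), longest("C")) / L
  s0 <- chars[chars != "C"]
  tokens <- character(0)
  for (ch in s0) {
    if (length(tokens) == 0 || tokens[length(tokens)] != ch) {
      tokens <- c(tokens, ch)
    }
  }
  taa <- tab <- tba <- tbb <- 0
  if (length(tokens) > 1) {
    for (i in 1:(length(tokens) - 1)) {
      pair <- paste0(tokens[i], tokens[i + 1])
      if (pair == "HH") taa <- taa + 1
      if (pair == "HE") tab <- tab + 1
      if (pair == "EH") tba <- tba + 1
      if (pair == "EE") tbb <- tbb + 1
    }
  }
  tpm <- matrix(0, 2, 2)
  if (taa + tab > 0) tpm[1, ] <- c(taa, tab) / (taa + tab)
  if (tbb + tba > 0) tpm[2, ] <- c(tba, tbb) / (tbb + tba)
  tpmf <- c(tpm[1, 1], tpm[1, 2], tpm[2, 1], tpm[2, 2],
            (tpm[1, 1] + tpm[2, 1]) / 2, (tpm[1, 2] + tpm[2, 2]) / 2)
  spm <- colSums(probs) / L
  unname(c(comp, pos, maxrun, tpmf, spm))
}

fm_subset_test <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], ids = fm$ids[idx],
                 labels = if (!is.null(fm$labels)) fm$labels[idx],
                 schema = fm$schema)
}

report_metrics_vec <- function(r) {
  c(acc = r$acc, sens = r$sens, spec = r$spec, pre = r$pre,
    f_score = r$f_score, mcc = r$mcc)
}

naive_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == -1 & pred == 1)
  tn <- sum(truth == -1 & pred == -1)
  fn <- sum(truth == 1 & pred == -1)
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (pre + sens > 0) 2 * pre * sens / (pre + sens) else 0
  mcc <- if (tp == 0 && fp == 0) -1 else {
    den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  c(acc = acc, sens = sens, spec = spec, pre = pre, f_score = f, mcc = mcc)
}

random_profile <- function(L, scale = 4) {
  pssm_profile(matrix(round(rnorm(L * 20, 0, scale)), L, 20),
               sequence_id = "rnd")
}

random_ss <- function(L) {
  states <- paste(sample(c("H", "E", "C"), L, replace = TRUE), collapse = "")
  probs <- matrix(runif(L * 3), L, 3)
  probs <- probs / rowSums(probs)
  structure_prediction(states, probs, sequence_id = "rnd")
}
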
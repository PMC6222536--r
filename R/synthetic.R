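# Synthetic fixture generator: consistent (sequence, PSSM, SS2, label)
# quadruples with controllable class separation, so every stage of the
# pipeline is testable without external databases or prediction software.
#
# Signal model (chosen once; see the methods vignette):
# * negative-class residues are uniform over the 20 amino acids; the
#   positive class applies an exponential (softmax) tilt of strength
#   `effect_size` toward the fixed hydrophobic subset {F,I,L,M,V};
# * profiles score +pssm_signal on the true residue column and -1 elsewhere,
#   plus integer-rounded Gaussian noise of SD `pssm_noise`;
# * state strings come from a 3-state Markov chain over {H,E,C} with stay
#   probability `stay`; for positive sequences every transition into H is
#   tilted by exp(structure_bias).
# Sequence, profile and structure signals are generated independently given
# the class, so each feature family is individually informative.

ENRICHED_RESIDUES <- c("F", "I", "L", "M", "V")

#' Synthetic-dataset generator configuration
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer pair (min, max) of sequence lengths; the
#'   minimum must be >= 20 (precondition of the PSSM-380 and PseAAC
#'   features).
#' @param effect_size Composition divergence between classes (>= 0; 0 means
#'   both classes share one distribution).
#' @param structure_bias Class-dependent helix-propensity shift of the
#'   secondary-structure chain (0 = no class signal).
#' @param pssm_noise SD of the integer-rounded Gaussian noise added to
#'   profile scores (>= 0).
#' @param pssm_signal Score of the true residue column in a noise-free
#'   profile.
#' @param seed Integer master seed; all generation is derived from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pos = 100L, n_neg = 100L,
                             length_range = c(30L, 60L), effect_size = 1,
                             structure_bias = 0.3, pssm_noise = 2,
                             pssm_signal = 5, seed = 1L) {
  if (length(length_range) != 2L || length_range[1L] < 20L ||
      length_range[2L] < length_range[1L]) {
    abort_validation("length_range must be (min, max) with min >= 20")
  }
  if (effect_size < 0 || pssm_noise < 0) {
    abort_validation("effect_size and pssm_noise must be >= 0")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 effect_size = effect_size, structure_bias = structure_bias,
                 pssm_noise = pssm_noise, pssm_signal = pssm_signal,
                 seed = as.integer(seed)),
            class = "generator_config")
}

class_composition <- function(effect_size, positive) {
  w <- rep(1, 20)
  if (positive && effect_size > 0) {
    w[AA_ALPHABETICAL %in% ENRICHED_RESIDUES] <- exp(effect_size)
  }
  w / sum(w)
}

#' Generate labelled synthetic sequences
#'
#' Draws residues from class-specific multinomials (see the generator notes
#' above) with lengths uniform over `length_range`. Fully determined by
#' `cfg$seed`.
#'
#' @param cfg A `generator_config`.
#' @return List with `sequences` (named character vector, ids `P0001...` /
#'   `N0001...`) and `labels` (named +1/-1 integer vector).
#' @export
gen_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  ids <- c(sprintf("P%04d", seq_len(cfg$n_pos)),
           sprintf("N%04d", seq_len(cfg$n_neg)))
  labels <- stats::setNames(rep(c(1L, -1L), c(cfg$n_pos, cfg$n_neg)), ids)
  p_pos <- class_composition(cfg$effect_size, TRUE)
  p_neg <- class_composition(cfg$effect_size, FALSE)
  lens <- sample(seq.int(cfg$length_range[1L], cfg$length_range[2L]),
                 length(ids), replace = TRUE)
  seqs <- vapply(seq_along(ids), function(i) {
    prob <- if (labels[[i]] == 1L) p_pos else p_neg
    paste(sample(AA_ALPHABETICAL, lens[i], replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  list(sequences = stats::setNames(seqs, ids), labels = labels)
}

#' Generate a synthetic evolutionary profile for a sequence
#'
#' Noise-free rows score `signal` on the residue actually present at that
#' position and -1 on the other 19 columns; integer-rounded Gaussian noise
#' of SD `noise` is then added. With `noise = 0` the profile is
#' deterministic and round-trips exactly through [write_pssm()] /
#' [parse_pssm()].
#'
#' @param seq Residue string.
#' @param noise Noise SD (>= 0).
#' @param signal True-residue score.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @param path Optional output path; when given, the profile is also
#'   written in the PSI-BLAST ASCII dialect.
#' @return A `pssm_profile`, invisibly when `path` is given.
#' @export
gen_pssm <- function(seq, noise = 0, signal = 5, seed = 1L,
                     id = "<unnamed>", path = NULL) {
  seq <- validate_residues(seq, id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  set.seed(seed)
  scores <- matrix(-1, nrow = L, ncol = 20L)
  scores[cbind(seq_len(L), match(chars, PSSM_RESIDUE_ORDER))] <- signal
  if (noise > 0) {
    scores <- scores + round(matrix(stats::rnorm(L * 20L, 0, noise), L, 20L))
  }
  profile <- pssm_profile(scores, sequence_id = id, residues = seq)
  if (!is.null(path)) {
    write_pssm(profile, path)
    return(invisible(profile))
  }
  profile
}

ss_transition_matrix <- function(bias = 0, stay = 0.8) {
  move <- (1 - stay) / 2
  P <- matrix(move, 3L, 3L, dimnames = list(SS_STATES, SS_STATES))
  diag(P) <- stay
  if (bias != 0) {
    P[, "H"] <- P[, "H"] * exp(bias)
    P <- P / rowSums(P)
  }
  P
}

#' Simulate a secondary-structure state string
#'
#' Hidden 3-state Markov chain over H, E, C with stay probability `stay`;
#' transitions into H are tilted by `exp(bias)`. The initial state is drawn
#' from the uniform distribution tilted the same way.
#'
#' @param L Length of the string.
#' @param bias Helix tilt (0 = symmetric chain).
#' @param stay Stay probability of the untilted chain.
#' @param seed Integer seed.
#' @return H/E/C state string of length L.
#' @export
simulate_ss_states <- function(L, bias = 0, stay = 0.8, seed = 1L) {
  set.seed(seed)
  P <- ss_transition_matrix(bias, stay)
  init <- rep(1, 3)
  names(init) <- SS_STATES
  if (bias != 0) init["H"] <- exp(bias)
  init <- init / sum(init)
  states <- character(L)
  states[1L] <- sample(SS_STATES, 1L, prob = init)
  for (i in seq_len(L - 1L)) {
    states[i + 1L] <- sample(SS_STATES, 1L, prob = P[states[i], ])
  }
  paste(states, collapse = "")
}

#' Generate a synthetic secondary-structure prediction for a sequence
#'
#' The state string comes from [simulate_ss_states()] with
#' `bias = structure_bias` for positive sequences and 0 for negatives; the
#' per-row probability triple puts 0.8 on the realised state and 0.1 on the
#' other two (rows sum to 1 exactly).
#'
#' @param seq Residue string (fixes the length and the residue column of
#'   the .ss2 output).
#' @param structure_bias Helix tilt applied to positive sequences.
#' @param label +1 or -1.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @param stay Stay probability of the state chain.
#' @param path Optional output path; when given, the prediction is also
#'   written in the .ss2 dialect.
#' @return A `structure_prediction`, invisibly when `path` is given.
#' @export
gen_ss2 <- function(seq, structure_bias = 0, label = -1L, seed = 1L,
                    id = "<unnamed>", stay = 0.8, path = NULL) {
  seq <- validate_residues(seq, id)
  L <- nchar(seq)
  bias <- if (label == 1L) structure_bias else 0
  states <- simulate_ss_states(L, bias = bias, stay = stay, seed = seed)
  chars <- strsplit(states, "", fixed = TRUE)[[1L]]
  probs <- matrix(0.1, nrow = L, ncol = 3L,
                  dimnames = list(NULL, SS2_PROB_ORDER))
  probs[cbind(seq_len(L), match(chars, SS2_PROB_ORDER))] <- 0.8
  sp <- structure_prediction(states, probs, sequence_id = id, residues = seq)
  if (!is.null(path)) {
    write_ss2(sp, path)
    return(invisible(sp))
  }
  sp
}

# deterministic per-item seeds derived from the master seed, kept in 32-bit
# integer range
derive_seed <- function(seed, stream, i) {
  as.integer((as.numeric(seed) + 10007 * stream + i) %% .Machine$integer.max)
}

#' Generate a complete synthetic dataset in memory
#'
#' Sequences, matched profiles and structure predictions plus labels, all
#' derived deterministically from `cfg$seed`.
#'
#' @param cfg A `generator_config`.
#' @return List with `sequences`, `labels`, `profiles` (list of
#'   `pssm_profile`), `predictions` (list of `structure_prediction`).
#' @export
gen_data <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  sq <- gen_sequences(cfg)
  ids <- names(sq$sequences)
  profiles <- lapply(seq_along(ids), function(i) {
    gen_pssm(sq$sequences[[i]], noise = cfg$pssm_noise,
             signal = cfg$pssm_signal, seed = derive_seed(cfg$seed, 1L, i),
             id = ids[i])
  })
  predictions <- lapply(seq_along(ids), function(i) {
    gen_ss2(sq$sequences[[i]], structure_bias = cfg$structure_bias,
            label = sq$labels[[i]], seed = derive_seed(cfg$seed, 2L, i),
            id = ids[i])
  })
  names(profiles) <- ids
  names(predictions) <- ids
  list(sequences = sq$sequences, labels = sq$labels,
       profiles = profiles, predictions = predictions)
}

#' Write a synthetic dataset directory
#'
#' Produces a self-consistent fixture directory:
#' `sequences.fasta`, `labels.tsv` (id, label), `pssm/<id>.pssm`,
#' `ss2/<id>.ss2` and a `manifest.json` recording the generator
#' configuration. Identical configurations produce byte-identical
#' directories.
#'
#' @param cfg A `generator_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
gen_dataset <- function(cfg, dir) {
  data <- gen_data(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  dir.create(file.path(dir, "ss2"), showWarnings = FALSE)
  write_fasta(data$sequences, file.path(dir, "sequences.fasta"))
  utils::write.table(
    data.frame(id = names(data$labels), label = data$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(data$sequences)) {
    write_pssm(data$profiles[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
    write_ss2(data$predictions[[id]], file.path(dir, "ss2", paste0(id, ".ss2")))
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
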
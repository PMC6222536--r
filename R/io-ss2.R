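#' Parse a PSI-PRED .ss2 secondary-structure prediction
#'
#' Reads the PSI-PRED VFORMAT: a comment header, then one row per residue
#' with the position index, the residue, the predicted state letter (C, H or
#' E) and the three state probabilities in C, H, E column order.
#'
#' Rows whose probabilities sum outside `[0.99, 1.01]` are kept but flagged
#' with a warning (class `cytorec_probability_warning`).
#'
#' @param path Path to the .ss2 file.
#' @param sequence_id Id to record; defaults to the file name without
#'   extension.
#' @return A `structure_prediction` object.
#' @export
parse_ss2 <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("ss2 file not found: %s", path))
  sequence_id <- sequence_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  if (length(rows) == 0L) {
    abort_parse(sprintf("'%s': empty ss2 body", path))
  }
  states <- character(length(rows))
  probs <- matrix(NA_real_, nrow = length(rows), ncol = 3L,
                  dimnames = list(NULL, SS2_PROB_ORDER))
  residues <- character(length(rows))
  for (i in seq_along(rows)) {
    tk <- strsplit(trimws(rows[[i]]), "[[:space:]]+")[[1L]]
    if (length(tk) < 6L) {
      abort_parse(sprintf("'%s': malformed ss2 row %d (%d fields, need 6)",
                          path, i, length(tk)))
    }
    if (!(tk[3L] %in% SS2_PROB_ORDER)) {
      abort_parse(sprintf("'%s' row %d: state letter '%s' not in {C,H,E}",
                          path, i, tk[3L]))
    }
    p <- suppressWarnings(as.numeric(tk[4:6]))
    if (anyNA(p)) {
      abort_parse(sprintf("'%s' row %d: non-numeric probability", path, i))
    }
    if (sum(p) < 0.99 || sum(p) > 1.01) {
      warning(warningCondition(
        sprintf("'%s' row %d: probabilities sum to %.4f", path, i, sum(p)),
        class = "cytorec_probability_warning"))
    }
    residues[i] <- tk[2L]
    states[i] <- tk[3L]
    probs[i, ] <- p
  }
  structure_prediction(paste(states, collapse = ""), probs,
                       sequence_id = sequence_id,
                       residues = paste(residues, collapse = ""))
}

#' Construct a secondary-structure prediction object
#'
#' @param states Character scalar over the alphabet {H, E, C}, length L.
#' @param probabilities L x 3 numeric matrix of state probabilities, column
#'   order (C, H, E) as in .ss2 files.
#' @param sequence_id Id of the underlying sequence.
#' @param residues Optional residue string of length L.
#' @return A `structure_prediction` object.
#' @export
structure_prediction <- function(states, probabilities,
                                 sequence_id = "<unnamed>", residues = NULL) {
  stopifnot(is.character(states), length(states) == 1L)
  chars <- strsplit(states, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    abort_validation(sprintf("prediction '%s': empty state string", sequence_id))
  }
  bad <- !(chars %in% SS_STATES)
  if (any(bad)) {
    abort_validation(sprintf("prediction '%s': state '%s' not in {H,E,C}",
                             sequence_id, chars[bad][1L]))
  }
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 3L) {
    abort_validation(sprintf("prediction '%s': probabilities must have 3 columns",
                             sequence_id))
  }
  if (nrow(probabilities) != length(chars)) {
    abort_validation(sprintf(
      "prediction '%s': %d states but %d probability rows",
      sequence_id, length(chars), nrow(probabilities)))
  }
  colnames(probabilities) <- SS2_PROB_ORDER
  structure(list(sequence_id = sequence_id, states = states,
                 probabilities = probabilities, residues = residues),
            class = "structure_prediction")
}

#' @export
print.structure_prediction <- function(x, ...) {
  cat(sprintf("<structure_prediction> '%s': %d states (%s%s)\n",
              x$sequence_id, nchar(x$states),
              substr(x$states, 1, 20),
              if (nchar(x$states) > 20) "..." else ""))
  invisible(x)
}

#' Write a structure prediction in the PSI-PRED .ss2 dialect
#'
#' @param sp A `structure_prediction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(sp, path) {
  stopifnot(inherits(sp, "structure_prediction"))
  chars <- strsplit(sp$states, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  res <- sp$residues %||% paste(rep("X", L), collapse = "")
  res <- strsplit(res, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSIPRED VFORMAT (cytorec synthetic)", ""), con)
  for (i in seq_len(L)) {
    writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       i, res[i], chars[i],
                       sp$probabilities[i, 1L], sp$probabilities[i, 2L],
                       sp$probabilities[i, 3L]), con)
  }
  invisible(path)
}
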
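#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the position-specific scoring matrix emitted by PSI-BLAST with
#' `-out_ascii_pssm`: free-text header lines, a residue-order header row,
#' then one row per sequence position carrying the position index, the query
#' residue and 20 log-odds columns (real files append 20 weighted-percentage
#' columns and two information columns; only the first 20 score columns are
#' kept). Trailing statistics lines are ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence_id Id to record; defaults to the file name without
#'   extension.
#' @return A `pssm_profile`: list with `sequence_id`, `residues` (the query
#'   sequence read back from the rows), `scores` (L x 20 numeric matrix of
#'   log-odds, columns named by `column_order`), and `column_order` (the
#'   file's residue header order).
#' @export
parse_pssm <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sequence_id <- sequence_id %||% sub("\\.[^.]*$", "", basename(path))

  tok <- lapply(lines, function(x) strsplit(trimws(x), "[[:space:]]+")[[1L]])

  # residue-order header: first line whose tokens are all single letters with
  # at least 20 of them
  header_at <- 0L
  for (i in seq_along(tok)) {
    tk <- tok[[i]]
    if (length(tk) >= 20L && all(grepl("^[A-Z]$", tk))) {
      header_at <- i
      break
    }
  }
  if (header_at == 0L) {
    abort_parse(sprintf("'%s': no residue header row found", path))
  }
  column_order <- tok[[header_at]][1:20]

  residues <- character()
  rows <- list()
  for (i in seq.int(header_at + 1L, length(tok))) {
    if (i > length(tok)) break
    tk <- tok[[i]]
    if (length(tk) == 0L) break                 # blank line ends the matrix
    if (!grepl("^[0-9]+$", tk[1L])) break       # trailing statistics
    if (length(tk) < 22L) {
      abort_parse(sprintf("'%s' line %d: truncated PSSM row (%d fields, need >= 22)",
                          path, i, length(tk)))
    }
    scores <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(scores)) {
      abort_parse(sprintf("'%s' line %d: non-numeric score cell", path, i))
    }
    residues[[length(residues) + 1L]] <- tk[2L]
    rows[[length(rows) + 1L]] <- scores
  }
  if (length(rows) == 0L) {
    abort_parse(sprintf("'%s': PSSM contains no data rows", path))
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- column_order
  pssm_profile(scores, sequence_id = sequence_id,
               residues = paste(residues, collapse = ""))
}

#' Construct a PSSM profile object
#'
#' @param scores L x 20 numeric matrix of raw log-odds scores; columns must
#'   follow `column_order`.
#' @param sequence_id Id of the underlying sequence.
#' @param residues Optional residue string of length L (the query sequence).
#' @param column_order Residue ordering of the 20 columns; defaults to the
#'   PSI-BLAST header order.
#' @return A `pssm_profile` object.
#' @export
pssm_profile <- function(scores, sequence_id = "<unnamed>", residues = NULL,
                         column_order = PSSM_RESIDUE_ORDER) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    abort_parse(sprintf("profile '%s': expected 20 score columns, got %d",
                        sequence_id, ncol(scores)))
  }
  if (nrow(scores) == 0L) {
    abort_parse(sprintf("profile '%s': zero rows", sequence_id))
  }
  if (!is.numeric(scores) || anyNA(scores)) {
    abort_parse(sprintf("profile '%s': scores must be numeric and non-missing",
                        sequence_id))
  }
  if (length(column_order) != 20L || anyDuplicated(column_order)) {
    abort_validation("column_order must be 20 distinct residues")
  }
  if (!is.null(residues) && nchar(residues) != nrow(scores)) {
    abort_validation(sprintf(
      "profile '%s': %d residues but %d matrix rows",
      sequence_id, nchar(residues), nrow(scores)))
  }
  colnames(scores) <- column_order
  structure(list(sequence_id = sequence_id, residues = residues,
                 scores = scores, column_order = column_order),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> '%s': %d positions x 20 residues (%s...)\n",
              x$sequence_id, nrow(x$scores),
              paste(x$column_order[1:5], collapse = " ")))
  invisible(x)
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' Emits a file that [parse_pssm()] (and other consumers of the
#' `-out_ascii_pssm` layout) reads back exactly. Scores are written as
#' integers when integral.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- nrow(profile$scores)
  res <- profile$residues %||% paste(rep("X", L), collapse = "")
  res <- strsplit(res, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", profile$column_order), collapse = ""))
  ), con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(round(profile$scores[i, ]))),
                            collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}
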
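#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file and validates every record against the
#' 20-letter standard amino-acid alphabet. Record identifiers are taken from
#' the header line up to the first whitespace; residues are upper-cased.
#' Ambiguity codes (B, J, O, U, X, Z) are rejected rather than remapped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: one residue string per record, names are
#'   the record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort_parse(sprintf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort_parse(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate sequence id '%s' in '%s'",
                             ids[duplicated(ids)][1L], path))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) validate_residues(seqs[[i]], ids[[i]])
  seqs
}

#' Validate a residue string
#'
#' Checks that a sequence is non-empty and uses only the 20 standard
#' amino-acid letters. Called by every reader and feature extractor; errors
#' name the sequence id and the first offending character.
#'
#' @param residues Character scalar, the sequence.
#' @param id Sequence id used in error messages.
#' @return The validated (upper-case) sequence, invisibly.
#' @export
validate_residues <- function(residues, id = "<unnamed>") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    abort_validation(sprintf("sequence '%s': residues must be a single string", id))
  }
  residues <- toupper(residues)
  if (nchar(residues) == 0L) {
    abort_validation(sprintf("sequence '%s': empty residue string", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA_ALPHABETICAL)
  if (any(bad)) {
    abort_validation(sprintf(
      "sequence '%s': character '%s' at position %d is not a standard amino acid",
      id, chars[bad][1L], which(bad)[1L]))
  }
  invisible(residues)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}
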
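#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequence records, validating that
#' every sequence is non-empty and restricted to the 20 standard amino acids
#' plus `X` (unknown). Sequences are uppercased. Duplicate identifiers are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `sequence` (character,
#'   uppercase one-letter codes).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "NSNELALKLAGLDINK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    validation_error("FASTA file '%s' does not exist", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) validation_error("'%s': not valid FASTA: %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) {
    validation_error("'%s': empty FASTA file", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    validation_error("'%s': duplicate record id '%s'", path, dup[1L])
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) < 1L) {
      validation_error("record '%s': empty sequence", ids[[i]])
    }
    assert_sequence(seqs[[i]], ids[[i]])
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `sequence` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  for (i in seq_len(nrow(x))) assert_sequence(x$sequence[[i]], x$id[[i]])
  set <- Biostrings::BStringSet(stats::setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
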
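#' Read a per-residue disorder-propensity track
#'
#' Supports the three text dialects produced by the common disorder
#' predictors: `disopred` (DISOPRED3-style: `idx aa mark propensity`, mark
#' `.` or `*`), `spotd` (SPOT-Disorder-style: `idx aa propensity label`) and
#' `iupred` (IUPred2A-style plain table: `idx aa propensity`, `#` comments).
#' Residue numbering must be contiguous from 1 and propensities in \[0, 1\].
#'
#' @param path Path to the track file.
#' @param dialect One of `"disopred"`, `"spotd"`, `"iupred"`.
#' @return A tibble with columns `residue`, `aa`, `propensity` and a
#'   `predictor` attribute naming the dialect.
#' @export
read_disorder_track <- function(path, dialect = c("disopred", "spotd", "iupred")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) validation_error("track file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) validation_error("'%s': no data lines", path)
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  ncol_need <- switch(dialect, disopred = 4L, spotd = 4L, iupred = 3L)
  prop_col <- switch(dialect, disopred = 4L, spotd = 3L, iupred = 3L)
  n <- length(parts)
  residue <- integer(n)
  aa <- character(n)
  propensity <- numeric(n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < ncol_need) {
      validation_error("'%s' line %d: expected %d columns, got %d",
        path, rows[i], ncol_need, length(p))
    }
    residue[i] <- suppressWarnings(as.integer(p[[1L]]))
    aa[i] <- toupper(p[[2L]])
    propensity[i] <- suppressWarnings(as.numeric(p[[prop_col]]))
    if (is.na(residue[i]) || is.na(propensity[i])) {
      validation_error("'%s' line %d: non-numeric index or propensity", path, rows[i])
    }
    if (dialect == "disopred" && !p[[3L]] %in% c(".", "*")) {
      validation_error("'%s' line %d: disorder mark must be '.' or '*'", path, rows[i])
    }
    if (propensity[i] < 0 || propensity[i] > 1) {
      validation_error("'%s' line %d: propensity %g outside [0,1]", path, rows[i], propensity[i])
    }
  }
  if (!identical(residue, seq_len(n))) {
    bad <- which(residue != seq_len(n))[1L]
    validation_error("'%s' line %d: residue numbering not contiguous from 1 (saw %d)",
      path, rows[bad], residue[bad])
  }
  out <- tibble(residue = residue, aa = aa, propensity = propensity)
  attr(out, "predictor") <- dialect
  out
}

#' Write a disorder track in a given dialect
#'
#' @param x Tibble as returned by [read_disorder_track()].
#' @param path Output path.
#' @param dialect Output dialect (see [read_disorder_track()]).
#' @return `path`, invisibly.
#' @export
write_disorder_track <- function(x, path, dialect = c("disopred", "spotd", "iupred")) {
  dialect <- match.arg(dialect)
  mark <- ifelse(x$propensity >= 0.5, "*", ".")
  lab <- ifelse(x$propensity >= 0.5, "D", "O")
  lines <- switch(dialect,
    disopred = sprintf("%5d %s %s %6.3f", x$residue, x$aa, mark, x$propensity),
    spotd = sprintf("%d\t%s\t%.3f\t%s", x$residue, x$aa, x$propensity, lab),
    iupred = c("# prediction", sprintf("%d\t%s\t%.3f", x$residue, x$aa, x$propensity))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSIPRED-style ss2 secondary-structure file
#'
#' Whitespace-separated with six columns (index, residue, state, coil, helix
#' and strand scores); comment lines start with `#`. The reported state is
#' the argmax of the three scores; the per-residue confidence is
#' `floor(9 * max score)` (0-9), used only for display.
#'
#' @param path Path to the ss2 file.
#' @return A tibble with columns `residue`, `aa`, `state` (`H`/`E`/`C`),
#'   `confidence` (integer 0-9), `p_coil`, `p_helix`, `p_strand`.
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) validation_error("ss2 file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  if (length(rows) == 0L) validation_error("'%s': no data lines", path)
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  n <- length(parts)
  residue <- integer(n); aa <- character(n)
  sc <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 6L) {
      validation_error("'%s' line %d: expected 6 columns, got %d", path, rows[i], length(p))
    }
    if (!p[[3L]] %in% c("H", "E", "C")) {
      validation_error("'%s' line %d: unknown state letter '%s'", path, rows[i], p[[3L]])
    }
    residue[i] <- as.integer(p[[1L]])
    aa[i] <- toupper(p[[2L]])
    sc[i, ] <- suppressWarnings(as.numeric(p[4:6]))
    if (anyNA(sc[i, ])) validation_error("'%s' line %d: non-numeric score", path, rows[i])
  }
  if (!identical(residue, seq_len(n))) {
    validation_error("'%s': residue numbering not contiguous from 1", path)
  }
  state <- c("C", "H", "E")[max.col(sc, ties.method = "first")]
  tibble(
    residue = residue, aa = aa, state = state,
    confidence = as.integer(floor(9 * apply(sc, 1L, max))),
    p_coil = sc[, 1L], p_helix = sc[, 2L], p_strand = sc[, 3L]
  )
}

#' Write an ss2-style secondary-structure file
#'
#' @param x Tibble as returned by [read_ss2()]. If the score columns are
#'   absent, one-hot scores are written from `state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(x, path) {
  if (!all(c("p_coil", "p_helix", "p_strand") %in% names(x))) {
    x$p_coil <- as.numeric(x$state == "C")
    x$p_helix <- as.numeric(x$state == "H")
    x$p_strand <- as.numeric(x$state == "E")
  }
  lines <- c(
    "# PSIPRED-style secondary structure",
    "",
    sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
      x$residue, x$aa, x$state, x$p_coil, x$p_helix, x$p_strand)
  )
  writeLines(lines, path)
  invisible(path)
}

DOMAIN_SOURCES <- c("smart", "pfam", "ncbi_curated", "cdd")
EVIDENCE_KINDS <- c("mutation", "functional", "site")

read_interval_tsv <- function(path, what, key_col, allowed) {
  if (!file.exists(path)) validation_error("%s file '%s' does not exist", what, path)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(key_col, "start", "end")
  if (!all(need %in% names(x))) {
    validation_error("'%s': required columns %s", path, paste(need, collapse = ", "))
  }
  bad <- which(!x[[key_col]] %in% allowed)
  if (length(bad) > 0L) {
    validation_error("'%s' line %d: unknown %s '%s'", path, bad[1L] + 1L,
      key_col, x[[key_col]][bad[1L]])
  }
  bad <- which(!(x$start >= 1 & x$start <= x$end))
  if (length(bad) > 0L) {
    validation_error("'%s' line %d: invalid interval [%s, %s]", path, bad[1L] + 1L,
      x$start[bad[1L]], x$end[bad[1L]])
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_tibble(x)
}

#' Read conserved-domain annotations
#'
#' Tab-separated with header columns `source` (one of smart, pfam,
#' ncbi_curated, cdd), `name`, `start`, `end` (1-based inclusive), in the
#' style of a CD-search concise report export.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble of domain intervals.
#' @export
read_domains <- function(path) {
  read_interval_tsv(path, "domain", "source", DOMAIN_SOURCES)
}

#' Read experimental NES evidence annotations
#'
#' Tab-separated with header columns `kind` (mutation, functional or site),
#' `start`, `end` (1-based inclusive).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble of evidence intervals.
#' @export
read_evidence <- function(path) {
  read_interval_tsv(path, "evidence", "kind", EVIDENCE_KINDS)
}

#' Write domain or evidence intervals as TSV
#'
#' @param x Tibble of intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
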
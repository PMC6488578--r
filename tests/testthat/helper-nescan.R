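# Shared test helpers.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent brute-force consensus oracle. Class templates are written out
# explicitly (0-based Phi offsets from the anchor, restricted spacer offsets,
# Pro-requirement offsets), and every anchor is checked by direct set
# membership — no code shared with the scanner.
oracle_defs <- list(
  list(id = "1a", dir = "forward", off = c(0, 4, 7, 9), nopw = c(5, 6, 8),
    pro = integer(0), bulky = FALSE),
  list(id = "1b", dir = "forward", off = c(0, 3, 6, 8), nopw = c(4, 5, 7),
    pro = integer(0), bulky = FALSE),
  list(id = "1c", dir = "forward", off = c(0, 4, 8, 10), nopw = c(5, 6, 7, 9),
    pro = integer(0), bulky = FALSE),
  list(id = "1d", dir = "forward", off = c(0, 3, 7, 9), nopw = c(4, 5, 6, 8),
    pro = integer(0), bulky = FALSE),
  list(id = "2", dir = "forward", off = c(0, 2, 5, 7), nopw = c(3, 4, 6),
    pro = integer(0), bulky = FALSE),
  list(id = "3", dir = "forward", off = c(0, 3, 7, 10), nopw = c(5, 6, 8, 9),
    pro = integer(0), bulky = FALSE),
  list(id = "4", dir = "forward", off = c(0, 4, 7, 11), nopw = c(5, 6),
    pro = c(8, 9, 10), bulky = FALSE),
  list(id = "1a-R", dir = "reverse", off = c(0, 4, 7, 9), nopw = c(5, 6, 8),
    pro = integer(0), bulky = TRUE),
  list(id = "1c-R", dir = "reverse", off = c(0, 4, 8, 10), nopw = c(5, 6, 7, 9),
    pro = integer(0), bulky = TRUE)
)

oracle_scan <- function(sequence) {
  phi <- c("L", "I", "V", "M", "F")
  ta <- c("T", "A")
  bulky <- c("L", "F", "M")
  nopw_ok <- setdiff(AA20, c("P", "W"))
  fwd <- strsplit(sequence, "")[[1]]
  L <- length(fwd)
  hits <- list()
  for (d in oracle_defs) {
    chars <- if (d$dir == "reverse") rev(fwd) else fwd
    span <- max(d$off)
    i <- 0L
    while (i < L - span) {
      i <- i + 1L
      p <- chars[i + d$off]
      # Phi3/Phi4 strictly hydrophobic; one T/A allowed at Phi1 or Phi2
      if (!(p[3] %in% phi) || !(p[4] %in% phi)) next
      ta_used <- NA
      if (p[1] %in% phi && p[2] %in% phi) ta_used <- FALSE
      if (p[1] %in% ta && p[2] %in% phi) ta_used <- TRUE
      if (p[1] %in% phi && p[2] %in% ta) ta_used <- TRUE
      if (is.na(ta_used)) next
      if (!all(chars[i + d$nopw] %in% nopw_ok)) next
      if (length(d$pro) > 0 && !("P" %in% chars[i + d$pro])) next
      if (d$bulky) {
        cand <- chars[i]
        if (i - 3 >= 1) cand <- c(cand, chars[i - 3])
        if (!any(cand %in% bulky)) next
      }
      pos <- i + d$off
      if (d$dir == "reverse") pos <- L - pos + 1L
      hits[[length(hits) + 1L]] <- tibble::tibble(
        class_id = d$id, direction = d$dir,
        phi1 = pos[1], phi2 = pos[2], phi3 = pos[3], phi4 = pos[4],
        ta_used = ta_used)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(class_id = character(), direction = character(),
      phi1 = integer(), phi2 = integer(), phi3 = integer(), phi4 = integer(),
      ta_used = logical()))
  }
  dplyr::arrange(out, class_id, direction, phi1, ta_used)
}

scan_key <- function(m) {
  dplyr::arrange(
    m[, c("class_id", "direction", "phi1", "phi2", "phi3", "phi4", "ta_used")],
    class_id, direction, phi1, ta_used)
}

# Sorted annotated registry (Phi0 when hydrophobic/annotated + Phi1..Phi4)
# of a match row, in local (window-relative? no: sequence) coordinates.
match_registry <- function(row, with_phi0 = TRUE) {
  pos <- c(row$phi1, row$phi2, row$phi3, row$phi4)
  if (with_phi0 && !is.na(row$phi0)) pos <- c(pos, row$phi0)
  sort(pos)
}

# A clean class-1a match plus its extraction window, for threading tests.
ideal_1a <- function() {
  seqs <- tibble::tibble(id = "p", sequence = "SSLSSSLSSLSLSS")
  m <- nes_scan(seqs)
  m <- m[m$class_id == "1a", ]
  list(match = m, window = m$seg_seq[[1]])
}

tiny_templates <- function() {
  tpl <- gen_toy_templates(1L)
  tpl[c("1a.1", "1b")]
}

det_config <- function(...) {
  defaults <- list(n_models = 1L, n_trials = 0L, n_parents = 1L,
    n_relax = 1L, n_steps = 0L, k_lowest = 1L, n_runs = 1L)
  do.call(nes_sampling_config, utils::modifyList(defaults, list(...)))
}

# Uniform per-residue tracks for context tests.
flat_track <- function(sequence, value, predictor = "disopred") {
  chars <- strsplit(sequence, "")[[1]]
  out <- tibble::tibble(residue = seq_along(chars), aa = chars,
    propensity = rep(value, length(chars)))
  attr(out, "predictor") <- predictor
  out
}
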
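#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange bind_rows group_by ungroup
NULL

# Amino-acid alphabet accepted in sequences ('X' = unknown residue).
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

# Hydrophobic registry residues allowed at the Phi1..Phi4 positions.
PHI_SET <- c("L", "I", "V", "M", "F")

# Spacer positions between Phi2 and Phi4 exclude Pro and Trp.
NO_PW_SET <- setdiff(setdiff(AA_ALPHABET, "X"), c("P", "W"))

# Kyte-Doolittle hydropathy, used by the surrogate pocket/exposure terms.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)
AA1 <- stats::setNames(names(AA3), AA3)

validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nescan_validation_error")
}

assert_sequence <- function(sequence, id = "<sequence>") {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 1L) {
    validation_error("record '%s': sequence must be a non-empty string", id)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    validation_error(
      "record '%s': illegal residue '%s' at position %d",
      id, chars[bad[1L]], bad[1L]
    )
  }
  invisible(sequence)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729 + 12347) %%
    2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
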
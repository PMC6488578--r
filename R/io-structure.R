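BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a CRM1-NES template structure from a PDB file
#'
#' Produces a coarse-grained per-residue representation: the four backbone
#' atom positions plus a side-chain centroid (mean of side-chain heavy atoms;
#' falls back to CA for glycine or when no side-chain atoms are present).
#' Only single-model files are accepted and the first alternate location is
#' kept. The CRM1 chain is truncated to the configured residue window.
#'
#' @param path Path to a PDB file.
#' @param chain_map Named list or vector with entries `groove` (the CRM1
#'   chain id) and `peptide` (the NES peptide chain id). Either may be
#'   omitted to read a single chain.
#' @param crm1_window Integer length-2: residue window kept for the groove
#'   chain (default `c(479, 655)`, scCRM1 numbering).
#' @return A tibble of class `nes_coords`, one row per residue, with columns
#'   `role`, `chain`, `resno`, `aa` and coordinate columns
#'   `n_x..o_z` (backbone) and `sc_x..sc_z` (side-chain centroid), in
#'   Angstroms. Residues missing a backbone atom are dropped with a warning.
#' @export
read_structure <- function(path, chain_map, crm1_window = c(479L, 655L)) {
  if (!file.exists(path)) validation_error("PDB file '%s' does not exist", path)
  n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (n_models > 1L) {
    validation_error("'%s': multi-model PDB files are not supported", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  out <- list()
  for (role in intersect(c("groove", "peptide"), names(chain_map))) {
    ch <- chain_map[[role]]
    ca <- at[at$chain == ch, , drop = FALSE]
    if (nrow(ca) == 0L) validation_error("'%s': chain '%s' is empty", path, ch)
    if (role == "groove") {
      ca <- ca[ca$resno >= crm1_window[[1L]] & ca$resno <= crm1_window[[2L]], , drop = FALSE]
      if (nrow(ca) == 0L) {
        validation_error("'%s': chain '%s' has no residues in window %d-%d",
          path, ch, crm1_window[[1L]], crm1_window[[2L]])
      }
    }
    out[[role]] <- residues_from_atoms(ca, role, ch, path)
  }
  res <- bind_rows(out)
  class(res) <- c("nes_coords", class(res))
  res
}

residues_from_atoms <- function(at, role, chain, path) {
  resnos <- unique(at$resno)
  rows <- vector("list", length(resnos))
  dropped <- 0L
  for (i in seq_along(resnos)) {
    r <- at[at$resno == resnos[[i]], , drop = FALSE]
    bb <- lapply(BACKBONE_ATOMS, function(a) {
      j <- which(r$elety == a)
      if (length(j) == 0L) NULL else as.numeric(r[j[1L], c("x", "y", "z")])
    })
    names(bb) <- BACKBONE_ATOMS
    if (any(vapply(bb, is.null, logical(1L)))) {
      dropped <- dropped + 1L
      next
    }
    sc_rows <- r[!r$elety %in% BACKBONE_ATOMS & !grepl("^H", r$elety), , drop = FALSE]
    sc <- if (nrow(sc_rows) == 0L) bb$CA else
      unname(colMeans(sc_rows[, c("x", "y", "z")]))
    aa <- AA1[[r$resid[[1L]]]] %||% "X"
    rows[[i]] <- tibble(
      role = role, chain = chain, resno = resnos[[i]], aa = aa,
      n_x = bb$N[1], n_y = bb$N[2], n_z = bb$N[3],
      ca_x = bb$CA[1], ca_y = bb$CA[2], ca_z = bb$CA[3],
      c_x = bb$C[1], c_y = bb$C[2], c_z = bb$C[3],
      o_x = bb$O[1], o_y = bb$O[2], o_z = bb$O[3],
      sc_x = sc[1], sc_y = sc[2], sc_z = sc[3]
    )
  }
  if (dropped > 0L) {
    warn(sprintf("'%s' chain %s: dropped %d residue(s) with missing backbone atoms",
      path, chain, dropped))
  }
  res <- bind_rows(rows)
  if (!all(diff(res$resno) > 0)) {
    validation_error("'%s' chain %s: residue numbers not strictly increasing", path, chain)
  }
  res
}

#' Write a coarse-grained coordinate set as a PDB file
#'
#' Backbone atoms are written as N/CA/C/O and the side-chain centroid as a
#' CB pseudo-atom (omitted for glycine, whose centroid is the CA position),
#' so that [read_structure()] round-trips the representation.
#'
#' @param coords An `nes_coords` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(coords, path) {
  xyz <- c(); elety <- c(); resno <- c(); resid <- c(); chain <- c()
  for (i in seq_len(nrow(coords))) {
    r <- coords[i, ]
    ats <- list(
      N = c(r$n_x, r$n_y, r$n_z), CA = c(r$ca_x, r$ca_y, r$ca_z),
      C = c(r$c_x, r$c_y, r$c_z), O = c(r$o_x, r$o_y, r$o_z)
    )
    if (r$aa != "G") ats$CB <- c(r$sc_x, r$sc_y, r$sc_z)
    for (a in names(ats)) {
      xyz <- c(xyz, ats[[a]])
      elety <- c(elety, a)
      resno <- c(resno, r$resno)
      resid <- c(resid, AA3[[r$aa]])
      chain <- c(chain, r$chain)
    }
  }
  bio3d::write.pdb(
    file = path, xyz = xyz, elety = elety, resno = resno,
    resid = resid, chain = chain, o = rep(1, length(elety)),
    b = rep(0, length(elety))
  )
  invisible(path)
}
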
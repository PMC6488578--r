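# Rolling-probe accessible surface on the coarse atom set.

CA_RADIUS <- 1.9

sc_radius <- function(aa) {
  off <- SC_OFFSET[aa]
  1.5 + 0.35 * off
}

# Deterministic Fibonacci lattice on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley style accessible surface area
#'
#' Rolls a probe over each atom sphere by testing deterministic lattice
#' points on the expanded (atom + probe) sphere against all neighbouring
#' expanded spheres. For a single isolated atom the result is exactly the
#' analytic sphere area `4 * pi * (r + probe)^2`.
#'
#' @param centers `n x 3` matrix of atom centers (Angstroms).
#' @param radii Atom radii (length n).
#' @param probe Probe radius (default 1.4 Angstroms).
#' @param n_points Lattice points per atom (default 128).
#' @return A list with `area` (accessible area per atom) and `fraction`
#'   (accessible fraction of each atom's expanded sphere).
#' @export
shrake_rupley <- function(centers, radii, probe = 1.4, n_points = 128L) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(length(radii) == n)
  pts <- fibonacci_sphere(n_points)
  rexp <- radii + probe
  frac <- numeric(n)
  d2 <- cross_dist2(centers, centers)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rexp[i] + rexp)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      frac[i] <- 1
      next
    }
    surf <- sweep(pts * rexp[i], 2L, centers[i, ], `+`)
    covered <- rep(FALSE, n_points)
    for (j in nb) {
      dd <- surf - matrix(centers[j, ], n_points, 3L, byrow = TRUE)
      covered <- covered | rowSums(dd^2) < rexp[j]^2
      if (all(covered)) break
    }
    frac[i] <- mean(!covered)
  }
  list(area = frac * 4 * pi * rexp^2, fraction = frac)
}

model_atoms <- function(model) {
  m <- length(model$seq_chars)
  at <- list(); res <- integer(); role <- character()
  if (model$has_groove) {
    g <- model$template$groove
    ng <- nrow(g)
    at[[1L]] <- model$template$groove_ca
    at[[2L]] <- model$template$groove_sc
    res <- c(res, seq_len(ng), seq_len(ng))
    role <- c(role, rep("groove", 2L * ng))
  }
  if (m > 0L) {
    at[[length(at) + 1L]] <- model$pep_ca
    at[[length(at) + 1L]] <- model$pep_sc
    res <- c(res, 10000L + seq_len(m), 10000L + seq_len(m))
    role <- c(role, rep("peptide", 2L * m))
  }
  centers <- do.call(rbind, at)
  radii <- numeric(nrow(centers))
  is_ca <- c(
    if (model$has_groove) rep(c(TRUE, FALSE), each = nrow(model$template$groove)),
    if (m > 0L) rep(c(TRUE, FALSE), each = m)
  )
  aa <- c(
    if (model$has_groove) rep(model$template$groove$aa, 2L),
    if (m > 0L) rep(model$seq_chars, 2L)
  )
  radii[is_ca] <- CA_RADIUS
  radii[!is_ca] <- sc_radius(aa[!is_ca])
  list(centers = centers, radii = radii, res = res, role = role, is_ca = is_ca)
}

#' Interface solvent accessibility of a complex model
#'
#' Computes the rolling-probe accessible-surface fraction of each interface
#' residue's side-chain centroid sphere (accessible area over its isolated
#' area) and returns their sum — a dimensionless cavity measure: near 0
#' for a snugly buried peptide, rising as interface side chains lose
#' contact. Side-chain (not backbone) accessibility is used because the
#' cavities being penalized form around under-filled hydrophobic pockets.
#' The default interface is the peptide's registry Phi residues plus the
#' groove residues within `groove_cutoff` of any pocket centroid.
#'
#' @param model A complex `nes_model` (groove + peptide).
#' @param interface `"default"`, `"peptide_phi"` (peptide Phi residues
#'   only) or `"groove"`.
#' @param probe Probe radius (default 1.4 Angstroms).
#' @param n_points Lattice points per atom (default 128).
#' @param groove_cutoff Pocket-to-CA distance defining groove interface
#'   residues (default 6 Angstroms).
#' @return Scalar summed accessibility fraction.
#' @export
interface_rsa <- function(model, interface = c("default", "peptide_phi", "groove"),
                          probe = 1.4, n_points = 128L, groove_cutoff = 6.0) {
  interface <- match.arg(interface)
  if (!model$has_groove) validation_error("model has no groove chain")
  atoms <- model_atoms(model)
  sr <- shrake_rupley(atoms$centers, atoms$radii, probe, n_points)
  rexp2 <- 4 * pi * (atoms$radii + probe)^2
  sel_res <- integer()
  if (interface %in% c("default", "peptide_phi")) {
    phi <- which(!is.na(model$pocket))
    sel_res <- c(sel_res, 10000L + phi)
  }
  if (interface %in% c("default", "groove")) {
    d2 <- cross_dist2(model$template$groove_ca, model$template$pockets)
    near <- which(apply(d2, 1L, min) < groove_cutoff^2)
    sel_res <- c(sel_res, near)
  }
  sel_res <- unique(sel_res)
  if (length(sel_res) == 0L) validation_error("interface residue set is empty")
  total <- 0
  for (rr in sel_res) {
    idx <- which(atoms$res == rr & !atoms$is_ca)
    total <- total + sum(sr$area[idx]) / sum(rexp2[idx])
  }
  total
}
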
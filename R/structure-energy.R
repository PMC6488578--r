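# Squared cross-distances between two n x 3 coordinate matrices.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

#' The coarse-grained surrogate energy backend
#'
#' A pluggable energy backend evaluates a complex, groove-only or
#' free-peptide model and returns a scalar (lower = more stable); it must be
#' a pure function of the coordinates. The shipped surrogate combines four
#' terms chosen to reproduce the qualitative physics of NES recognition at
#' the CRM1 groove:
#'
#' * pocket term: for each registry Phi slot, `-w_pocket * hydropathy(aa) *
#'   exp(-(d/sigma)^2)` with `d` the side-chain-centroid-to-pocket distance —
#'   burying a hydrophobic side chain in its pocket is rewarded, a polar one
#'   penalized;
#' * clash term: soft quadratic repulsion for peptide-groove atom pairs
#'   below `d0_groove` and non-bonded intra-peptide pairs below `d0_intra`;
#' * exposure term: penalty for hydrophobic peptide residues whose side
#'   chain is far from every pocket (solvent-exposed grease);
#' * strain term: harmonic deviation of the peptide CA trace from the
#'   template anchors.
#'
#' @param w_pocket,sigma_pocket Pocket reward weight and range (default 2,
#'   2.5 Angstroms).
#' @param k_clash,d0_groove,d0_intra Clash force constant and contact
#'   distances (default 1, 2.8, 2.3 Angstroms).
#' @param w_exposure,exposure_onset,exposure_cap Exposure penalty weight,
#'   onset distance and cap (default 0.5, 4 Angstroms, 2).
#' @param k_strain Strain force constant (default 0.5 per square Angstrom).
#' @param h_min Minimum hydropathy for the exposure penalty (default 1).
#' @return A backend object (list with `name`, `deterministic` and
#'   `evaluate(model)`).
#' @export
surrogate_backend <- function(w_pocket = 2.0, sigma_pocket = 2.5,
                              k_clash = 1.0, d0_groove = 2.8, d0_intra = 2.3,
                              w_exposure = 0.5, exposure_onset = 4.0,
                              exposure_cap = 2.0, k_strain = 0.5,
                              h_min = 1.0) {
  force(w_pocket)
  evaluate <- function(model) {
    e <- 0
    m <- length(model$seq_chars)
    if (m > 0L) {
      h <- KD_HYDROPATHY[model$seq_chars]
      if (model$has_groove) {
        phi <- which(!is.na(model$pocket))
        if (length(phi) > 0L) {
          pk <- model$template$pockets[model$pocket[phi] + 1L, , drop = FALSE]
          d <- sqrt(rowSums((model$pep_sc[phi, , drop = FALSE] - pk)^2))
          e <- e - w_pocket * sum(h[phi] * exp(-(d / sigma_pocket)^2))
        }
        pep_atoms <- rbind(model$pep_ca, model$pep_sc)
        gr_atoms <- rbind(model$template$groove_ca, model$template$groove_sc)
        d2 <- cross_dist2(pep_atoms, gr_atoms)
        viol <- d0_groove - sqrt(d2[d2 < d0_groove^2])
        if (length(viol) > 0L) e <- e + k_clash * sum(viol^2)
        hyd <- which(h >= h_min)
        if (length(hyd) > 0L) {
          dmin <- sqrt(apply(
            cross_dist2(model$pep_sc[hyd, , drop = FALSE], model$template$pockets),
            1L, min))
          e <- e + w_exposure * sum(h[hyd] *
            pmin(exposure_cap, pmax(0, dmin - exposure_onset) / exposure_onset))
        }
      }
      if (m > 2L) {
        atoms <- rbind(model$pep_ca, model$pep_sc)
        res <- rep(seq_len(m), 2L)
        d2 <- cross_dist2(atoms, atoms)
        sep <- abs(outer(res, res, `-`))
        hit <- d2 < d0_intra^2 & sep >= 2L & upper.tri(d2)
        if (any(hit)) e <- e + k_clash * sum((d0_intra - sqrt(d2[hit]))^2)
      }
      e <- e + k_strain * sum((model$pep_ca - model$anchors)^2)
    }
    e
  }
  structure(
    list(name = "cg-surrogate", deterministic = TRUE, evaluate = evaluate),
    class = "nes_backend"
  )
}

#' Default energy backend
#'
#' @return The surrogate backend with default parameters.
#' @export
default_backend <- function() surrogate_backend()

#' A constant energy backend (testing/degenerate use)
#'
#' @param value The constant energy returned for every model.
#' @return A backend object.
#' @export
constant_backend <- function(value = 0) {
  structure(
    list(name = "constant", deterministic = TRUE,
      evaluate = function(model) value),
    class = "nes_backend"
  )
}

#' Scale a backend's energies by a positive factor
#'
#' @param backend A backend object.
#' @param lambda Positive scale factor.
#' @return A backend whose energies are `lambda` times the original.
#' @export
scaled_backend <- function(backend, lambda) {
  stopifnot(lambda > 0)
  structure(
    list(name = paste0(backend$name, "*", lambda),
      deterministic = backend$deterministic,
      evaluate = function(model) lambda * backend$evaluate(model)),
    class = "nes_backend"
  )
}
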
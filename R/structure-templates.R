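# Coarse-grained CRM1-groove templates.
#
# A template holds the groove fragment (CA + side-chain-centroid pseudo-atoms),
# the five hydrophobic pocket centroids P0-P4, and per-registry-slot peptide
# backbone anchors stored in N->C order. Registry slots run from one residue
# before Phi0 to two residues after Phi4; for reverse-binding templates the
# N->C slot order is the mirror of the binding order.

# Side-chain centroid offset from CA (Angstroms), roughly residue size.
SC_OFFSET <- c(
  G = 0, A = 0.8, S = 1.2, C = 1.2, T = 1.2, V = 1.2, P = 1.2,
  I = 1.6, L = 1.6, N = 1.6, D = 1.6,
  M = 1.9, E = 1.9, Q = 1.9, K = 1.9, H = 1.9,
  F = 2.2, R = 2.2, Y = 2.2, W = 2.2, X = 1.2
)

POCKET_SPACING <- 5.0
PHI_ANCHOR_Z <- 1.8

# Registry slots from one residue before Phi0 to two residues after Phi4,
# in binding order; pocket column gives the P0-P4 assignment of Phi slots.
build_registry <- function(class_id, phi0_offset = 3L) {
  spec <- class_slot_table()[[class_id]]
  if (is.null(spec)) validation_error("no slot template for class '%s'", class_id)
  codes <- spec$codes
  slot <- c("pre1", "phi0", paste0("s0_", seq_len(phi0_offset - 1L)))
  pocket <- c(NA_integer_, 0L, rep(NA_integer_, phi0_offset - 1L))
  phi_i <- 0L
  for (j in seq_along(codes)) {
    if (codes[[j]] == "phi") {
      phi_i <- phi_i + 1L
      slot <- c(slot, paste0("phi", phi_i))
      pocket <- c(pocket, phi_i)
    } else {
      slot <- c(slot, sprintf("sp%d_%d", phi_i, j))
      pocket <- c(pocket, NA_integer_)
    }
  }
  slot <- c(slot, "post1", "post2")
  pocket <- c(pocket, NA_integer_, NA_integer_)
  tibble(slot = slot, pocket = pocket)
}

toy_pockets <- function() {
  p <- cbind(
    x = POCKET_SPACING * 0:4,
    y = rep(0, 5L),
    z = rep(-0.2, 5L)
  )
  rownames(p) <- paste0("P", 0:4)
  p
}

# Idealized groove: two CA rails flanking the pocket line, an occluding ring
# of pseudo-atoms around each pocket mouth, and a floor atom beneath each
# pocket, so pocket-bound side chains are genuinely solvent-occluded.
toy_groove <- function(seed = 1L) {
  set.seed(derive_seed(seed, 7L))
  rail_x <- seq(-6, 26, by = 2)
  pts <- rbind(
    cbind(rail_x, 4.6, -1.5),
    cbind(rail_x, -4.6, -1.5)
  )
  pk <- toy_pockets()
  for (k in 1:5) {
    ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
    ring <- cbind(pk[k, 1] + 3.0 * cos(ang), pk[k, 2] + 3.0 * sin(ang),
      pk[k, 3] + 0.6)
    pts <- rbind(pts, ring, c(pk[k, 1], pk[k, 2], pk[k, 3] - 3.0))
  }
  n <- nrow(pts)
  aa <- sample(c("L", "I", "V", "A", "S", "T", "F", "K", "E"), n, replace = TRUE)
  tibble(
    role = "groove", chain = "A", resno = 478L + seq_len(n), aa = aa,
    ca_x = pts[, 1], ca_y = pts[, 2], ca_z = pts[, 3],
    sc_x = pts[, 1], sc_y = pts[, 2] * 0.92, sc_z = pts[, 3] + 0.3
  )
}

anchor_positions <- function(registry, y_off, z_off) {
  n <- nrow(registry)
  x <- numeric(n); y <- rep(y_off, n); z <- rep(z_off, n)
  phi_idx <- which(!is.na(registry$pocket))
  x[phi_idx] <- POCKET_SPACING * registry$pocket[phi_idx]
  y[phi_idx] <- 0; z[phi_idx] <- PHI_ANCHOR_Z
  # spacers between pinned slots: interpolate x; outside: extrapolate at 2.2 A
  pins <- phi_idx
  for (j in seq_len(n)) {
    if (j %in% pins) next
    lo <- pins[pins < j]; hi <- pins[pins > j]
    if (length(lo) > 0L && length(hi) > 0L) {
      a <- max(lo); b <- min(hi)
      x[j] <- x[a] + (x[b] - x[a]) * (j - a) / (b - a)
    } else if (length(hi) > 0L) {
      b <- min(hi)
      x[j] <- x[b] - 2.2 * (b - j)
    } else {
      a <- max(lo)
      x[j] <- x[a] + 2.2 * (j - a)
    }
  }
  cbind(x = x, y = y, z = z)
}

new_template <- function(template_id, class_id, direction, provenance,
                         registry, anchors, groove, pockets) {
  if (direction == "reverse") {
    registry <- registry[rev(seq_len(nrow(registry))), ]
    anchors <- anchors[rev(seq_len(nrow(anchors))), , drop = FALSE]
  }
  structure(
    list(
      template_id = template_id, class_id = class_id, direction = direction,
      provenance = provenance, registry = registry, anchors = anchors,
      groove = groove,
      groove_ca = as.matrix(groove[, c("ca_x", "ca_y", "ca_z")]),
      groove_sc = as.matrix(groove[, c("sc_x", "sc_y", "sc_z")]),
      pockets = pockets
    ),
    class = "nes_template"
  )
}

#' Generate the synthetic CRM1-groove template library
#'
#' Builds an idealized groove (five pocket centroids along the groove axis,
#' flanking rails and pocket-mouth occluders) and one peptide-backbone anchor
#' set per template class, with class-specific registry spacing and a
#' distinct spacer-arc placement per template so templates are geometrically
#' distinguishable. Covers the classes with solved CRM1 complex structures:
#' 1a (two templates), 1b, 1c, 2, a reverse-bound class-2 type, 4 and 1a-R;
#' class-3 queries are fitted with the class-1a templates.
#'
#' @param seed Integer seed (groove residue identities).
#' @return A named list of `nes_template` objects (class `nes_template_library`).
#' @export
gen_toy_templates <- function(seed = 1L) {
  groove <- toy_groove(seed)
  pockets <- toy_pockets()
  specs <- list(
    list(id = "1a.1", class = "1a", dir = "forward", y = -4.5, z = 3.0),
    list(id = "1a.2", class = "1a", dir = "forward", y = -3.0, z = 6.0),
    list(id = "1b", class = "1b", dir = "forward", y = -1.5, z = 3.0),
    list(id = "1c", class = "1c", dir = "forward", y = 0.0, z = 6.0),
    list(id = "2", class = "2", dir = "forward", y = 1.5, z = 3.0),
    list(id = "2-R", class = "2", dir = "reverse", y = 3.0, z = 6.0),
    list(id = "4", class = "4", dir = "forward", y = 4.5, z = 3.0),
    list(id = "1a-R", class = "1a", dir = "reverse", y = 6.0, z = 6.0)
  )
  out <- lapply(specs, function(s) {
    reg <- build_registry(s$class)
    anc <- anchor_positions(reg, s$y, s$z)
    new_template(s$id, s$class, s$dir, "synthetic", reg, anc, groove, pockets)
  })
  names(out) <- vapply(out, `[[`, character(1L), "template_id")
  structure(out, class = "nes_template_library")
}

TEMPLATE_REQUIRED_CLASSES <- c("1a", "1b", "1c", "2", "4")

#' Build the CRM1 template library
#'
#' Either generates the synthetic library ([gen_toy_templates()]) or reads a
#' directory of PDB template files described by a tab-separated manifest
#' (`manifest.tsv`) with columns `template_id`, `class_id`, `direction`,
#' `pdb_file`, `groove_chain`, `peptide_chain`, `phi1_resno`. Pocket
#' centroids are taken from the template peptide's own Phi side-chain
#' centroids; anchors from its backbone.
#'
#' @param source `"synthetic"` or a directory path containing the manifest.
#' @param seed Seed for the synthetic source.
#' @return An `nes_template_library`.
#' @export
build_template_library <- function(source = "synthetic", seed = 1L) {
  if (identical(source, "synthetic")) {
    return(gen_toy_templates(seed))
  }
  manifest_path <- file.path(source, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    validation_error("template manifest '%s' not found", manifest_path)
  }
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE, progress = FALSE)
  need <- c("template_id", "class_id", "direction", "pdb_file",
    "groove_chain", "peptide_chain", "phi1_resno")
  if (!all(need %in% names(man))) {
    validation_error("manifest requires columns: %s", paste(need, collapse = ", "))
  }
  missing_cls <- setdiff(TEMPLATE_REQUIRED_CLASSES, man$class_id)
  if (length(missing_cls) > 0L) {
    validation_error("manifest missing template class(es): %s",
      paste(missing_cls, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(man)), function(i) {
    template_from_pdb(
      file.path(source, man$pdb_file[[i]]), man$template_id[[i]],
      man$class_id[[i]], man$direction[[i]], man$groove_chain[[i]],
      man$peptide_chain[[i]], man$phi1_resno[[i]]
    )
  })
  names(out) <- man$template_id
  structure(out, class = "nes_template_library")
}

template_from_pdb <- function(path, template_id, class_id, direction,
                              groove_chain, peptide_chain, phi1_resno) {
  coords <- read_structure(path,
    chain_map = list(groove = groove_chain, peptide = peptide_chain))
  pep <- coords[coords$role == "peptide", , drop = FALSE]
  groove <- coords[coords$role == "groove", , drop = FALSE]
  if (nrow(pep) == 0L) validation_error("'%s': peptide chain '%s' missing", path, peptide_chain)
  reg <- build_registry(class_id)
  # slots in binding order map to consecutive peptide residues around phi1
  phi1_slot <- which(reg$slot == "phi1")
  resnos <- phi1_resno + (seq_len(nrow(reg)) - phi1_slot)
  keep <- resnos %in% pep$resno
  reg <- reg[keep, , drop = FALSE]
  idx <- match(resnos[keep], pep$resno)
  anchors <- as.matrix(pep[idx, c("ca_x", "ca_y", "ca_z")])
  pockets <- matrix(NA_real_, 5L, 3L, dimnames = list(paste0("P", 0:4), NULL))
  for (j in which(!is.na(reg$pocket))) {
    pockets[reg$pocket[[j]] + 1L, ] <-
      as.numeric(pep[idx[[j]], c("sc_x", "sc_y", "sc_z")])
  }
  if (anyNA(pockets[2:5, ])) {
    validation_error("'%s': template peptide does not cover Phi1-Phi4", path)
  }
  if (anyNA(pockets[1L, ])) pockets[1L, ] <- 2 * pockets[2L, ] - pockets[3L, ]
  new_template(template_id, class_id, direction, basename(path),
    reg, anchors, groove, pockets)
}

#' @export
print.nes_template <- function(x, ...) {
  cat(sprintf("<nes_template %s> class %s (%s), %d registry slots, %d groove residues\n",
    x$template_id, x$class_id, x$direction, nrow(x$registry), nrow(x$groove)))
  invisible(x)
}

#' @export
print.nes_template_library <- function(x, ...) {
  cat(sprintf("<nes_template_library> %d templates: %s\n", length(x),
    paste(names(x), collapse = ", ")))
  invisible(x)
}
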
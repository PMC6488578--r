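# Synthetic data generation: proteins with planted NES motifs, matching
# disorder/SS/domain tracks, and labeled benchmark sets with synthetic K_D.
# Every generator is deterministic under its seed and emits ground truth.

SPACER_POOL <- c("S", "N", "Q", "E", "K", "R", "D", "G", "H")
PHI_BULKY <- c("L", "F", "M")

#' Specify one planted motif or decoy
#'
#' @param class_id Consensus class, with `-R` suffix for reverse binding
#'   (e.g. `"1a"`, `"1a-R"`).
#' @param position 1-based start of the planted window in the protein.
#' @param context Flanking context the track generator will build:
#'   `"disordered_tail"`, `"ordered_core"` or `"boundary"`.
#' @param phi_residues Optional length-4 character vector fixing the
#'   Phi1-Phi4 residues.
#' @param kind `"plant"` (true positive) or `"decoy"` (consensus-matching
#'   false positive).
#' @param decoy_type For decoys: `"ordered"` (buried in an ordered core) or
#'   `"beta"` (strand conformation over the middle).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(class_id, position,
                       context = c("disordered_tail", "ordered_core", "boundary"),
                       phi_residues = NULL, kind = c("plant", "decoy"),
                       decoy_type = c("ordered", "beta")) {
  context <- match.arg(context)
  kind <- match.arg(kind)
  decoy_type <- if (kind == "decoy") match.arg(decoy_type) else NA_character_
  if (!is.null(phi_residues) && length(phi_residues) != 4L) {
    validation_error("phi_residues must have length 4")
  }
  structure(
    list(class_id = class_id, position = as.integer(position),
      context = context, phi_residues = phi_residues, kind = kind,
      decoy_type = decoy_type),
    class = "plant_spec"
  )
}

parse_class <- function(class_id) {
  reverse <- grepl("-R$", class_id)
  list(base = sub("-R$", "", class_id),
    direction = if (reverse) "reverse" else "forward")
}

# Build a motif string satisfying its class spec exactly, spanning the full
# registry window pre1..post2. Uses the caller's RNG stream. `violation`
# degrades the motif: "ala" replaces Phi2/Phi3 with Ala, "pro" puts Pro in
# a restricted Phi2->Phi3 spacer ("ala" is substituted for class 4, whose
# Phi3->Phi4 spacer requires a Pro anyway). Phi0 is polar by default so the
# motif registers as exactly one class (a hydrophobic Phi0 three residues
# before a class-1a Phi1 always creates an additional class-3 registry).
build_motif <- function(class_id, phi_residues = NULL, violation = "none",
                        phi0_hydrophobic = FALSE) {
  cl <- parse_class(class_id)
  reg <- build_registry(cl$base)
  n <- nrow(reg)
  res <- sample(SPACER_POOL, n, replace = TRUE)
  phi_slots <- paste0("phi", 1:4)
  for (i in 1:4) {
    idx <- which(reg$slot == phi_slots[[i]])
    res[[idx]] <- if (!is.null(phi_residues)) phi_residues[[i]] else
      if (i == 1L) sample(PHI_BULKY, 1L) else sample(c("L", "I", "F", "M"), 1L)
  }
  res[[which(reg$slot == "phi0")]] <- if (phi0_hydrophobic)
    sample(PHI_SET, 1L) else sample(SPACER_POOL, 1L)
  if (cl$base == "4") {
    res[[grep("^sp3_", reg$slot)[[1L]]]] <- "P"
  }
  if (violation == "pro" && cl$base == "4") violation <- "ala"
  if (violation == "ala") {
    res[[which(reg$slot == "phi2")]] <- "A"
    res[[which(reg$slot == "phi3")]] <- "A"
  } else if (violation == "pro") {
    # target a restricted (no-PW) Phi2->Phi3 spacer slot; class 3's first
    # spacer slot is unrestricted, so a Pro there would not break the match
    codes <- class_slot_table()[[cl$base]]$codes
    frame <- which(reg$slot == "phi1") - 1L
    sp2 <- grep("^sp2_", reg$slot)
    sp2 <- sp2[codes[sp2 - frame] == "nopw"]
    if (length(sp2) == 0L) {
      validation_error("class %s has no restricted Phi2-Phi3 spacer", class_id)
    }
    res[[sp2[[1L]]]] <- "P"
  }
  phi_idx <- match(phi_slots, reg$slot)
  if (cl$direction == "reverse") {
    res <- rev(res)
    phi_idx <- n - phi_idx + 1L
  }
  list(seq = paste(res, collapse = ""), len = n,
    phi1 = phi_idx[[1L]], phi = sort(phi_idx),
    class_id = cl$base, direction = cl$direction)
}

# Disordered regions implied by plant contexts (used consistently by
# gen_protein's background composition and gen_tracks' propensity blocks).
disorder_regions <- function(truth, L, pad = 25L) {
  regs <- list()
  for (i in seq_len(nrow(truth))) {
    if (truth$context[[i]] == "disordered_tail") {
      regs[[length(regs) + 1L]] <-
        c(max(1L, truth$start[[i]] - pad), min(L, truth$end[[i]] + pad))
    } else if (truth$context[[i]] == "boundary") {
      mid <- (truth$start[[i]] + truth$end[[i]]) %/% 2L
      regs[[length(regs) + 1L]] <- c(mid, min(L, truth$end[[i]] + pad))
    }
  }
  regs
}

#' Generate a protein with planted motifs and ground truth
#'
#' Background residues are sampled near-uniformly with Phi-residue (and
#' Thr/Ala) frequencies damped, and hydrophobics excluded entirely from
#' disordered-context regions (mirroring the hydrophobic depletion of real
#' disordered tails), so planted windows dominate the consensus signal.
#' Planted motifs satisfy their class spec exactly.
#'
#' @param plant_specs List of [plant_spec()] objects (possibly empty).
#' @param length Protein length.
#' @param seed Integer seed.
#' @param id Sequence identifier (default `"synthetic_protein"`).
#' @return A list with `record` (tibble `id`, `sequence`) and `truth`
#'   (tibble: kind, class_id, direction, context, decoy_type, start, end,
#'   phi1, phi_positions).
#' @export
gen_protein <- function(plant_specs, length, seed = 1L, id = "synthetic_protein") {
  if (inherits(plant_specs, "plant_spec")) plant_specs <- list(plant_specs)
  set.seed(derive_seed(seed, 11L))
  motifs <- lapply(plant_specs, function(s)
    build_motif(s$class_id, s$phi_residues))
  starts <- vapply(plant_specs, `[[`, integer(1L), "position")
  ends <- starts + vapply(motifs, `[[`, integer(1L), "len") - 1L
  if (any(starts < 1L) || any(ends > length)) {
    validation_error("planted window falls outside the sequence")
  }
  if (length(starts) > 1L) {
    ord <- order(starts)
    if (any(starts[ord][-1L] <= ends[ord][-length(ends)])) {
      validation_error("overlapping planted windows")
    }
  }
  w <- rep(1, length(AA_ALPHABET) - 1L)
  names(w) <- setdiff(AA_ALPHABET, "X")
  w[PHI_SET] <- 0.15
  w[c("T", "A")] <- 0.3
  chars <- sample(names(w), length, replace = TRUE, prob = w)
  truth <- tibble(
    kind = vapply(plant_specs, `[[`, character(1L), "kind"),
    class_id = vapply(plant_specs, `[[`, character(1L), "class_id"),
    direction = vapply(motifs, `[[`, character(1L), "direction"),
    context = vapply(plant_specs, `[[`, character(1L), "context"),
    decoy_type = vapply(plant_specs, `[[`, character(1L), "decoy_type"),
    start = starts, end = ends,
    phi1 = starts + vapply(motifs, `[[`, integer(1L), "phi1") - 1L,
    phi_positions = vapply(seq_along(motifs), function(i)
      paste(starts[[i]] + motifs[[i]]$phi - 1L, collapse = ","), character(1L))
  )
  for (reg in disorder_regions(truth, length)) {
    span <- reg[[1L]]:reg[[2L]]
    chars[span] <- sample(c(SPACER_POOL, "P"), length(span), replace = TRUE)
  }
  for (i in seq_along(motifs)) {
    chars[starts[[i]]:ends[[i]]] <- seq_chars(motifs[[i]]$seq)
  }
  list(record = tibble(id = id, sequence = paste(chars, collapse = "")),
    truth = truth)
}

beta_track <- function(mu, conc_ordered = 100, conc_disordered = 10) {
  conc <- ifelse(mu < 0.1, conc_ordered, conc_disordered)
  stats::rbeta(length(mu), mu * conc, (1 - mu) * conc)
}

#' Generate disorder, secondary-structure and domain tracks
#'
#' Builds per-residue propensities from Beta distributions around a smooth
#' target profile: ~0.7 in the disordered regions implied by the ground
#' truth contexts, ~0.03 elsewhere (well below the 0.1 order cutoff), with a
#' 7-residue moving-average transition at block edges. Secondary structure
#' is helix over plant middles, strand over `"beta"`-decoy middles, coil
#' elsewhere. One domain row covers each ordered block of at least 50
#' residues.
#'
#' @param sequence Protein sequence string.
#' @param truth Ground-truth tibble from [gen_protein()].
#' @param seed Integer seed.
#' @return A list: `disopred`, `spotd`, `iup` (disorder-track tibbles),
#'   `ss` (ss2-style tibble), `domains` (domain tibble).
#' @export
gen_tracks <- function(sequence, truth, seed = 1L) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  mask <- rep(FALSE, L)
  for (reg in disorder_regions(truth, L)) mask[reg[[1L]]:reg[[2L]]] <- TRUE
  mu_raw <- ifelse(mask, 0.7, 0.03)
  mu <- as.numeric(stats::filter(mu_raw, rep(1 / 7, 7L), sides = 2L))
  mu[is.na(mu)] <- mu_raw[is.na(mu)]
  tracks <- lapply(1:3, function(t) {
    set.seed(derive_seed(seed, 20L + t))
    out <- tibble(residue = seq_len(L), aa = chars, propensity = beta_track(mu))
    attr(out, "predictor") <- c("disopred", "spotd", "iupred")[[t]]
    out
  })
  state <- rep("C", L)
  for (i in seq_len(nrow(truth))) {
    phis <- as.integer(strsplit(truth$phi_positions[[i]], ",")[[1L]])
    span <- min(phis):max(phis)
    if (truth$kind[[i]] == "plant") {
      state[span] <- "H"
    } else if (identical(truth$decoy_type[[i]], "beta")) {
      state[span] <- "E"
    }
  }
  ss <- tibble(
    residue = seq_len(L), aa = chars, state = state,
    confidence = 8L,
    p_coil = ifelse(state == "C", 0.9, 0.05),
    p_helix = ifelse(state == "H", 0.9, 0.05),
    p_strand = ifelse(state == "E", 0.9, 0.05)
  )
  r <- rle(!mask)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- which(r$values & r$lengths >= 50L)
  domains <- tibble(
    source = rep("pfam", length(keep)),
    name = sprintf("CORE%d", seq_along(keep)),
    start = starts[keep], end = stops[keep]
  )
  list(disopred = tracks[[1L]], spotd = tracks[[2L]], iup = tracks[[3L]],
    ss = ss, domains = domains)
}

#' Generate a labeled benchmark set with synthetic K_D values
#'
#' Binder peptides are built on-register for the template-covered classes;
#' non-binders degrade a fresh motif with Phi-to-Ala substitutions or a Pro
#' spacer violation (alternating). Every peptide gets a deterministic
#' reference energy `e_true` and interface accessibility `rsa_true` from the
#' threading pose (no stochastic sampling), and
#' `lnK_D = slope * (e_true + rsa_weight * rsa_true) + intercept +
#' Normal(0, noise)`. `kd_nM` is reported for binders only; `lnkd_true`
#' (the generator's ground truth) for all rows.
#'
#' @param n Number of peptides (>= 10).
#' @param noise Standard deviation of the lnK_D noise (default 0.6).
#' @param seed Integer seed.
#' @param binder_frac Fraction of binders (default 0.6).
#' @param slope,intercept Linear map from energy to lnK_D (default 0.5, 14).
#' @param rsa_weight Weight of `rsa_true` inside the generated lnK_D
#'   (default 0; set 0.35 to exercise the RSA-weight recovery).
#' @param templates Template library (default [gen_toy_templates()]).
#' @param backend Energy backend (default [default_backend()]).
#' @return A tibble: name, class, sequence, phi1, seg_start, binder,
#'   violation, e_true, rsa_true, lnkd_true, kd_nM.
#' @export
gen_benchmark <- function(n, noise = 0.6, seed = 1L, binder_frac = 0.6,
                          slope = 0.5, intercept = 14, rsa_weight = 0,
                          templates = NULL, backend = default_backend()) {
  if (n < 10L) validation_error("n must be at least 10")
  if (is.null(templates)) templates <- gen_toy_templates(1L)
  classes <- c("1a", "1b", "1c", "2", "3", "4", "1a-R")
  n_bind <- round(n * binder_frac)
  set.seed(derive_seed(seed, 31L))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    binder <- i <= n_bind
    violation <- if (binder) "none" else c("ala", "pro")[[(i %% 2L) + 1L]]
    mot <- build_motif(classes[[((i - 1L) %% length(classes)) + 1L]],
      violation = violation, phi0_hydrophobic = TRUE)
    rows[[i]] <- tibble(
      name = sprintf("pep%02d", i),
      class = if (mot$direction == "reverse")
        paste0(mot$class_id, "-R") else mot$class_id,
      sequence = mot$seq, phi1 = mot$phi1, seg_start = 1L,
      binder = binder, violation = violation
    )
  }
  out <- bind_rows(rows)
  eps <- stats::rnorm(n, 0, noise)
  det_config <- nes_sampling_config(n_models = 1L, n_trials = 0L,
    n_parents = 1L, n_relax = 1L, n_steps = 0L, k_lowest = 1L, n_runs = 1L)
  scored <- score_peptides(out, templates, backend, det_config, seed)
  out$e_true <- scored$e_bind_mean
  out$rsa_true <- scored$rsa
  out$lnkd_true <- slope * (out$e_true + rsa_weight * out$rsa_true) +
    intercept + eps
  out$kd_nM <- ifelse(out$binder, exp(out$lnkd_true), NA_real_)
  out
}

#' Score a table of peptides with the binding-energy protocol
#'
#' @param peptides Tibble with columns `sequence`, `phi1`, `seg_start`.
#' @param templates Template library.
#' @param backend Energy backend.
#' @param config Sampling configuration.
#' @param seed Integer seed (per-row sub-seeds are derived).
#' @return `peptides` with `e_bind_mean`, `rsa`, `e_bind_rsa`,
#'   `best_template` and `best_class` appended.
#' @export
score_peptides <- function(peptides, templates, backend = default_backend(),
                           config = fast_sampling_config(), seed = 1L) {
  n <- nrow(peptides)
  e <- numeric(n); rsa <- numeric(n); er <- numeric(n)
  bt <- character(n); bc <- character(n)
  for (i in seq_len(n)) {
    res <- e_bind(peptides$sequence[[i]],
      tibble(phi1 = peptides$phi1[[i]], seg_start = peptides$seg_start[[i]]),
      templates, backend, config, seed = derive_seed(seed, 700L + i))
    e[[i]] <- res$e_bind_mean
    rsa[[i]] <- res$rsa
    er[[i]] <- if (is.finite(res$e_bind_rsa)) res$e_bind_rsa else res$e_bind_mean
    bt[[i]] <- res$best_template
    bc[[i]] <- res$best_class
  }
  peptides$e_bind_mean <- e
  peptides$rsa <- rsa
  peptides$e_bind_rsa <- er
  peptides$best_template <- bt
  peptides$best_class <- bc
  peptides
}

#' The packaged demo layout: one true plant plus two decoys
#'
#' A length-300 protein with a class-1a motif planted in a disordered tail,
#' a class-1a decoy buried in the ordered core and a class-2 decoy whose
#' middle is strand.
#'
#' @return A list of [plant_spec()]s.
#' @export
demo_plant_specs <- function() {
  list(
    plant_spec("2", 60L, context = "ordered_core", kind = "decoy",
      decoy_type = "beta"),
    plant_spec("1a", 120L, context = "ordered_core", kind = "decoy",
      decoy_type = "ordered"),
    plant_spec("1a", 255L, context = "disordered_tail")
  )
}

#' Write a complete demo input bundle
#'
#' Generates the demo protein and tracks and writes every pipeline input to
#' `dir`: FASTA, the three disorder-track dialects, an ss2 file, domain and
#' evidence TSVs, the ground truth, and a YAML manifest.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of written paths, invisibly.
#' @export
simulate_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- gen_protein(demo_plant_specs(), 300L, seed = seed, id = "demo_protein")
  tr <- gen_tracks(gp$record$sequence, gp$truth, seed = seed)
  plant <- gp$truth[gp$truth$kind == "plant", ]
  evidence <- tibble(kind = "functional", start = plant$start, end = plant$end)
  p <- list(
    fasta = file.path(dir, "demo.fasta"),
    disopred = file.path(dir, "demo.diso"),
    spotd = file.path(dir, "demo.spotd"),
    iup = file.path(dir, "demo.iupred"),
    ss2 = file.path(dir, "demo.ss2"),
    domains = file.path(dir, "demo_domains.tsv"),
    evidence = file.path(dir, "demo_evidence.tsv"),
    truth = file.path(dir, "demo_truth.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_fasta(gp$record, p$fasta)
  write_disorder_track(tr$disopred, p$disopred, "disopred")
  write_disorder_track(tr$spotd, p$spotd, "spotd")
  write_disorder_track(tr$iup, p$iup, "iupred")
  write_ss2(tr$ss, p$ss2)
  write_intervals(tr$domains, p$domains)
  write_intervals(evidence, p$evidence)
  readr::write_tsv(gp$truth, p$truth, progress = FALSE)
  yaml::write_yaml(
    list(id = "demo_protein", seed = seed, length = 300L,
      files = lapply(p[setdiff(names(p), "manifest")], basename)),
    p$manifest)
  invisible(p)
}
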
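#' Sampling configuration for the binding-energy protocol
#'
#' Defaults mirror the ensemble bookkeeping of the modeling protocol
#' (50 Monte-Carlo models, 5 lowest-energy parents each relaxed 50 times,
#' lowest-10 averaging, 5 replicate runs) with the per-model trial count
#' scaled to desk size (2,000 trials; the protocol shape, not the trial
#' count, carries the signal at this resolution).
#'
#' @param n_models Independent Metropolis chains per ensemble (default 50).
#' @param n_trials Metropolis trials per chain (default 2000).
#' @param n_parents Lowest-energy models selected for relaxation (default 5).
#' @param n_relax Independent greedy-descent runs per parent (default 50).
#' @param n_steps Descent steps per relax run (default 25).
#' @param k_lowest Ensemble energies averaged (default 10).
#' @param n_runs Independent replicate runs of the whole protocol (default 5).
#' @param temperature Metropolis temperature in backend energy units
#'   (default 1).
#' @param sigma_bb,sigma_sc Proposal step sizes, backbone anchor and
#'   side-chain centroid (default 0.25 / 0.4 Angstroms).
#' @param relax_radius Constraint radius tethering relaxation to its start
#'   pose (default 1 Angstrom).
#' @param compute_rsa Whether `e_bind()` computes the interface RSA of the
#'   best model (default TRUE).
#' @param w_rsa RSA correction weight (default 0.35).
#' @return A named list of class `nes_sampling_config`.
#' @export
nes_sampling_config <- function(n_models = 50L, n_trials = 2000L,
                                n_parents = 5L, n_relax = 50L, n_steps = 25L,
                                k_lowest = 10L, n_runs = 5L, temperature = 1.0,
                                sigma_bb = 0.25, sigma_sc = 0.4,
                                relax_radius = 1.0, compute_rsa = TRUE,
                                w_rsa = 0.35) {
  structure(
    list(n_models = n_models, n_trials = n_trials, n_parents = n_parents,
      n_relax = n_relax, n_steps = n_steps, k_lowest = k_lowest,
      n_runs = n_runs, temperature = temperature, sigma_bb = sigma_bb,
      sigma_sc = sigma_sc, relax_radius = relax_radius,
      compute_rsa = compute_rsa, w_rsa = w_rsa),
    class = "nes_sampling_config"
  )
}

#' Fast sampling preset
#'
#' A reduced protocol (6 chains x 40 trials, 2 parents x 3 relax runs, one
#' replicate) for interactive exploration and the packaged examples; the
#' ensemble shape (sample, select, relax, lowest-k average) is unchanged.
#'
#' @param ... Overrides passed to [nes_sampling_config()].
#' @return An `nes_sampling_config`.
#' @export
fast_sampling_config <- function(...) {
  defaults <- list(n_models = 6L, n_trials = 40L, n_parents = 2L,
    n_relax = 3L, n_steps = 15L, k_lowest = 10L, n_runs = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(nes_sampling_config, args)
}

#' Thread a peptide window onto a template
#'
#' Places each window residue on the template backbone anchor of its
#' registry slot, aligning the window's Phi1 to the template's Phi1 slot
#' (N-to-C; for reverse-binding templates the slot order is mirrored, so a
#' forward window threads against the groove direction). Residues falling
#' outside the template registry are clipped. Side-chain centroids are
#' initialized along the CA-to-pocket direction for Phi slots and away from
#' the groove for spacers.
#'
#' @param peptide_seq The window sequence (N-to-C string).
#' @param match One-row match tibble (needs `phi1`, `seg_start`).
#' @param template An `nes_template`.
#' @return An `nes_model`.
#' @export
thread_peptide <- function(peptide_seq, match, template) {
  chars <- seq_chars(toupper(peptide_seq))
  w1 <- abs(match$phi1[[1L]] - match$seg_start[[1L]]) + 1L
  if (w1 < 1L || w1 > length(chars)) {
    validation_error("match Phi1 position falls outside the peptide window")
  }
  t1 <- which(template$registry$slot == "phi1")
  shift <- t1 - w1
  js <- seq_along(chars)
  slots <- js + shift
  keep <- slots >= 1L & slots <= nrow(template$registry)
  if (!keep[[w1]]) {
    validation_error("template '%s' has no anchor for the Phi1 slot",
      template$template_id)
  }
  js <- js[keep]; slots <- slots[keep]
  seq_chars_placed <- chars[js]
  pocket <- template$registry$pocket[slots]
  anchors <- template$anchors[slots, , drop = FALSE]
  pep_ca <- anchors
  pep_sc <- anchors
  for (i in seq_along(js)) {
    off <- SC_OFFSET[[seq_chars_placed[[i]]]]
    if (!is.na(pocket[[i]])) {
      v <- template$pockets[pocket[[i]] + 1L, ] - pep_ca[i, ]
      nv <- sqrt(sum(v^2))
      dirv <- if (nv > 1e-9) v / nv else c(0, 0, -1)
    } else {
      dirv <- c(0, 0, 1)
    }
    pep_sc[i, ] <- pep_ca[i, ] + off * dirv
  }
  structure(
    list(
      template = template, template_id = template$template_id,
      seq_chars = seq_chars_placed, slot_idx = slots, pocket = pocket,
      anchors = anchors, pep_ca = pep_ca, pep_sc = pep_sc,
      has_groove = TRUE, energy = NA_real_, seed = NA_integer_
    ),
    class = "nes_model"
  )
}

#' Strip the groove from a complex model (free-peptide state)
#'
#' @param model An `nes_model`.
#' @return The model with the groove (and pocket/exposure context) removed.
#' @export
free_peptide <- function(model) {
  model$has_groove <- FALSE
  model
}

#' Groove-only model of a template
#'
#' @param template An `nes_template`.
#' @return An `nes_model` with no peptide residues.
#' @export
groove_model <- function(template) {
  structure(
    list(
      template = template, template_id = template$template_id,
      seq_chars = character(), slot_idx = integer(), pocket = integer(),
      anchors = matrix(numeric(), 0L, 3L),
      pep_ca = matrix(numeric(), 0L, 3L), pep_sc = matrix(numeric(), 0L, 3L),
      has_groove = TRUE, energy = NA_real_, seed = NA_integer_
    ),
    class = "nes_model"
  )
}

#' @export
print.nes_model <- function(x, ...) {
  cat(sprintf("<nes_model> template %s, %d residues%s, energy %s\n",
    x$template_id, length(x$seq_chars),
    if (x$has_groove) " + groove" else " (free peptide)",
    format(x$energy)))
  invisible(x)
}

perturb_residue <- function(model, r, sigma_bb, sigma_sc) {
  model$pep_ca[r, ] <- model$pep_ca[r, ] + stats::rnorm(3L, 0, sigma_bb)
  model$pep_sc[r, ] <- model$pep_sc[r, ] + stats::rnorm(3L, 0, sigma_sc)
  model
}

#' Sample conformations by Metropolis Monte Carlo
#'
#' Runs `n_models` independent Metropolis chains of `n_trials` local moves
#' (small perturbations of one peptide residue's backbone anchor and
#' side-chain centroid) from the threaded pose, accepting by the standard
#' criterion at fixed temperature. Deterministic given `seed`. Moves
#' producing a non-finite energy are rejected.
#'
#' @param model Starting `nes_model`.
#' @param backend Energy backend.
#' @param n_models,n_trials Chain count and length.
#' @param seed Integer seed.
#' @param temperature Metropolis temperature.
#' @param sigma_bb,sigma_sc Proposal step sizes.
#' @return A list of `nes_model`s with `energy` set.
#' @export
sample_models <- function(model, backend, n_models = 50L, n_trials = 2000L,
                          seed = 1L, temperature = 1.0,
                          sigma_bb = 0.25, sigma_sc = 0.4) {
  stopifnot(n_models >= 1L, n_trials >= 0L)
  m <- length(model$seq_chars)
  base_e <- backend$evaluate(model)
  out <- vector("list", n_models)
  n_nonfinite <- 0L
  for (k in seq_len(n_models)) {
    sk <- derive_seed(seed, k)
    set.seed(sk)
    cur <- model
    cur_e <- base_e
    if (m > 0L) {
      for (t in seq_len(n_trials)) {
        r <- sample.int(m, 1L)
        cand <- perturb_residue(cur, r, sigma_bb, sigma_sc)
        cand_e <- backend$evaluate(cand)
        if (!is.finite(cand_e)) {
          n_nonfinite <- n_nonfinite + 1L
          next
        }
        if (cand_e <= cur_e || stats::runif(1L) < exp((cur_e - cand_e) / temperature)) {
          cur <- cand
          cur_e <- cand_e
        }
      }
    }
    cur$energy <- cur_e
    cur$seed <- sk
    out[[k]] <- cur
  }
  if (n_nonfinite > 0L) {
    warn(sprintf("rejected %d move(s) with non-finite energy", n_nonfinite))
  }
  out
}

#' Constrained local relaxation of sampled models
#'
#' Selects the `n_parents` lowest-energy models and runs `n_relax`
#' independent greedy descents per parent (`n_steps` proposals each,
#' accepting only improvements and only poses whose CA trace stays within
#' `radius` of the parent start pose). Children never have higher energy
#' than their parent.
#'
#' @param models List of sampled `nes_model`s.
#' @param backend Energy backend.
#' @param n_parents,n_relax,n_steps Protocol sizes.
#' @param radius Constraint radius (Angstroms).
#' @param seed Integer seed.
#' @param sigma_bb,sigma_sc Proposal step sizes (default half the sampler's).
#' @return List of child `nes_model`s (length `min(n_parents, length(models))
#'   * n_relax`).
#' @export
refine_models <- function(models, backend, n_parents = 5L, n_relax = 50L,
                          n_steps = 25L, radius = 1.0, seed = 1L,
                          sigma_bb = 0.12, sigma_sc = 0.2) {
  stopifnot(length(models) >= 1L)
  energies <- vapply(models, `[[`, numeric(1L), "energy")
  parents <- models[order(energies)[seq_len(min(n_parents, length(models)))]]
  children <- list()
  for (p in seq_along(parents)) {
    parent <- parents[[p]]
    m <- length(parent$seq_chars)
    for (j in seq_len(n_relax)) {
      set.seed(derive_seed(seed, p * 1009L + j))
      cur <- parent
      cur_e <- parent$energy
      if (m > 0L) {
        for (s in seq_len(n_steps)) {
          r <- sample.int(m, 1L)
          cand <- perturb_residue(cur, r, sigma_bb, sigma_sc)
          disp <- sqrt(max(rowSums((cand$pep_ca - parent$pep_ca)^2)))
          if (disp > radius) next
          cand_e <- backend$evaluate(cand)
          if (is.finite(cand_e) && cand_e < cur_e) {
            cur <- cand
            cur_e <- cand_e
          }
        }
      }
      cur$energy <- cur_e
      children[[length(children) + 1L]] <- cur
    }
  }
  children
}

#' Lowest-k ensemble energy
#'
#' Mean of the `k` smallest energies in an ensemble (the full ensemble, with
#' a warning, when fewer than `k` models are available).
#'
#' @param x Numeric energies or a list of `nes_model`s.
#' @param k Number of lowest energies averaged (default 10).
#' @return Scalar mean.
#' @export
aggregate_energy <- function(x, k = 10L) {
  e <- if (is.list(x)) vapply(x, `[[`, numeric(1L), "energy") else x
  stopifnot(length(e) >= 1L)
  if (length(e) < k) {
    warn(sprintf("only %d model(s) available; averaging all (k = %d)", length(e), k))
    return(mean(e))
  }
  mean(sort(e)[seq_len(k)])
}

sample_and_aggregate <- function(model, backend, config, seed) {
  samples <- sample_models(model, backend,
    n_models = config$n_models, n_trials = config$n_trials, seed = seed,
    temperature = config$temperature, sigma_bb = config$sigma_bb,
    sigma_sc = config$sigma_sc)
  children <- refine_models(samples, backend,
    n_parents = config$n_parents, n_relax = config$n_relax,
    n_steps = config$n_steps, radius = config$relax_radius,
    seed = derive_seed(seed, 555L))
  ensemble <- c(samples, children)
  energies <- vapply(ensemble, `[[`, numeric(1L), "energy")
  list(
    energy = aggregate_energy(energies, config$k_lowest),
    best = ensemble[[which.min(energies)]]
  )
}

#' Relative binding energy of a peptide at the CRM1 groove
#'
#' Implements the full template-based protocol: the window is threaded onto
#' every template; complex and free-peptide ensembles are sampled and
#' relaxed; ensemble energies are lowest-k averages; the free-peptide
#' reference is the minimum over all backbone-fitted models; per-template
#' `E_bind = E_complex - E_protein - E_peptide`; the template with the
#' lowest `E_bind` is selected. The whole protocol is replicated `n_runs`
#' times with distinct sub-seeds (the groove-only energy is computed once
#' per template and reused); the replicate mean and standard deviation are
#' reported, and the interface RSA of the overall best model is computed
#' when configured.
#'
#' @param peptide_seq Window sequence.
#' @param match One-row match tibble (`phi1`, `seg_start`).
#' @param templates An `nes_template_library`.
#' @param backend Energy backend (default [default_backend()]).
#' @param config An [nes_sampling_config()].
#' @param seed Integer seed.
#' @return An `nes_binding` object; see [tidy.nes_binding()] and
#'   [glance.nes_binding()].
#' @export
e_bind <- function(peptide_seq, match, templates, backend = default_backend(),
                   config = nes_sampling_config(), seed = 1L) {
  stopifnot(length(templates) >= 1L)
  tn <- names(templates)
  eb <- matrix(NA_real_, length(templates), config$n_runs,
    dimnames = list(tn, NULL))
  e_prot <- vapply(templates, function(t) backend$evaluate(groove_model(t)),
    numeric(1L))
  best_model <- NULL
  best_model_e <- Inf
  run_best <- character(config$n_runs)
  for (r in seq_len(config$n_runs)) {
    e_cplx <- numeric(length(templates))
    e_pep <- numeric(length(templates))
    bests <- vector("list", length(templates))
    for (i in seq_along(templates)) {
      t <- templates[[i]]
      threaded <- thread_peptide(peptide_seq, match, t)
      sc <- sample_and_aggregate(threaded, backend, config,
        derive_seed(seed, r * 131L + i))
      e_cplx[[i]] <- sc$energy
      bests[[i]] <- sc$best
      sp <- sample_and_aggregate(free_peptide(threaded), backend, config,
        derive_seed(seed, r * 131L + i + 50L))
      e_pep[[i]] <- sp$energy
    }
    eb[, r] <- e_cplx - e_prot - min(e_pep)
    ri <- which.min(eb[, r])
    run_best[[r]] <- tn[[ri]]
    if (bests[[ri]]$energy < best_model_e) {
      best_model <- bests[[ri]]
      best_model_e <- bests[[ri]]$energy
    }
  }
  per_template <- rowMeans(eb)
  bi <- which.min(per_template)
  e_bind_runs <- apply(eb, 2L, min)
  rsa <- if (isTRUE(config$compute_rsa)) interface_rsa(best_model) else NA_real_
  res <- structure(
    list(
      peptide_seq = peptide_seq,
      per_template = per_template,
      per_template_runs = eb,
      best_template = tn[[bi]],
      best_class = templates[[bi]]$class_id,
      best_direction = templates[[bi]]$direction,
      e_bind = unname(per_template[[bi]]),
      e_bind_runs = unname(e_bind_runs),
      run_best_template = run_best,
      e_bind_mean = mean(e_bind_runs),
      e_bind_sd = stats::sd(e_bind_runs),
      rsa = rsa,
      weight_w = NA_real_,
      e_bind_rsa = NA_real_,
      best_model = best_model,
      seed = seed
    ),
    class = "nes_binding"
  )
  if (isTRUE(config$compute_rsa)) res <- rsa_correct(res, w = config$w_rsa)
  res
}

#' Apply the RSA correction to a binding result
#'
#' `E_bind^RSA = <E_bind> + w * RSA`, penalizing interface cavities that the
#' energy terms alone under-count.
#'
#' @param result An `nes_binding`.
#' @param w RSA weight (default 0.35).
#' @return The result with `weight_w` and `e_bind_rsa` set.
#' @export
rsa_correct <- function(result, w = 0.35) {
  stopifnot(inherits(result, "nes_binding"))
  if (!is.finite(result$rsa)) {
    validation_error("RSA has not been computed for this result")
  }
  result$weight_w <- w
  result$e_bind_rsa <- result$e_bind_mean + w * result$rsa
  result
}

#' Optimize the RSA correction weight
#'
#' Grid search for the weight maximizing the squared Pearson correlation of
#' `e + w * rsa` with `ln(K_D)`; ties break toward the smaller weight.
#'
#' @param e_values Uncorrected binding energies.
#' @param rsa_values Interface RSA values (paired).
#' @param lnkd ln(K_D) values (paired).
#' @param w_grid Candidate weights (default `seq(0, 1, 0.05)`).
#' @return The selected weight.
#' @export
optimize_rsa_weight <- function(e_values, rsa_values, lnkd,
                                w_grid = seq(0, 1, by = 0.05)) {
  n <- length(lnkd)
  if (n < 3L || length(e_values) != n || length(rsa_values) != n) {
    validation_error("need at least 3 paired observations")
  }
  if (stats::sd(lnkd) == 0) validation_error("ln(K_D) values have zero variance")
  r2 <- vapply(w_grid, function(w) {
    s <- e_values + w * rsa_values
    if (stats::sd(s) == 0) return(-Inf)
    stats::cor(s, lnkd)^2
  }, numeric(1L))
  if (all(!is.finite(r2))) validation_error("scores have zero variance at every weight")
  w_grid[[which.max(r2)]]
}

#' @export
print.nes_binding <- function(x, ...) {
  cat(sprintf(
    "<nes_binding> %s\n  best template %s (class %s, %s)\n  E_bind %.3f (mean %.3f, sd %s over %d run(s))\n  RSA %s, E_bind^RSA %s\n",
    x$peptide_seq, x$best_template, x$best_class, x$best_direction,
    x$e_bind, x$e_bind_mean, format(x$e_bind_sd, digits = 3),
    length(x$e_bind_runs), format(x$rsa, digits = 3),
    format(x$e_bind_rsa, digits = 4)))
  invisible(x)
}

#' Tidy a binding result into per-template rows
#'
#' @param x An `nes_binding`.
#' @param ... Unused.
#' @return A tibble with one row per template.
#' @method tidy nes_binding
#' @export
tidy.nes_binding <- function(x, ...) {
  tibble(
    template_id = names(x$per_template),
    e_bind = unname(x$per_template),
    is_best = names(x$per_template) == x$best_template
  )
}

#' One-row summary of a binding result
#'
#' @param x An `nes_binding`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance nes_binding
#' @export
glance.nes_binding <- function(x, ...) {
  tibble(
    peptide = x$peptide_seq, best_template = x$best_template,
    best_class = x$best_class, e_bind = x$e_bind,
    e_bind_mean = x$e_bind_mean, e_bind_sd = x$e_bind_sd,
    rsa = x$rsa, e_bind_rsa = x$e_bind_rsa
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
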
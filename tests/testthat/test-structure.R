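test_that("registry slots run from pre-Phi0 to post-Phi4 with pocket mapping", {
  reg <- nescan:::build_registry("1a")
  # 1 pre + Phi0 + 2 frame spacers + 10 template slots + 2 post
  expect_equal(nrow(reg), 16L)
  expect_equal(reg$slot[1:2], c("pre1", "phi0"))
  expect_equal(reg$slot[15:16], c("post1", "post2"))
  expect_equal(reg$pocket[match(paste0("phi", 0:4), reg$slot)], 0:4)
  expect_true(all(is.na(reg$pocket[grep("^s", reg$slot)])))
  # class 4 has the longest template (Phi1..Phi4 span 12)
  expect_equal(nrow(nescan:::build_registry("4")), 18L)
  # 1c carries one more Phi2->Phi3 spacer slot than 1a
  expect_equal(nrow(nescan:::build_registry("1c")) - nrow(reg), 1L)
  expect_error(nescan:::build_registry("9z"), class = "nescan_validation_error")
})

test_that("the synthetic template library covers the solved-structure classes", {
  tpl <- gen_toy_templates(1L)
  expect_s3_class(tpl, "nes_template_library")
  expect_length(tpl, 8L)
  classes <- vapply(tpl, `[[`, character(1), "class_id")
  expect_true(all(c("1a", "1b", "1c", "2", "4") %in% classes))
  expect_equal(sum(classes == "1a"), 3L) # 1a.1, 1a.2 and the reverse-bound 1a-R
  dirs <- vapply(tpl, `[[`, character(1), "direction")
  expect_setequal(unique(dirs), c("forward", "reverse"))
  for (t in tpl) {
    # five pocket centroids evenly spaced along the groove axis
    expect_equal(dim(t$pockets), c(5L, 3L))
    gaps <- sqrt(rowSums(diff(t$pockets)^2))
    expect_equal(gaps, rep(nescan:::POCKET_SPACING, 4), ignore_attr = TRUE)
    # every Phi slot's backbone anchor sits directly above its pocket
    phi_rows <- which(!is.na(t$registry$pocket))
    for (j in phi_rows) {
      pk <- t$pockets[t$registry$pocket[[j]] + 1L, ]
      expect_equal(unname(t$anchors[j, 1:2]), unname(pk[1:2]))
    }
    expect_equal(nrow(t$anchors), nrow(t$registry))
  }
  # reverse templates store slots in mirrored N->C order
  expect_equal(tpl[["1a-R"]]$registry$slot[[1]], "post2")
  # same-class templates are geometrically distinguishable
  d <- sqrt(rowSums((tpl[["1a.1"]]$anchors - tpl[["1a.2"]]$anchors)^2))
  expect_gte(max(d), 2)
})

test_that("threading aligns Phi1, places Phis over pockets and clips", {
  x <- ideal_1a()
  tpl <- gen_toy_templates(1L)[["1a.1"]]
  model <- thread_peptide(x$window, x$match, tpl)
  expect_s3_class(model, "nes_model")
  expect_equal(length(model$seq_chars), 14L)
  phi_i <- which(!is.na(model$pocket))
  expect_equal(model$pocket[phi_i], 1:4)
  expect_equal(model$seq_chars[phi_i], c("L", "L", "L", "L"))
  reg_rows <- match(paste0("phi", 1:4), tpl$registry$slot)
  expect_equal(model$pep_ca[phi_i, ], tpl$anchors[reg_rows, ], ignore_attr = TRUE)
  # residues beyond the registry are clipped
  long <- paste0(strrep("G", 10), x$window)
  match_long <- x$match
  match_long$seg_start <- 1L
  match_long$phi1 <- x$match$phi1 + 10L
  clipped <- thread_peptide(long, match_long, tpl)
  expect_equal(length(clipped$seq_chars), nrow(tpl$registry))
  # Phi1 outside the window is an error
  bad <- x$match
  bad$phi1 <- 40L
  expect_error(thread_peptide(x$window, bad, tpl),
    class = "nescan_validation_error")
})

test_that("the surrogate backend is a pure function that penalizes clashes", {
  x <- ideal_1a()
  tpl <- gen_toy_templates(1L)[["1a.1"]]
  model <- thread_peptide(x$window, x$match, tpl)
  b <- default_backend()
  e1 <- b$evaluate(model)
  expect_true(is.finite(e1))
  expect_identical(e1, b$evaluate(model))
  # ramming a residue into a groove atom raises the energy
  crash <- model
  crash$pep_ca[1, ] <- as.numeric(tpl$groove_ca[1, ])
  crash$pep_sc[1, ] <- as.numeric(tpl$groove_sc[1, ])
  expect_gt(b$evaluate(crash), e1)
  # pulling the peptide out of the groove raises the energy (strain+exposure)
  out <- model
  out$pep_ca[, 3] <- out$pep_ca[, 3] + 8
  out$pep_sc[, 3] <- out$pep_sc[, 3] + 8
  expect_gt(b$evaluate(out), e1)
})

test_that("Metropolis sampling is deterministic given the seed", {
  x <- ideal_1a()
  tpl <- gen_toy_templates(1L)[["1a.1"]]
  model <- thread_peptide(x$window, x$match, tpl)
  b <- default_backend()
  s1 <- sample_models(model, b, n_models = 3L, n_trials = 20L, seed = 5L)
  s2 <- sample_models(model, b, n_models = 3L, n_trials = 20L, seed = 5L)
  expect_identical(
    vapply(s1, `[[`, numeric(1), "energy"),
    vapply(s2, `[[`, numeric(1), "energy"))
  s3 <- sample_models(model, b, n_models = 3L, n_trials = 20L, seed = 6L)
  expect_false(identical(
    vapply(s1, `[[`, numeric(1), "energy"),
    vapply(s3, `[[`, numeric(1), "energy")))
})

test_that("relaxation children never exceed their parent's energy", {
  x <- ideal_1a()
  tpl <- gen_toy_templates(1L)[["1a.1"]]
  model <- thread_peptide(x$window, x$match, tpl)
  b <- default_backend()
  s <- sample_models(model, b, n_models = 4L, n_trials = 15L, seed = 2L)
  parent_e <- min(vapply(s, `[[`, numeric(1), "energy"))
  kids <- refine_models(s, b, n_parents = 1L, n_relax = 5L, n_steps = 10L,
    seed = 3L)
  expect_length(kids, 5L)
  expect_true(all(vapply(kids, `[[`, numeric(1), "energy") <= parent_e))
})

test_that("lowest-k aggregation matches the sort-and-average oracle", {
  expect_equal(aggregate_energy(c(5, 1, 3, 2), k = 2L), 1.5)
  expect_equal(aggregate_energy(c(-1, -4), k = 2L), -2.5)
  expect_warning(out <- aggregate_energy(c(4, 8), k = 10L), "averaging all")
  expect_equal(out, 6)
})

test_that("a constant backend yields E_bind = -c", {
  x <- ideal_1a()
  tpl <- tiny_templates()
  res <- e_bind(x$window, x$match, tpl, backend = constant_backend(3.7),
    config = det_config(n_runs = 2L, compute_rsa = FALSE), seed = 1L)
  expect_equal(res$e_bind, -3.7)
  expect_equal(res$e_bind_mean, -3.7)
  expect_equal(res$e_bind_sd, 0)
})

test_that("scaling the backend and temperature scales E_bind exactly", {
  x <- ideal_1a()
  tpl <- tiny_templates()
  cfg <- nes_sampling_config(n_models = 2L, n_trials = 15L, n_parents = 1L,
    n_relax = 2L, n_steps = 5L, k_lowest = 2L, n_runs = 1L,
    compute_rsa = FALSE)
  lam <- 2.5
  cfg2 <- cfg
  cfg2$temperature <- lam * cfg$temperature
  b <- default_backend()
  r1 <- e_bind(x$window, x$match, tpl, backend = b, config = cfg, seed = 4L)
  r2 <- e_bind(x$window, x$match, tpl, backend = scaled_backend(b, lam),
    config = cfg2, seed = 4L)
  expect_equal(r2$per_template, lam * r1$per_template)
  expect_equal(r2$best_template, r1$best_template)
})

test_that("the full binding protocol is bitwise reproducible", {
  x <- ideal_1a()
  tpl <- tiny_templates()
  cfg <- fast_sampling_config(n_models = 2L, n_trials = 10L, n_relax = 2L,
    n_steps = 5L, k_lowest = 2L)
  r1 <- e_bind(x$window, x$match, tpl, config = cfg, seed = 11L)
  r2 <- e_bind(x$window, x$match, tpl, config = cfg, seed = 11L)
  expect_identical(r1$per_template_runs, r2$per_template_runs)
  expect_identical(r1$e_bind_rsa, r2$e_bind_rsa)
  expect_s3_class(glance(r1), "tbl_df")
  td <- tidy(r1)
  expect_equal(sum(td$is_best), 1L)
  expect_equal(td$template_id[td$is_best], r1$best_template)
})

test_that("accessible surface is exact for isolated and buried atoms", {
  one <- shrake_rupley(matrix(c(0, 0, 0), 1L), radii = 2, probe = 1.4)
  expect_equal(one$fraction, 1)
  expect_equal(one$area, 4 * pi * 3.4^2)
  # a small sphere at the center of a large one is fully buried
  two <- shrake_rupley(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1, 5))
  expect_equal(two$fraction[1], 0)
  expect_equal(two$fraction[2], 1)
  # far-apart atoms do not shadow each other
  far <- shrake_rupley(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(2, 2))
  expect_equal(far$fraction, c(1, 1))
})

test_that("interface RSA needs a groove and grows as the peptide leaves it", {
  x <- ideal_1a()
  tpl <- gen_toy_templates(1L)[["1a.1"]]
  model <- thread_peptide(x$window, x$match, tpl)
  expect_error(interface_rsa(free_peptide(model)),
    class = "nescan_validation_error")
  snug <- interface_rsa(model)
  out <- model
  out$pep_ca[, 3] <- out$pep_ca[, 3] + 10
  out$pep_sc[, 3] <- out$pep_sc[, 3] + 10
  expect_gt(interface_rsa(out), snug)
})

test_that("the RSA correction is plain arithmetic on the replicate mean", {
  x <- ideal_1a()
  res <- e_bind(x$window, x$match, tiny_templates(),
    config = det_config(), seed = 1L)
  expect_equal(res$e_bind_rsa, res$e_bind_mean + 0.35 * res$rsa)
  re <- rsa_correct(res, w = 0.8)
  expect_equal(re$e_bind_rsa, res$e_bind_mean + 0.8 * res$rsa)
  no_rsa <- e_bind(x$window, x$match, tiny_templates(),
    config = det_config(compute_rsa = FALSE), seed = 1L)
  expect_error(rsa_correct(no_rsa), class = "nescan_validation_error")
})

test_that("RSA weight optimization recovers an exact planted weight", {
  set.seed(12)
  e <- rnorm(40)
  r <- runif(40, 0, 2)
  expect_equal(optimize_rsa_weight(e, r, e + 0.35 * r), 0.35)
  expect_equal(optimize_rsa_weight(e, r, e + 0.9 * r), 0.9)
  # with no RSA signal every weight ties; the smaller weight wins
  expect_equal(optimize_rsa_weight(e, rep(0, 40), e), 0)
  expect_error(optimize_rsa_weight(e[1:2], r[1:2], e[1:2]),
    class = "nescan_validation_error")
  expect_error(optimize_rsa_weight(e, r, rep(1, 40)),
    class = "nescan_validation_error")
})
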
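test_that("protein generation is deterministic and validates placements", {
  specs <- demo_plant_specs()
  g1 <- gen_protein(specs, 300L, seed = 9L)
  g2 <- gen_protein(specs, 300L, seed = 9L)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth, g2$truth)
  g3 <- gen_protein(specs, 300L, seed = 10L)
  expect_false(identical(g1$record$sequence, g3$record$sequence))
  expect_equal(nchar(g1$record$sequence), 300L)
  # overlapping or out-of-bounds plants are rejected
  bad <- list(plant_spec("1a", 50L), plant_spec("1a", 55L))
  expect_error(gen_protein(bad, 300L), "overlap",
    class = "nescan_validation_error")
  expect_error(gen_protein(list(plant_spec("1a", 295L)), 300L),
    class = "nescan_validation_error")
})

test_that("planted motifs are recovered by the scanner at their registry", {
  for (cl in c("1a", "1b", "1c", "2", "3", "4", "1a-R")) {
    g <- gen_protein(list(plant_spec(cl, 100L)), 250L, seed = 3L)
    m <- nes_scan(g$record)
    hit <- m[m$class_id == cl, ]
    expect_gte(nrow(hit), 1L)
    want <- as.integer(strsplit(g$truth$phi_positions, ",")[[1]])
    got <- FALSE
    for (i in seq_len(nrow(hit))) {
      got <- got || identical(match_registry(hit[i, ], with_phi0 = FALSE), want)
    }
    expect_true(got, label = sprintf("class %s registry recovered", cl))
  }
})

test_that("the damped background yields few spurious consensus matches", {
  for (s in c(1L, 2L, 3L)) {
    g <- gen_protein(list(), 300L, seed = s)
    expect_lte(nrow(nes_scan(g$record)), 5L)
  }
})

test_that("track generation matches the ground-truth contexts", {
  g <- gen_protein(demo_plant_specs(), 300L, seed = 1L)
  tr1 <- gen_tracks(g$record$sequence, g$truth, seed = 1L)
  tr2 <- gen_tracks(g$record$sequence, g$truth, seed = 1L)
  expect_identical(tr1$disopred$propensity, tr2$disopred$propensity)
  expect_false(identical(tr1$disopred$propensity, tr1$spotd$propensity))
  lab <- order_labels(tr1$disopred, tr1$spotd)
  # deep ordered core: residues 1..200 are far from any disordered block
  expect_gte(mean(lab$label[1:200] == "O"), 0.95)
  # the planted tail region is strongly disordered
  plant <- g$truth[g$truth$kind == "plant", ]
  expect_equal(segment_location(lab, plant$start, plant$end), "DISO")
  # domains cover only ordered blocks of >= 50 residues
  expect_gte(nrow(tr1$domains), 1L)
  expect_true(all(tr1$domains$end - tr1$domains$start + 1L >= 50L))
  expect_lt(tr1$domains$end[1], plant$start)
  # secondary structure: helix over the plant, strand over the beta decoy
  beta_decoy <- g$truth[g$truth$kind == "decoy" & g$truth$decoy_type == "beta", ]
  phis <- as.integer(strsplit(beta_decoy$phi_positions, ",")[[1]])
  expect_true(all(tr1$ss$state[min(phis):max(phis)] == "E"))
  phis_p <- as.integer(strsplit(plant$phi_positions, ",")[[1]])
  expect_true(all(tr1$ss$state[min(phis_p):max(phis_p)] == "H"))
})

test_that("decoys carry the intended context flags after annotation", {
  g <- gen_protein(demo_plant_specs(), 300L, seed = 2L)
  tr <- gen_tracks(g$record$sequence, g$truth, seed = 2L)
  m <- nes_scan(g$record)
  ann <- annotate_context(m, domains = tr$domains, ss = tr$ss,
    tracks = list(disopred = tr$disopred, spotd = tr$spotd, iup = tr$iup))
  truth <- g$truth
  row_for <- function(t) {
    cand <- ann[ann$seg_start >= t$start - 2L & ann$seg_end <= t$end + 2L, ]
    cand[cand$class_id == t$class_id, ][1, ]
  }
  plant_row <- row_for(truth[truth$kind == "plant", ])
  expect_true(plant_row$highlighted)
  expect_equal(plant_row$flags, "_D")
  ord_row <- row_for(truth[which(truth$decoy_type == "ordered"), ])
  expect_false(ord_row$highlighted)
  expect_equal(ord_row$loc_diso, "ORD")
  expect_equal(ord_row$loc_cdd, "MID")
  beta_row <- row_for(truth[which(truth$decoy_type == "beta"), ])
  expect_false(beta_row$highlighted)
  expect_match(beta_row$flags, "_beta")
})

test_that("the synthetic benchmark encodes lnK_D linearly in the true score", {
  bm <- gen_benchmark(20L, noise = 0, seed = 5L)
  expect_equal(nrow(bm), 20L)
  expect_equal(sum(bm$binder), 12L)
  expect_true(all(is.na(bm$kd_nM[!bm$binder])))
  expect_true(all(bm$kd_nM[bm$binder] > 0))
  # zero noise: lnkd_true is an exact affine function of e_true
  fit <- correlate_lnkd(bm$e_true, exp(bm$lnkd_true))
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 14, tolerance = 1e-9)
  # determinism and noise injection
  expect_identical(bm$e_true, gen_benchmark(20L, noise = 0, seed = 5L)$e_true)
  noisy <- gen_benchmark(20L, noise = 0.6, seed = 5L)
  expect_identical(noisy$e_true, bm$e_true)
  expect_false(identical(noisy$lnkd_true, bm$lnkd_true))
  expect_error(gen_benchmark(5L), class = "nescan_validation_error")
})

test_that("non-binder peptides violate their own class pattern", {
  bm <- gen_benchmark(20L, noise = 0, seed = 7L)
  for (i in which(!bm$binder)) {
    m <- nes_scan(tibble::tibble(id = "p", sequence = bm$sequence[[i]]))
    same <- m[m$class_id == sub("-R$", "", bm$class[[i]]) |
      m$class_id == bm$class[[i]], ]
    hit_at_register <- any(same$phi1 == bm$phi1[[i]] & !same$ta_used)
    expect_false(hit_at_register,
      label = sprintf("peptide %s still matches cleanly", bm$name[[i]]))
  }
})

test_that("peptide scoring appends reproducible binding columns", {
  bm <- gen_benchmark(10L, noise = 0, seed = 2L, binder_frac = 1)
  tpl <- gen_toy_templates(1L)
  cfg <- det_config()
  s1 <- score_peptides(bm, tpl, config = cfg, seed = 3L)
  s2 <- score_peptides(bm, tpl, config = cfg, seed = 3L)
  expect_identical(s1$e_bind_mean, s2$e_bind_mean)
  expect_true(all(c("e_bind_mean", "rsa", "e_bind_rsa", "best_template",
    "best_class") %in% names(s1)))
  expect_equal(s1$e_bind_rsa, s1$e_bind_mean + 0.35 * s1$rsa)
  expect_true(all(s1$best_template %in% names(tpl)))
})
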
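# nescan

Sequence- and structure-based prediction of CRM1-dependent nuclear export
signals (NES) in R.

An NES is a short hydrophobic peptide motif (roughly 10-15 residues) that the
export receptor CRM1 recognizes through five hydrophobic pockets (P0-P4) in
its groove. Consensus-pattern matching alone vastly over-predicts such
motifs; `nescan` combines three stages to separate plausible export signals
from pattern noise:

1. **Consensus scanning** — all placements of the modified Kosugi class
   templates (classes 1a, 1b, 1c, 1d, 2, 3, 4 plus the reverse-binding
   classes 1a-R and 1c-R), with the Φ0 registry position, empirical class
   priorities, and candidate/false-positive labeling against experimental
   evidence intervals.
2. **Structural context** — per-residue disorder tracks from two primary
   predictors define highly ordered regions (both propensities strictly
   below 0.1); each match is located relative to ordered/disordered
   regions, conserved domains, and predicted β-strand content. Matches that
   are not buried in ordered regions and not β-rich are *highlighted* for
   scoring.
3. **Binding-energy scoring** — each highlighted window is threaded onto
   CRM1-groove templates, sampled with a Metropolis/relaxation ensemble
   protocol, and scored as `E_bind = E_complex - E_protein - E_peptide`
   (lowest-k ensemble averages, replicated runs), plus an interface
   solvent-accessibility correction `E_bind^RSA = E_bind + w * RSA`
   (default `w = 0.35`) that penalizes under-filled pockets.

Everything is deterministic under a seed, returns tibbles, and ships with
seeded synthetic generators (proteins with planted motifs, matching
disorder/SS/domain tracks, and labeled benchmarks with synthetic K_D
values), so the whole pipeline runs and is testable offline.

## Worked example

```r
library(nescan)

# 1. Generate a demo protein: a class-1a motif planted in a disordered
#    tail, plus an ordered-core decoy and a beta-strand decoy.
g  <- gen_protein(demo_plant_specs(), 300, seed = 42, id = "demo")
tr <- gen_tracks(g$record$sequence, g$truth, seed = 42)
plant <- g$truth[g$truth$kind == "plant", ]
ev <- tibble::tibble(kind = "functional", start = plant$start, end = plant$end)

# 2. Scan + annotate + score in one call.
tbl <- run_protein(
  g$record,
  tracks   = list(disopred = tr$disopred, spotd = tr$spotd, iup = tr$iup),
  domains  = tr$domains,
  ss       = tr$ss,
  evidence = ev,
  config   = nes_config(seed = 42, sampling = fast_sampling_config())
)

# Every consensus match with its context; only the planted motif is
# highlighted (the decoys are vetoed by the ordered region / beta content).
dplyr::select(tbl, class_id, priority, seg_start, seg_end,
  loc_diso, loc_cdd, beta, flags, highlighted, label, e_bind_rsa)

# 3. Rank the highlighted candidates by corrected binding energy.
rank_candidates(tbl)

# 4. Score one peptide explicitly and inspect the per-template landscape.
hi  <- tbl[tbl$highlighted, ][1, ]
res <- e_bind(hi$seg_seq, hi, gen_toy_templates(1),
  config = fast_sampling_config(), seed = 42)
res            # best template, replicate mean/sd, RSA, corrected score
tidy(res)      # one row per template
glance(res)    # one-row summary
ggplot2::autoplot(res)
```

The packaged affinity benchmark (validated NES peptides with measured K_D
plus consensus-matching non-binders) supports the correlation and
discrimination harness:

```r
b <- load_affinity_benchmark()
m <- metrics_from_counts(tp = 17, fp = 23, tn = 318, fn = 2)
```

## Command line

A thin CLI wraps the same functions (`inst/cli/nescan` after install):

```sh
nescan simulate --seed 3 --out-dir bundle
nescan run --fasta bundle/demo.fasta --diso bundle/demo.diso \
  --spotd bundle/demo.spotd --ss2 bundle/demo.ss2 \
  --domains bundle/demo_domains.tsv --evidence bundle/demo_evidence.tsv \
  --seed 3 --out-dir results
nescan benchmark --reference --out-dir bench
```

Each run writes TSV outputs plus a `run_log.yaml` with the version, seed and
parameters; outputs are byte-identical across repeated seeded runs.

## Reproduction

* Install: `R CMD INSTALL --no-docs --no-html --no-help .`
* Tests: `Rscript -e 'testthat::test_dir("tests/testthat", package = "nescan",
  load_package = "installed")'` — the suite includes an acceptance file
  (`tests/testthat/test-acceptance.R`) checking scanner/oracle equivalence,
  worked benchmark examples, context rules, the binding-protocol arithmetic,
  template self-selection, surrogate discrimination, parameter recovery,
  pipeline recovery of planted motifs, and the confusion-metric formulas.
* Summary metrics: `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`
  writes the main computed quantities (match counts, highlighted counts,
  benchmark correlation, recovered RSA weight, self-selection rate,
  reference confusion metrics) as flat JSON. All randomness derives from
  `--seed`.

See the vignette source (`vignettes/nes-prediction.Rmd`) for the method
description, parameter choices and limitations.
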
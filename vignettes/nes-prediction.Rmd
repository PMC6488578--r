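---
title: "Predicting CRM1-dependent nuclear export signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CRM1-dependent nuclear export signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nescan)
```

## The problem

Nuclear export signals (NES) are short hydrophobic peptides recognized by
the export receptor CRM1 (exportin-1). The binding groove of CRM1 presents
five hydrophobic pockets, P0-P4, that accept four to five hydrophobic
registry residues (Φ0-Φ4, generally Leu/Ile/Val/Met/Phe) spaced in a small
number of characteristic patterns. Purely pattern-based scanning finds
these spacings everywhere: the overwhelming majority of consensus matches
in real proteins are false positives. `nescan` implements a three-stage
pipeline that filters matches by structural plausibility and then scores
the survivors with a template-based binding-energy model.

## Stage 1: consensus scanning

Nine class templates are compiled (`nes_classes()`): forward classes 1a,
1b, 1c, 1d, 2, 3 and 4, and reverse-binding classes 1a-R and 1c-R which
apply the mirrored template to the reversed sequence. The slot rules are:

* Φ1-Φ4 accept L, I, V, M, F; **one** of Φ1/Φ2 may instead be Thr or Ala.
* Spacers between Φ2 and Φ4 (between Φ0 and Φ2 for reverse classes, read
  N-to-C) exclude Pro and Trp; class 3's first Φ2-Φ3 spacer position is
  unrestricted. All other spacers accept anything. An unknown residue `X`
  never satisfies a Φ slot or a restricted spacer.
* Class 4 requires at least one Pro in its three-residue Φ3-Φ4 spacer
  (a turn-forming constraint).
* Reverse classes additionally require one of the residues bound in the
  P0/P1 register to be L, F or M. Class 1c-R is flagged experimental.

Every placement of every class is recorded (`nes_scan()`); overlapping
matches are grouped (`group_overlaps()`, start positions within 5
residues). Φ0 is located three residues upstream of Φ1 in the binding
frame; it is not restricted to hydrophobics, but a hydrophobic Φ0
upgrades a class-1a match to the top empirical priority. Priorities are
1 (class 1a with five Φs), 2 (plain 1a/1c, 1a-R, 2, 3, 4), 3 (1a/1c with
Thr/Ala), 4 (1b, 1d, 1c-R, and Thr/Ala-substituted 2/3/4 and reverse
classes), 5 (1b/1d with Thr/Ala). The extraction window runs from one
residue before Φ0 to two residues after Φ4, clamped at the termini. A
match whose Φ2-Φ4 span overlaps an experimental-evidence interval is
labeled `cand`, otherwise `fp`.

## Stage 2: structural context

CRM1 can only engage motifs it can reach: NES segments buried in folded
domains or locked into β-strands are implausible regardless of sequence.

* **Order/disorder**: a residue is ordered (`O`) iff its disorder
  propensities from both primary predictor tracks are strictly below 0.1
  — a deliberately strict cutoff (typical disorder thresholds are ~0.5)
  so that `O` marks *confidently* ordered residues. A third (IUPred-style)
  track is carried for reporting only.
* **Segment location**: over the segment plus 20 flanking residues on each
  side (truncated at the termini), more than 90% `D` means `DISO`, more
  than 90% `O` means `ORD`, anything else `boundary`.
* **Domains**: the longest overlapping conserved domain governs; `MID`
  means fully inside with more than 5 residues of margin at both ends,
  domains shorter than 50 residues are reported `small`, otherwise
  `boundary`; `NA` when no domain overlaps.
* **β content**: the fraction of predicted strand states over the closed
  Φ1-Φ4 span.

A match is *highlighted* — passed to the structure stage — iff it is not
in the `ORD` region and its β content is at most 0.5 (a missing SS track
leaves the β criterion passing). Flags `_D`/`_O` and `_beta` summarize
this per row in the lookup table.

## Stage 3: template-based binding energy

Each highlighted window is threaded onto every template in a CRM1-groove
library: the window's Φ1 is aligned to the template's Φ1 anchor slot,
residues map N-to-C onto consecutive backbone anchors (mirrored slot order
for reverse-binding templates), and residues outside the template registry
are clipped. The packaged synthetic library covers the classes with solved
CRM1-complex structures (1a twice, 1b, 1c, 2, a reverse-bound 2, 4, and
1a-R); class-3 queries are fitted with the class-1a templates. A library
can also be read from PDB files via a manifest (`build_template_library()`).

Energies come from a pluggable backend. The shipped coarse-grained
surrogate models each residue as a CA plus a side-chain centroid and sums
four terms: a pocket reward for hydrophobic centroids buried in their
pocket (scaled by Kyte-Doolittle hydropathy and a Gaussian of distance),
soft-core clash repulsion, an exposure penalty for hydrophobic side chains
far from every pocket, and a harmonic strain to the template anchors. It
is a pure, deterministic function of coordinates, so any physics-grade
scoring function can be substituted without touching the protocol.

The sampling protocol mirrors ensemble modeling practice: `n_models`
independent Metropolis chains from the threaded pose, the `n_parents`
lowest-energy models each relaxed by `n_relax` constrained greedy descents,
and the ensemble summarized by the mean of its `k_lowest` energies. Then

```
E_bind = E_complex - E_protein - E_peptide
```

with the free-peptide reference taken as the *minimum* over all
backbone-fitted free-peptide ensembles, so a peptide is never penalized
for being threaded on a poor template. The whole protocol is replicated
`n_runs` times; the replicate mean and standard deviation are reported and
the template with the lowest energy is selected. Default bookkeeping
follows the protocol shape (50 chains, 5 parents × 50 relaxations,
lowest-10 averaging, 5 runs) with the per-chain trial count scaled to desk
size; `fast_sampling_config()` shrinks every knob for interactive use.

Finally, the interface solvent accessibility (RSA) of the best model —
the summed accessible-surface fraction of the peptide's Φ side chains and
the pocket-lining groove residues, computed with a deterministic
Shrake-Rupley lattice — corrects the score:

```
E_bind^RSA = mean(E_bind) + w * RSA,  w = 0.35 by default
```

penalizing interface cavities that pairwise energy terms under-count.
`optimize_rsa_weight()` re-derives `w` by grid search against ln(K_D).

## Benchmarking

`load_affinity_benchmark()` ships a table of validated NES peptides with
measured dissociation constants and consensus-matching pull-down-negative
peptides. The harness correlates scores with ln(K_D)
(`correlate_lnkd()`) and evaluates binder/non-binder discrimination
(`confusion()`, `sweep_threshold()`, `metrics_from_counts()`, including
the diagnostic odds ratio with an explicit degeneracy flag when a
confusion cell is empty).

## Synthetic data

All generators are deterministic under a seed and emit ground truth:

* `gen_protein()` plants exact-consensus motifs into a background with
  damped hydrophobic frequencies (and none at all in disordered-context
  regions, mirroring the hydrophobic depletion of real disordered tails).
  Planted Φ0 is polar by default because a hydrophobic residue three
  positions before a class-1a Φ1 *always* creates an additional class-3
  registry — an instructive ambiguity of the consensus itself.
* `gen_tracks()` draws disorder propensities from Beta distributions
  around a smoothed target profile (~0.03 ordered, ~0.7 disordered, with
  concentrations chosen so ordered residues fall below the 0.1 cutoff on
  both tracks ~99.6% of the time), helix/strand SS states over planted
  and decoy middles, and one domain row per long ordered block.
* `gen_benchmark()` builds on-register binders and violated non-binders
  (Φ→Ala or a Pro planted in a restricted spacer) and maps a deterministic
  threading energy to `lnK_D = slope * (E + w_rsa * RSA) + intercept +
  noise`, so correlation and weight-recovery behavior can be tested
  end-to-end.

## Numerical and scale choices

* Determinism everywhere: seeds flow through a single integer derivation
  (`derive_seed()`), Monte Carlo uses R's RNG exclusively, the surface
  lattice is a fixed Fibonacci sphere, and CLI outputs are byte-identical
  across repeated seeded runs (run logs deliberately omit timestamps).
* Desk-scale sizes are package choices, not claims: the synthetic groove,
  the reduced trial counts in `fast_sampling_config()`, and the 128-point
  surface lattice trade resolution for runtime while preserving every
  protocol property (ensemble shape, lowest-k averaging, replicate
  statistics, RSA correction).

## Limitations

* The surrogate backend reproduces *qualitative* physics — pocket burial,
  clashes, exposure — not calibrated affinities. On the packaged affinity
  table it does not recover the experimental ln(K_D) ordering (the
  published analysis used a full molecular-mechanics energy function and
  crystal-structure templates); the correlation properties are therefore
  demonstrated on the synthetic benchmark, where ground truth exists.
* The synthetic template library is idealized geometry, not crystal
  structures; template self-selection is a consistency property of the
  generator/scorer pair.
* Class 1d and 1c-R have no dedicated templates (1c-R is experimental in
  the consensus set as well); their matches are still scanned, annotated
  and prioritized.
* Disorder, secondary-structure and domain tracks are *inputs*: the
  package parses predictor outputs (or simulates them) but does not run
  the predictors.
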
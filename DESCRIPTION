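Package: nescan
Title: Sequence- and Structure-Based Prediction of CRM1-Dependent Nuclear
    Export Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans protein sequences for nuclear export signal (NES) consensus
    motifs of the modified Kosugi classes, annotates every match with its
    intrinsic-disorder, conserved-domain and secondary-structure context, and
    scores candidate segments by threading them onto CRM1 groove templates and
    evaluating a relative binding energy with a coarse-grained surrogate
    energy backend, including a solvent-accessibility correction that
    penalizes interface cavities. Ships readers for the common external
    formats (FASTA, disorder-propensity tracks in three predictor dialects,
    PSIPRED ss2 files, domain and evidence interval tables, PDB templates), a
    benchmark harness with a packaged affinity table of validated NES peptides
    and consensus-matching non-binders, and seeded synthetic-data generators
    so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
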
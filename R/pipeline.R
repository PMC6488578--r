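# End-to-end orchestration: scan -> context-annotate -> structure-score the
# highlighted segments -> per-protein lookup table; plus the CLI entry point.

#' Pipeline run configuration
#'
#' Houses every rule cutoff and the structure-stage settings. The default
#' sampling preset is [fast_sampling_config()] so a full protein runs at
#' desk scale; pass `sampling = nes_sampling_config()` for the full
#' protocol.
#'
#' @param disorder_cutoff Strict order/disorder propensity cutoff (0.1).
#' @param window_frac Dominance fraction for segment location (0.9).
#' @param flank Flank width for segment location (20).
#' @param beta_cut Beta-content threshold (0.5).
#' @param overlap_delta Segment-grouping start-distance (5).
#' @param edge Domain end margin (5).
#' @param small_len Small-domain length bound (50).
#' @param w_rsa RSA correction weight (0.35).
#' @param structure_stage Run the binding-energy stage (default TRUE).
#' @param score_all Score every row, not only highlighted ones (default
#'   FALSE).
#' @param sampling An [nes_sampling_config()].
#' @param seed Integer seed for the structure stage.
#' @return A list of class `nes_config`.
#' @export
nes_config <- function(disorder_cutoff = 0.1, window_frac = 0.9, flank = 20L,
                       beta_cut = 0.5, overlap_delta = 5L, edge = 5L,
                       small_len = 50L, w_rsa = 0.35, structure_stage = TRUE,
                       score_all = FALSE, sampling = fast_sampling_config(),
                       seed = 1L) {
  stopifnot(disorder_cutoff > 0, disorder_cutoff < 1,
    window_frac > 0, window_frac < 1, flank >= 0, beta_cut >= 0, beta_cut <= 1,
    overlap_delta >= 1, edge >= 0, small_len >= 1, w_rsa >= 0)
  sampling$w_rsa <- w_rsa
  structure(
    list(disorder_cutoff = disorder_cutoff, window_frac = window_frac,
      flank = as.integer(flank), beta_cut = beta_cut,
      overlap_delta = as.integer(overlap_delta), edge = as.integer(edge),
      small_len = as.integer(small_len), w_rsa = w_rsa,
      structure_stage = structure_stage, score_all = score_all,
      sampling = sampling, seed = as.integer(seed)),
    class = "nes_config"
  )
}

check_track_alignment <- function(L, tracks, ss, domains, evidence, id) {
  chk_len <- function(x, what) {
    if (!is.null(x) && nrow(x) != L) {
      validation_error("%s track for '%s' has %d rows but the sequence has %d residues",
        what, id, nrow(x), L)
    }
  }
  if (is.null(tracks$disopred) || is.null(tracks$spotd)) {
    validation_error("disorder tracks 'disopred' and 'spotd' are required")
  }
  chk_len(tracks$disopred, "disopred")
  chk_len(tracks$spotd, "spotd")
  chk_len(tracks$iup, "iupred")
  chk_len(ss, "secondary-structure")
  chk_iv <- function(x, what) {
    if (!is.null(x) && nrow(x) > 0L && any(x$end > L)) {
      validation_error("%s interval ends beyond residue %d of '%s'", what, L, id)
    }
  }
  chk_iv(domains, "domain")
  chk_iv(evidence, "evidence")
  invisible(TRUE)
}

lookup_structure_cols <- c("e_bind_mean", "e_bind_sd", "rsa", "e_bind_rsa",
  "best_template", "best_class")

add_empty_structure_cols <- function(rows) {
  rows$e_bind_mean <- rep(NA_real_, nrow(rows))
  rows$e_bind_sd <- rep(NA_real_, nrow(rows))
  rows$rsa <- rep(NA_real_, nrow(rows))
  rows$e_bind_rsa <- rep(NA_real_, nrow(rows))
  rows$best_template <- rep(NA_character_, nrow(rows))
  rows$best_class <- rep(NA_character_, nrow(rows))
  rows
}

#' Run the full prediction pipeline on one protein
#'
#' Scans the sequence for consensus matches, annotates each with its
#' structural context, optionally labels against experimental evidence, and
#' runs the binding-energy stage on the highlighted rows (all rows with
#' `score_all`). Deterministic given `config$seed`. All input alignment is
#' validated before any computation.
#'
#' @param seqs One-row tibble (`id`, `sequence`) or a single sequence string.
#' @param tracks Named list of disorder tracks: `disopred`, `spotd`
#'   (required), `iup` (optional).
#' @param domains Domain tibble or NULL (`loc_cdd` becomes `"NA"`).
#' @param ss Secondary-structure tibble or NULL (`beta = NA`, criterion
#'   treated as passing).
#' @param evidence Evidence tibble or NULL (no `label` column).
#' @param config An [nes_config()].
#' @param templates Template library (default: synthetic library, built
#'   lazily when the structure stage runs).
#' @param backend Energy backend.
#' @return The lookup table: one row per consensus match with context
#'   columns, grouping, optional `label`, and the structure-score columns
#'   (NA where not scored); ordered by `seg_start` then `priority`.
#' @export
run_protein <- function(seqs, tracks, domains = NULL, ss = NULL,
                        evidence = NULL, config = nes_config(),
                        templates = NULL, backend = default_backend()) {
  if (is.character(seqs)) seqs <- tibble(id = "protein", sequence = seqs)
  if (nrow(seqs) != 1L) validation_error("run_protein takes exactly one sequence")
  assert_sequence(seqs$sequence[[1L]], seqs$id[[1L]])
  L <- nchar(seqs$sequence[[1L]])
  check_track_alignment(L, tracks, ss, domains, evidence, seqs$id[[1L]])
  labeling <- order_labels(tracks$disopred, tracks$spotd,
    cutoff = config$disorder_cutoff)
  rows <- nes_scan(seqs)
  rows <- group_overlaps(rows, delta = config$overlap_delta)
  if (nrow(rows) == 0L) {
    rows <- annotate_context(rows, labeling, domains, ss, tracks,
      flank = config$flank, frac = config$window_frac, edge = config$edge,
      small_len = config$small_len, beta_cut = config$beta_cut)
    if (!is.null(evidence)) rows$label <- character(0L)
    return(add_empty_structure_cols(rows))
  }
  rows <- annotate_context(rows, labeling, domains, ss, tracks,
    flank = config$flank, frac = config$window_frac, edge = config$edge,
    small_len = config$small_len, beta_cut = config$beta_cut)
  if (!is.null(evidence)) {
    rows <- label_candidate(rows, evidence)
    rows$matched_evidence <- NULL
  }
  rows <- add_empty_structure_cols(rows)
  if (isTRUE(config$structure_stage)) {
    to_score <- if (isTRUE(config$score_all)) seq_len(nrow(rows)) else
      which(rows$highlighted)
    if (length(to_score) > 0L) {
      if (is.null(templates)) templates <- gen_toy_templates(1L)
      for (i in to_score) {
        res <- e_bind(rows$seg_seq[[i]], rows[i, ], templates, backend,
          config$sampling, seed = derive_seed(config$seed, 900L + i))
        rows$e_bind_mean[[i]] <- res$e_bind_mean
        rows$e_bind_sd[[i]] <- res$e_bind_sd
        rows$rsa[[i]] <- res$rsa
        rows$e_bind_rsa[[i]] <- res$e_bind_rsa
        rows$best_template[[i]] <- res$best_template
        rows$best_class[[i]] <- res$best_class
      }
    }
  }
  arrange(rows, .data$seg_start, .data$priority)
}

#' Rank scored candidates
#'
#' Highlighted rows sorted ascending by `e_bind_rsa` (falling back to
#' `e_bind_mean` where the RSA correction is absent); ties broken by
#' priority then `seg_start`.
#'
#' @param rows A lookup table from [run_protein()].
#' @return The highlighted rows, ranked, with a `rank` column.
#' @export
rank_candidates <- function(rows) {
  out <- rows[rows$highlighted, , drop = FALSE]
  key <- ifelse(is.na(out$e_bind_rsa), out$e_bind_mean, out$e_bind_rsa)
  out <- out[order(key, out$priority, out$seg_start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

write_lookup <- function(rows, path) {
  out <- rows[!vapply(rows, is.list, logical(1L))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---- CLI ------------------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: nescan <subcommand> [options]",
    "subcommands:",
    "  scan       --fasta F [--out-dir D]",
    "  annotate   --fasta F --diso F --spotd F [--iup F] [--ss2 F]",
    "             [--domains F] [--evidence F] [--config F] [--out-dir D]",
    "  score      like annotate, plus --templates DIR --seed N",
    "  run        alias of score (full pipeline)",
    "  benchmark  --reference | --input F [--seed N] [--out-dir D]",
    "  simulate   [--seed N] [--out-dir D]",
    sep = "\n")
}

cli_options <- function() {
  list(
    optparse::make_option("--fasta", type = "character", default = NULL),
    optparse::make_option("--diso", type = "character", default = NULL),
    optparse::make_option("--spotd", type = "character", default = NULL),
    optparse::make_option("--iup", type = "character", default = NULL),
    optparse::make_option("--ss2", type = "character", default = NULL),
    optparse::make_option("--domains", type = "character", default = NULL),
    optparse::make_option("--evidence", type = "character", default = NULL),
    optparse::make_option("--templates", type = "character", default = "synthetic"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--reference", action = "store_true", default = FALSE,
      help = "use the packaged affinity benchmark"),
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--out-dir", type = "character", default = ".",
      dest = "out_dir")
  )
}

cli_config <- function(opts) {
  args <- list(seed = opts$seed)
  if (!is.null(opts$config)) {
    cfg <- yaml::read_yaml(opts$config)
    known <- names(formals(nes_config))
    bad <- setdiff(names(cfg), known)
    if (length(bad) > 0L) {
      validation_error("unknown config key(s): %s", paste(bad, collapse = ", "))
    }
    args <- utils::modifyList(cfg, args)
  }
  do.call(nes_config, args)
}

cli_require <- function(opts, fields) {
  for (f in fields) {
    if (is.null(opts[[f]])) validation_error("--%s is required", f)
  }
}

cli_load_inputs <- function(opts) {
  cli_require(opts, c("fasta", "diso", "spotd"))
  list(
    seqs = read_fasta(opts$fasta),
    tracks = list(
      disopred = read_disorder_track(opts$diso, "disopred"),
      spotd = read_disorder_track(opts$spotd, "spotd"),
      iup = if (!is.null(opts$iup)) read_disorder_track(opts$iup, "iupred")
    ),
    ss = if (!is.null(opts$ss2)) read_ss2(opts$ss2),
    domains = if (!is.null(opts$domains)) read_domains(opts$domains),
    evidence = if (!is.null(opts$evidence)) read_evidence(opts$evidence)
  )
}

write_run_log <- function(path, subcommand, opts, config = NULL) {
  log <- list(
    tool = "nescan",
    version = tryCatch(as.character(utils::packageVersion("nescan")),
      error = function(e) "dev"),
    subcommand = subcommand, seed = opts$seed,
    parameters = if (!is.null(config))
      config[c("disorder_cutoff", "window_frac", "flank", "beta_cut",
        "overlap_delta", "edge", "small_len", "w_rsa")]
  )
  yaml::write_yaml(log, path)
  invisible(path)
}

cli_benchmark <- function(opts, out_dir) {
  if (!opts$reference && is.null(opts$input)) {
    validation_error("benchmark needs --reference or --input")
  }
  entries <- if (opts$reference) load_affinity_benchmark() else {
    x <- readr::read_tsv(opts$input, show_col_types = FALSE, progress = FALSE)
    need <- c("name", "sequence", "class", "kd_nM", "binder")
    if (!all(need %in% names(x))) {
      validation_error("benchmark input requires columns: %s",
        paste(need, collapse = ", "))
    }
    x
  }
  # derive a threading registry for each peptide from its own scan
  prep <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    m <- nes_scan(tibble(id = entries$name[[i]],
      sequence = entries$sequence[[i]]))
    if (nrow(m) == 0L) next
    m <- m[order(m$priority, m$seg_start), ]
    prep[[i]] <- tibble(name = entries$name[[i]],
      sequence = entries$sequence[[i]],
      phi1 = m$phi1[[1L]], seg_start = m$seg_start[[1L]],
      kd_nM = entries$kd_nM[[i]], binder = entries$binder[[i]])
  }
  skipped <- entries$name[vapply(prep, is.null, logical(1L))]
  if (length(skipped) > 0L) {
    message("no consensus match, skipped: ", paste(skipped, collapse = ", "))
  }
  pep <- bind_rows(prep)
  scored <- score_peptides(pep, gen_toy_templates(1L),
    config = fast_sampling_config(), seed = opts$seed)
  readr::write_tsv(scored, file.path(out_dir, "benchmark_scores.tsv"),
    progress = FALSE)
  with_kd <- scored[!is.na(scored$kd_nM), , drop = FALSE]
  cor_e <- correlate_lnkd(with_kd$e_bind_mean, with_kd$kd_nM)
  cor_rsa <- correlate_lnkd(with_kd$e_bind_rsa, with_kd$kd_nM)
  report <- bind_rows(
    cbind(tibble(score = "e_bind_mean"), cor_e),
    cbind(tibble(score = "e_bind_rsa"), cor_rsa)
  )
  readr::write_tsv(report, file.path(out_dir, "benchmark_correlation.tsv"),
    progress = FALSE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `scan`, `annotate`, `score`, `run`, `benchmark`, `simulate`.
#' Writes TSV outputs plus a structured YAML log into `--out-dir`. Exit code
#' 0 on success; validation/usage errors print a message and return 2.
#'
#' @param argv Character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code (invisibly): 0 success, 2 validation error.
#' @export
nes_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0L || argv[[1L]] %in% c("-h", "--help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    sub <- argv[[1L]]
    if (!sub %in% c("scan", "annotate", "score", "run", "benchmark", "simulate")) {
      validation_error("unknown subcommand '%s'", sub)
    }
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_options(),
        add_help_option = FALSE),
      args = argv[-1L])
    out_dir <- opts$out_dir
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (sub == "scan") {
      cli_require(opts, "fasta")
      seqs <- read_fasta(opts$fasta)
      write_matches(group_overlaps(nes_scan(seqs)),
        file.path(out_dir, "matches.tsv"))
      write_run_log(file.path(out_dir, "run_log.yaml"), sub, opts)
    } else if (sub %in% c("annotate", "score", "run")) {
      inp <- cli_load_inputs(opts)
      config <- cli_config(opts)
      if (sub == "annotate") config$structure_stage <- FALSE
      templates <- if (identical(opts$templates, "synthetic")) NULL else
        build_template_library(opts$templates)
      tables <- lapply(seq_len(nrow(inp$seqs)), function(i) {
        run_protein(inp$seqs[i, ], inp$tracks, inp$domains, inp$ss,
          inp$evidence, config, templates)
      })
      write_lookup(bind_rows(tables), file.path(out_dir, "lookup.tsv"))
      write_run_log(file.path(out_dir, "run_log.yaml"), sub, opts, config)
    } else if (sub == "benchmark") {
      cli_benchmark(opts, out_dir)
      write_run_log(file.path(out_dir, "run_log.yaml"), sub, opts)
    } else if (sub == "simulate") {
      simulate_bundle(out_dir, seed = opts$seed)
      write_run_log(file.path(out_dir, "run_log.yaml"), sub, opts)
    }
    0L
  }, nescan_validation_error = function(e) {
    message("error: ", conditionMessage(e))
    message(cli_usage())
    2L
  })
  invisible(code)
}
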
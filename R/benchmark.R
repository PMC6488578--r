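#' Load the packaged CRM1-NES affinity benchmark
#'
#' A published benchmark of peptides used in CRM1 binding studies: validated
#' NES motifs with measured dissociation constants (K_D, nM) plus
#' consensus-matching sequences validated as non-binders by pull-down assay.
#' Columns: `name`, `class` (annotated NES class; `-` for engineered
#' mutants), `start`/`end` (residue span in the source protein), `sequence`,
#' `phi_registry` (annotated hydrophobic registry as local 1-based
#' positions, comma-separated; NA where the annotation is ambiguous),
#' `kd_nM` (NA for non-binders), `binder`, `consensus_fit` (FALSE for
#' entries annotated as not fitting the consensus), `note`
#' (engineered/unpublished annotations).
#'
#' @param path Path to the fixture (default: the packaged copy). The file's
#'   md5 checksum is verified against the packaged table's.
#' @return A tibble with 37 entries.
#' @export
load_affinity_benchmark <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crm1_nes_affinity_benchmark.tsv",
      package = "nescan", mustWork = TRUE)
  }
  sum <- unname(tools::md5sum(path))
  expected <- "c32b2429cf8bedf95f7efe2c7b4936ad"
  if (!identical(sum, expected)) {
    validation_error("affinity benchmark fixture is corrupted (md5 %s)", sum)
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      name = "c", class = "c", start = "i", end = "i", sequence = "c",
      phi_registry = "c", kd_nM = "d", binder = "l", consensus_fit = "l",
      note = "c"
    ))
  as_tibble(x)
}

#' Correlate binding scores with ln(K_D)
#'
#' Ordinary least squares of `ln(K_D)` on the score, with the Pearson
#' correlation and its two-sided test.
#'
#' @param scores Binding scores (lower = stronger predicted binding).
#' @param kd_nM Dissociation constants in nM (all > 0).
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `slope`,
#'   `intercept`, `n`.
#' @export
correlate_lnkd <- function(scores, kd_nM) {
  n <- length(scores)
  if (n != length(kd_nM) || n < 3L) {
    validation_error("need at least 3 paired observations")
  }
  if (any(!is.finite(scores)) || any(!is.finite(kd_nM)) || any(kd_nM <= 0)) {
    validation_error("scores must be finite and K_D values positive")
  }
  lnkd <- log(kd_nM)
  if (stats::sd(scores) == 0 || stats::sd(lnkd) == 0) {
    validation_error("zero variance in scores or ln(K_D)")
  }
  fit <- stats::lm(lnkd ~ scores)
  ct <- stats::cor.test(scores, lnkd)
  tibble(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)[[2L]]),
    intercept = unname(stats::coef(fit)[[1L]]),
    n = n
  )
}

#' Confusion metrics from counts
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A one-row tibble with the counts plus `tpr` (recall/sensitivity),
#'   `tnr` (specificity), `precision`, `f1` and `dor` (diagnostic odds
#'   ratio, `Inf` with `dor_degenerate = TRUE` when `fp * fn = 0`).
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(tpr) && (precision + tpr) > 0) {
    2 * precision * tpr / (precision + tpr)
  } else NA_real_
  degenerate <- fp * fn == 0
  dor <- if (degenerate) Inf else (tp * tn) / (fp * fn)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, tnr = tnr,
    precision = precision, f1 = f1, dor = dor, dor_degenerate = degenerate)
}

#' Confusion metrics of a score-based binder prediction
#'
#' Scores at or below `threshold` predict a binder (lower binding energy =
#' more stable complex).
#'
#' @param scores Finite scores.
#' @param labels Logical true-binder labels.
#' @param threshold Decision threshold.
#' @return A one-row metrics tibble (see [metrics_from_counts()]) with a
#'   `threshold` column.
#' @export
confusion <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
    is.logical(labels))
  pred <- scores <= threshold
  out <- metrics_from_counts(
    tp = sum(pred & labels), fp = sum(pred & !labels),
    tn = sum(!pred & !labels), fn = sum(!pred & labels)
  )
  out$threshold <- threshold
  out
}

#' Metrics at every distinct score threshold
#'
#' @param scores Finite scores.
#' @param labels Logical labels with at least one positive and one negative.
#' @return A tibble with one metrics row per distinct score value.
#' @export
sweep_threshold <- function(scores, labels) {
  stopifnot(any(labels), any(!labels))
  cuts <- sort(unique(scores))
  bind_rows(lapply(cuts, function(th) confusion(scores, labels, th)))
}
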
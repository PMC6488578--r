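# ggplot2 displays for the main result types.

#' Segment map of consensus matches
#'
#' One horizontal bar per match (extraction window), colored by priority,
#' with the registry Phi positions marked.
#'
#' @param matches Match tibble from [nes_scan()].
#' @return A ggplot object.
#' @export
plot_matches <- function(matches) {
  stopifnot(nrow(matches) > 0L)
  m <- matches
  m$row <- factor(sprintf("%s %s@%d", m$protein_id, m$class_id, m$seg_start),
    levels = unique(sprintf("%s %s@%d", m$protein_id, m$class_id, m$seg_start)))
  phi <- tidyr::pivot_longer(
    m[, c("row", "phi1", "phi2", "phi3", "phi4")],
    cols = tidyr::starts_with("phi"), values_to = "pos")
  ggplot2::ggplot(m) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$seg_start, xend = .data$seg_end,
      y = .data$row, yend = .data$row, color = factor(.data$priority)),
      linewidth = 3) +
    ggplot2::geom_point(data = phi, ggplot2::aes(x = .data$pos, y = .data$row),
      shape = 124, size = 3) +
    ggplot2::labs(x = "residue", y = NULL, color = "priority") +
    ggplot2::theme_minimal()
}

#' Disorder profile with annotated segments
#'
#' Plots the per-residue disorder propensities with the order cutoff and
#' overlays the lookup-table segments, distinguishing highlighted rows.
#'
#' @param rows Lookup table from [run_protein()] (or annotated matches).
#' @param tracks Named list with `disopred` and `spotd` track tibbles.
#' @param cutoff Order/disorder cutoff drawn as a reference line (0.1).
#' @return A ggplot object.
#' @export
plot_context_profile <- function(rows, tracks, cutoff = 0.1) {
  prof <- bind_rows(
    tibble(residue = tracks$disopred$residue,
      propensity = tracks$disopred$propensity, predictor = "disopred"),
    tibble(residue = tracks$spotd$residue,
      propensity = tracks$spotd$propensity, predictor = "spotd")
  )
  p <- ggplot2::ggplot(prof,
    ggplot2::aes(x = .data$residue, y = .data$propensity,
      color = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2) +
    ggplot2::labs(x = "residue", y = "disorder propensity") +
    ggplot2::theme_minimal()
  if (nrow(rows) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = rows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$seg_start, xmax = .data$seg_end,
        ymin = -0.08, ymax = -0.02, fill = .data$highlighted))
  }
  p
}

#' Score vs ln(K_D) scatter with the fitted line
#'
#' @param scores Binding scores.
#' @param kd_nM Dissociation constants (nM).
#' @return A ggplot object.
#' @export
plot_benchmark_fit <- function(scores, kd_nM) {
  fit <- correlate_lnkd(scores, kd_nM)
  df <- tibble(score = scores, lnkd = log(kd_nM))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$lnkd)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
      color = "steelblue") +
    ggplot2::labs(x = "binding score", y = "ln(K_D)",
      subtitle = sprintf("r = %.3f, R^2 = %.3f, p = %.2g",
        fit$r, fit$r_squared, fit$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_benchmark_fit autoplot method for binding-energy results:
#'   per-template replicate energies with the per-template means.
#' @param object An `nes_binding` result.
#' @param ... Ignored.
#' @method autoplot nes_binding
#' @export
autoplot.nes_binding <- function(object, ...) {
  eb <- object$per_template_runs
  runs <- tibble(
    template_id = rep(rownames(eb), ncol(eb)),
    run = rep(seq_len(ncol(eb)), each = nrow(eb)),
    e_bind = as.vector(eb)
  )
  means <- tidy(object)
  ggplot2::ggplot(runs,
    ggplot2::aes(x = .data$template_id, y = .data$e_bind)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = means, color = "firebrick", shape = 95,
      size = 8) +
    ggplot2::labs(x = "template", y = "E_bind",
      subtitle = sprintf("best: %s (class %s)", object$best_template,
        object$best_class)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
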
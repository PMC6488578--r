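#' Per-residue order/disorder labeling
#'
#' A residue is labeled ordered (`O`) iff its disorder propensities from both
#' primary predictors (DISOPRED3-style and SPOT-Disorder-style tracks) are
#' strictly below `cutoff`; otherwise it is potentially disordered (`D`).
#' IUPred-style values are carried for reporting only and never enter the
#' call.
#'
#' @param disopred,spotd Disorder-track tibbles ([read_disorder_track()]).
#' @param cutoff Strict order/disorder cutoff (default 0.1).
#' @return A tibble with columns `residue` and `label` (`O`/`D`).
#' @export
order_labels <- function(disopred, spotd, cutoff = 0.1) {
  if (nrow(disopred) != nrow(spotd)) {
    validation_error("disorder tracks differ in length (%d vs %d)",
      nrow(disopred), nrow(spotd))
  }
  tibble(
    residue = disopred$residue,
    label = ifelse(disopred$propensity < cutoff & spotd$propensity < cutoff, "O", "D")
  )
}

#' Classify a segment's disorder location
#'
#' Over the window made of the segment plus `flank` residues on each side
#' (truncated at the termini; only existing residues count in the
#' denominator): `DISO` if the D-fraction exceeds `frac`, `ORD` if the
#' O-fraction exceeds `frac`, else `boundary`.
#'
#' @param labeling Labeling tibble from [order_labels()].
#' @param seg_start,seg_end Segment bounds (1-based inclusive).
#' @param flank Flanking residues on each side (default 20).
#' @param frac Dominance fraction (default 0.9).
#' @return One of `"DISO"`, `"boundary"`, `"ORD"`.
#' @export
segment_location <- function(labeling, seg_start, seg_end, flank = 20L, frac = 0.9) {
  L <- nrow(labeling)
  stopifnot(seg_start >= 1L, seg_end <= L, seg_start <= seg_end)
  win <- labeling$label[max(1L, seg_start - flank):min(L, seg_end + flank)]
  d_frac <- mean(win == "D")
  if (d_frac > frac) "DISO" else if ((1 - d_frac) > frac) "ORD" else "boundary"
}

#' Classify a segment's location relative to conserved domains
#'
#' `NA` if the segment overlaps no domain. Otherwise the longest overlapping
#' domain governs: `small` if that domain is shorter than `small_len`
#' residues; `MID` if the segment lies entirely inside it with more than
#' `edge` residues to both domain ends; else `boundary`.
#'
#' @param domains Domain tibble ([read_domains()]).
#' @param seg_start,seg_end Segment bounds.
#' @param edge Margin (residues) defining the domain end region (default 5).
#' @param small_len Domains shorter than this are `small` (default 50).
#' @return One of `"MID"`, `"boundary"`, `"small"`, `"NA"`.
#' @export
domain_location <- function(domains, seg_start, seg_end, edge = 5L, small_len = 50L) {
  if (is.null(domains) || nrow(domains) == 0L) return("NA")
  ov <- domains[domains$start <= seg_end & domains$end >= seg_start, , drop = FALSE]
  if (nrow(ov) == 0L) return("NA")
  lens <- ov$end - ov$start + 1L
  d <- ov[which.max(lens), ]
  if ((d$end - d$start + 1L) < small_len) return("small")
  inside <- seg_start >= d$start & seg_end <= d$end
  deep <- (seg_start - d$start) > edge & (d$end - seg_end) > edge
  if (inside && deep) "MID" else "boundary"
}

#' Beta-strand content of a match's middle region
#'
#' Fraction of residues predicted as strand (`E`) over the middle of the
#' segment, defined as the closed Phi1-Phi4 registry span.
#'
#' @param ss SS tibble ([read_ss2()]).
#' @param phi1,phi4 Registry bounds (order-free; reverse matches allowed).
#' @return Fraction in \[0, 1\].
#' @export
beta_content <- function(ss, phi1, phi4) {
  lo <- min(phi1, phi4); hi <- max(phi1, phi4)
  stopifnot(lo >= 1L, hi <= nrow(ss))
  mean(ss$state[lo:hi] == "E")
}

#' Annotate matches with their structural context
#'
#' Adds, per match: the disorder location (`loc_diso`), the conserved-domain
#' location (`loc_cdd`), the beta-strand content of the Phi1-Phi4 middle
#' (`beta`), the mean disorder propensity of each predictor over the segment
#' (`diso_avg`, `spotd_avg`, `iup_avg`), display flags and the highlight
#' decision. Flags: `_D` when the segment is in the disordered or boundary
#' region, `_O` when in the ordered region, `_beta` when `beta > beta_cut`.
#' A segment is highlighted iff it is not in the ordered region and
#' `beta <= beta_cut` (the accessible, non-strand segments that the
#' structure stage scores).
#'
#' @param matches Match tibble from [nes_scan()].
#' @param labeling Labeling from [order_labels()] (or NULL to compute from
#'   tracks).
#' @param domains Domain tibble or NULL (no annotation: `loc_cdd = "NA"`).
#' @param ss SS tibble or NULL (then `beta = NA` and the beta criterion is
#'   treated as passing).
#' @param tracks Named list with disorder tracks `disopred`, `spotd`, `iup`
#'   (`iup` optional).
#' @param flank,frac,edge,small_len,beta_cut Rule parameters (defaults 20,
#'   0.9, 5, 50, 0.5).
#' @return `matches` with the context columns appended.
#' @export
annotate_context <- function(matches, labeling = NULL, domains = NULL, ss = NULL,
                             tracks, flank = 20L, frac = 0.9, edge = 5L,
                             small_len = 50L, beta_cut = 0.5) {
  if (is.null(labeling)) {
    labeling <- order_labels(tracks$disopred, tracks$spotd)
  }
  n <- nrow(matches)
  loc_diso <- character(n); loc_cdd <- character(n); beta <- numeric(n)
  diso_avg <- numeric(n); spotd_avg <- numeric(n); iup_avg <- numeric(n)
  seg_mean <- function(track, a, b) {
    if (is.null(track)) return(NA_real_)
    mean(track$propensity[a:b])
  }
  for (i in seq_len(n)) {
    a <- matches$seg_start[[i]]; b <- matches$seg_end[[i]]
    loc_diso[[i]] <- segment_location(labeling, a, b, flank = flank, frac = frac)
    loc_cdd[[i]] <- domain_location(domains, a, b, edge = edge, small_len = small_len)
    beta[[i]] <- if (is.null(ss)) NA_real_ else
      beta_content(ss, matches$phi1[[i]], matches$phi4[[i]])
    diso_avg[[i]] <- seg_mean(tracks$disopred, a, b)
    spotd_avg[[i]] <- seg_mean(tracks$spotd, a, b)
    iup_avg[[i]] <- seg_mean(tracks$iup, a, b)
  }
  beta_ok <- is.na(beta) | beta <= beta_cut
  flags <- purrr::map2_chr(loc_diso, beta_ok, function(ld, bok) {
    f <- if (ld == "ORD") "_O" else "_D"
    if (!bok) f <- paste0(f, ",_beta")
    f
  })
  matches$loc_diso <- loc_diso
  matches$loc_cdd <- loc_cdd
  matches$beta <- beta
  matches$diso_avg <- diso_avg
  matches$spotd_avg <- spotd_avg
  matches$iup_avg <- iup_avg
  matches$flags <- flags
  matches$highlighted <- loc_diso != "ORD" & beta_ok
  matches
}
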
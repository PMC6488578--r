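TA_SET <- c("T", "A")
BULKY_SET <- c("L", "F", "M")
ALL_CLASS_IDS <- c("1a", "1b", "1c", "1d", "2", "3", "4", "1a-R", "1c-R")

# Forward slot templates. Spacer codes between Phi slots:
#   "any"  - any residue (including X),
#   "nopw" - any standard residue except Pro/Trp (X never satisfies it).
# The no-PW restriction covers only the Phi2->Phi4 spacers; the Phi1->Phi2
# spacer is unrestricted (Pro there is legal, e.g. the Cyclin D1 PTD spacer).
# Reverse classes mirror a forward template onto the reversed sequence, which
# places the no-PW spacers on the Phi0-x-Phi1-[x]n-Phi2 stretch as read
# forward, and add the bulky-residue rule at the P0/P1 register.
class_slot_table <- function() {
  spec <- function(class_id, direction, s12, s23, s34, pro_req = FALSE,
                   bulky = FALSE, experimental = FALSE) {
    codes <- c("phi", s12, "phi", s23, "phi", s34, "phi")
    list(
      class_id = class_id, direction = direction,
      codes = codes, phi_offsets = which(codes == "phi") - 1L,
      pro_requirement = pro_req, reverse_bulky_rule = bulky,
      experimental = experimental
    )
  }
  any_ <- function(n) rep("any", n)
  nopw <- function(n) rep("nopw", n)
  list(
    `1a` = spec("1a", "forward", any_(3L), nopw(2L), nopw(1L)),
    `1b` = spec("1b", "forward", any_(2L), nopw(2L), nopw(1L)),
    `1c` = spec("1c", "forward", any_(3L), nopw(3L), nopw(1L)),
    `1d` = spec("1d", "forward", any_(2L), nopw(3L), nopw(1L)),
    `2` = spec("2", "forward", any_(1L), nopw(2L), nopw(1L)),
    `3` = spec("3", "forward", any_(2L), c("any", nopw(2L)), nopw(2L)),
    `4` = spec("4", "forward", any_(3L), nopw(2L), any_(3L), pro_req = TRUE),
    `1a-R` = spec("1a-R", "reverse", any_(3L), nopw(2L), nopw(1L), bulky = TRUE),
    `1c-R` = spec("1c-R", "reverse", any_(3L), nopw(3L), nopw(1L),
      bulky = TRUE, experimental = TRUE)
  )
}

#' Compile the NES consensus class patterns
#'
#' Builds the modified-Kosugi class set: the forward classes 1a, 1b, 1c, 1d,
#' 2, 3 and 4 plus the reverse classes 1a-R and 1c-R (mirrored templates
#' with a bulky-residue requirement). Phi slots accept Leu, Ile, Val, Met or
#' Phe; Thr or Ala may substitute at exactly one of Phi1/Phi2. Class 4
#' requires at least one Pro in its three-residue Phi3-Phi4 spacer.
#'
#' @param classes Character vector of class ids to compile (default: all 9).
#' @param phi0_offset Offset of Phi0 upstream of Phi1 in the binding frame
#'   (default 3, i.e. Phi0-x-x-Phi1).
#' @return A tibble with one row per class: `class_id`, `direction`,
#'   `phi_offsets` and `slot_codes` (list columns), `ta_allowance`,
#'   `pro_requirement`, `reverse_bulky_rule`, `experimental`, `phi0_offset`.
#' @export
nes_classes <- function(classes = NULL, phi0_offset = 3L) {
  tab <- class_slot_table()
  classes <- classes %||% names(tab)
  unknown <- setdiff(classes, names(tab))
  if (length(unknown) > 0L) {
    validation_error("unknown NES class name(s): %s", paste(unknown, collapse = ", "))
  }
  rows <- purrr::map(classes, function(cl) {
    s <- tab[[cl]]
    tibble(
      class_id = s$class_id, direction = s$direction,
      phi_offsets = list(s$phi_offsets), slot_codes = list(s$codes),
      ta_allowance = TRUE, pro_requirement = s$pro_requirement,
      reverse_bulky_rule = s$reverse_bulky_rule,
      experimental = s$experimental, phi0_offset = as.integer(phi0_offset)
    )
  })
  bind_rows(rows)
}

# Match one compiled class against one character vector (already mirrored for
# reverse classes). Returns anchors and ta bookkeeping in local coordinates.
match_class_frame <- function(chars, spec) {
  L <- length(chars)
  tmplen <- length(spec$slot_codes[[1L]])
  if (L < tmplen) {
    return(tibble(anchor = integer(), ta_used = logical(), ta_position = integer()))
  }
  offs <- spec$phi_offsets[[1L]]
  codes <- spec$slot_codes[[1L]]
  spacer_idx <- which(codes != "phi")
  anchors <- integer(); tas <- logical(); tapos <- integer()
  for (i in seq_len(L - tmplen + 1L)) {
    p <- chars[i + offs]
    if (!(p[[3L]] %in% PHI_SET && p[[4L]] %in% PHI_SET)) next
    in_phi <- p[1:2] %in% PHI_SET
    in_ta <- p[1:2] %in% TA_SET
    if (all(in_phi)) {
      ta <- FALSE; tp <- NA_integer_
    } else if (in_ta[[1L]] && in_phi[[2L]]) {
      ta <- TRUE; tp <- 1L
    } else if (in_phi[[1L]] && in_ta[[2L]]) {
      ta <- TRUE; tp <- 2L
    } else {
      next
    }
    ok <- TRUE
    for (j in spacer_idx) {
      if (codes[[j]] == "nopw" && !chars[i + j - 1L] %in% NO_PW_SET) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    if (spec$pro_requirement) {
      s34 <- chars[(i + offs[[3L]] + 1L):(i + offs[[4L]] - 1L)]
      if (!"P" %in% s34) next
    }
    if (spec$reverse_bulky_rule) {
      # Residues landing in the P0/P1 pockets: the (mirrored) Phi1 and, when
      # it exists, the unrestricted Phi0 position 3 upstream of it.
      reg <- chars[i]
      p0 <- i - spec$phi0_offset
      if (p0 >= 1L) reg <- c(reg, chars[p0])
      if (!any(reg %in% BULKY_SET)) next
    }
    anchors <- c(anchors, i); tas <- c(tas, ta); tapos <- c(tapos, tp)
  }
  tibble(anchor = anchors, ta_used = tas, ta_position = tapos)
}

scan_sequence <- function(protein_id, sequence, specs) {
  chars <- seq_chars(sequence)
  L <- length(chars)
  rev_chars <- rev(chars)
  out <- vector("list", nrow(specs))
  for (k in seq_len(nrow(specs))) {
    spec <- specs[k, ]
    frame <- if (spec$direction == "reverse") rev_chars else chars
    hits <- match_class_frame(frame, spec)
    if (nrow(hits) == 0L) next
    offs <- spec$phi_offsets[[1L]]
    phi_local <- outer(hits$anchor, offs, `+`) # registry Phi1..Phi4, local frame
    phi_orig <- if (spec$direction == "reverse") L - phi_local + 1L else phi_local
    out[[k]] <- tibble(
      protein_id = protein_id,
      class_id = spec$class_id,
      direction = spec$direction,
      phi1 = phi_orig[, 1L], phi2 = phi_orig[, 2L],
      phi3 = phi_orig[, 3L], phi4 = phi_orig[, 4L],
      ta_used = hits$ta_used, ta_position = hits$ta_position,
      phi0_offset = spec$phi0_offset
    )
  }
  bind_rows(out)
}

#' Scan sequences for NES consensus matches
#'
#' Reports every anchored placement of every compiled class template that
#' satisfies all slot constraints, including overlapping hits and multiple
#' classes at the same location. Thr/Ala substitution is applied at most once
#' per match across Phi1/Phi2. `X` residues never satisfy a Phi slot or a
#' no-PW spacer slot.
#'
#' The returned matches carry the full registry: [detect_phi0()],
#' [assign_priority()] and [extract_window()] are applied, so the result is
#' ready for context annotation.
#'
#' @param seqs Tibble with columns `id`, `sequence` (as from [read_fasta()]),
#'   or a single named character string.
#' @param specs Compiled class specs from [nes_classes()].
#' @return A tibble of matches: one row per (class, placement) with registry
#'   positions `phi0..phi4` (1-based, original coordinates; decreasing for
#'   reverse classes), `phi0_hydrophobic`, `ta_used`, `priority`,
#'   `seg_start`, `seg_end`, `seg_seq`.
#' @examples
#' nes_scan(tibble::tibble(id = "NS2", sequence = "STVDEMTKKFGTLTIHD"))
#' @export
nes_scan <- function(seqs, specs = nes_classes()) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs) %||% sprintf("seq%d", seq_along(seqs)),
      sequence = unname(seqs))
  }
  for (i in seq_len(nrow(seqs))) assert_sequence(seqs$sequence[[i]], seqs$id[[i]])
  matches <- purrr::map2(seqs$id, seqs$sequence,
    ~ scan_sequence(.x, .y, specs)) %>% bind_rows()
  if (nrow(matches) == 0L) {
    return(empty_match_tibble())
  }
  matches %>%
    detect_phi0(seqs) %>%
    assign_priority() %>%
    extract_window(seqs) %>%
    arrange(.data$protein_id, .data$seg_start, .data$priority, .data$class_id)
}

empty_match_tibble <- function() {
  tibble(
    protein_id = character(), class_id = character(), direction = character(),
    phi1 = integer(), phi2 = integer(), phi3 = integer(), phi4 = integer(),
    ta_used = logical(), ta_position = integer(), phi0_offset = integer(),
    phi0 = integer(), phi0_hydrophobic = logical(), priority = integer(),
    seg_start = integer(), seg_end = integer(), seg_seq = character()
  )
}

lookup_sequences <- function(matches, seqs) {
  idx <- match(matches$protein_id, seqs$id)
  if (anyNA(idx)) {
    validation_error("matches reference protein id(s) absent from `seqs`: %s",
      paste(unique(matches$protein_id[is.na(idx)]), collapse = ", "))
  }
  seqs$sequence[idx]
}

#' Locate the Phi0 registry position of each match
#'
#' Phi0 sits at a fixed offset upstream of Phi1 in the binding frame
#' (default 3 residues: Phi0-x-x-Phi1) and is not restricted to hydrophobic
#' residues; `phi0_hydrophobic` records whether it is one of L/I/V/M/F.
#' Phi0 is unassigned when the offset falls outside the sequence. For
#' reverse-class matches the offset is applied in the mirrored frame.
#'
#' @param matches Match tibble from the scanner.
#' @param seqs Sequence tibble (`id`, `sequence`).
#' @return `matches` with `phi0` (integer or NA) and `phi0_hydrophobic`.
#' @export
detect_phi0 <- function(matches, seqs) {
  seqv <- lookup_sequences(matches, seqs)
  L <- nchar(seqv)
  phi0 <- ifelse(matches$direction == "reverse",
    matches$phi1 + matches$phi0_offset,
    matches$phi1 - matches$phi0_offset)
  phi0 <- ifelse(phi0 >= 1L & phi0 <= L, phi0, NA_integer_)
  res <- substring(seqv, phi0, phi0)
  matches$phi0 <- as.integer(phi0)
  matches$phi0_hydrophobic <- !is.na(phi0) & res %in% PHI_SET
  matches
}

#' Assign the empirical class priority of each match
#'
#' Priorities follow the observed class abundances among validated NES
#' motifs: (1) class 1a with five Phis (hydrophobic Phi0); (2) classes
#' 1a/1c with four Phis, 1a-R, 2, 3 and 4 without Thr/Ala substitution;
#' (3) classes 1a/1c with Thr/Ala at Phi1 or Phi2; (4) classes 1b, 1d and
#' 1c-R, plus Thr/Ala-substituted 2, 3, 4 and reverse classes; (5) classes
#' 1b/1d with Thr/Ala.
#'
#' @param matches Match tibble after [detect_phi0()].
#' @return `matches` with an integer `priority` column (1-5).
#' @export
assign_priority <- function(matches) {
  pr <- purrr::pmap_int(
    list(matches$class_id, matches$ta_used, matches$phi0_hydrophobic,
      matches$direction),
    function(cl, ta, phi0h, dir) {
      if (!ta) {
        if (cl == "1a" && phi0h && dir == "forward") return(1L)
        if (cl %in% c("1a", "1c", "1a-R", "2", "3", "4")) return(2L)
        if (cl %in% c("1b", "1d", "1c-R")) return(4L)
      } else {
        if (cl %in% c("1a", "1c")) return(3L)
        if (cl %in% c("2", "3", "4", "1a-R", "1c-R")) return(4L)
        if (cl %in% c("1b", "1d")) return(5L)
      }
      abort(sprintf("unclassifiable match: class %s, ta_used=%s", cl, ta))
    }
  )
  matches$priority <- pr
  matches
}

#' Extract the segment window of each match
#'
#' The window runs from one residue before Phi0 to two residues after Phi4,
#' clamped at the sequence termini (mirrored for reverse classes). When Phi0
#' is unassigned the window starts at `Phi1 - phi0_offset - 1`.
#'
#' @param matches Match tibble after [detect_phi0()].
#' @param seqs Sequence tibble (`id`, `sequence`).
#' @return `matches` with `seg_start`, `seg_end` and `seg_seq`.
#' @export
extract_window <- function(matches, seqs) {
  seqv <- lookup_sequences(matches, seqs)
  L <- nchar(seqv)
  fwd <- matches$direction == "forward"
  up <- ifelse(is.na(matches$phi0),
    matches$phi1 + ifelse(fwd, -1L, 1L) * (matches$phi0_offset + 1L),
    matches$phi0 + ifelse(fwd, -1L, 1L))
  down <- matches$phi4 + ifelse(fwd, 2L, -2L)
  matches$seg_start <- as.integer(pmax(1L, pmin(up, down)))
  matches$seg_end <- as.integer(pmin(L, pmax(up, down)))
  matches$seg_seq <- substring(seqv, matches$seg_start, matches$seg_end)
  matches
}

#' Group matches whose windows start close together
#'
#' Matches of the same protein whose segment start positions differ by less
#' than `delta` are joined transitively into one group (connected components
#' on the start-position line). Within a group, matches are ordered by
#' priority, then start, then class id; all are retained.
#'
#' @param matches Match tibble with `seg_start`.
#' @param delta Start-difference threshold (default 5).
#' @return `matches` with an integer `group` column, reordered.
#' @export
group_overlaps <- function(matches, delta = 5L) {
  if (nrow(matches) == 0L) {
    matches$group <- integer()
    return(matches)
  }
  matches <- arrange(matches, .data$protein_id, .data$seg_start)
  grp <- integer(nrow(matches))
  g <- 0L
  for (i in seq_len(nrow(matches))) {
    new_group <- i == 1L ||
      matches$protein_id[[i]] != matches$protein_id[[i - 1L]] ||
      (matches$seg_start[[i]] - matches$seg_start[[i - 1L]]) >= delta
    if (new_group) g <- g + 1L
    grp[[i]] <- g
  }
  matches$group <- grp
  matches %>%
    group_by(.data$group) %>%
    arrange(.data$priority, .data$seg_start, .data$class_id, .by_group = TRUE) %>%
    ungroup()
}

#' Label matches as candidate NES or false positive against evidence
#'
#' A match is a candidate (`cand`) iff the closed interval spanned by its
#' Phi2-Phi4 registry positions intersects any experimental evidence
#' interval; otherwise it is a false positive (`fp`).
#'
#' @param matches Match tibble.
#' @param evidence Evidence tibble (`kind`, `start`, `end`), possibly per
#'   protein via a `protein_id` column; without one, applied to all.
#' @return `matches` with `label` and a `matched_evidence` list column of the
#'   overlapping evidence rows.
#' @export
label_candidate <- function(matches, evidence) {
  lab <- character(nrow(matches))
  hits <- vector("list", nrow(matches))
  for (i in seq_len(nrow(matches))) {
    ev <- evidence
    if ("protein_id" %in% names(ev)) {
      ev <- ev[ev$protein_id == matches$protein_id[[i]], , drop = FALSE]
    }
    lo <- min(matches$phi2[[i]], matches$phi4[[i]])
    hi <- max(matches$phi2[[i]], matches$phi4[[i]])
    ov <- ev[ev$start <= hi & ev$end >= lo, , drop = FALSE]
    lab[[i]] <- if (nrow(ov) > 0L) "cand" else "fp"
    hits[[i]] <- ov
  }
  matches$label <- lab
  matches$matched_evidence <- hits
  matches
}

#' Write a match table as TSV
#'
#' @param matches Match tibble (list columns are flattened).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  out <- matches
  out$phi_positions <- purrr::pmap_chr(
    list(out$phi0, out$phi1, out$phi2, out$phi3, out$phi4),
    function(p0, p1, p2, p3, p4) {
      paste(stats::na.omit(c(p0, p1, p2, p3, p4)), collapse = ",")
    }
  )
  out <- out[!vapply(out, is.list, logical(1L))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
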
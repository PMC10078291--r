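# Pause summits, pause indices, differential nascent transcription and
# anchored composite profiles from strand-specific signal.

# sense-strand signal in transcription coordinates p = 0 .. n-1
# (p measured downstream from the TSS; reversed for minus-strand genes)
sense_vector <- function(track, gene, from_p, to_p) {
  if (gene$strand == "+") {
    signal_window(track, gene$chrom, gene$tss + from_p, gene$tss + to_p, "+")
  } else {
    rev(signal_window(track, gene$chrom, gene$tss - to_p + 1, gene$tss - from_p + 1, "-"))
  }
}

#' Pause summit, pause region and pause index for one time point
#'
#' The pause summit is the leftmost (in the direction of transcription)
#' maximum of sense-strand signal within 1 kb downstream of the TSS;
#' the pause region is the 50-bp window `[summit - 25, summit + 25)`;
#' the gene body runs from `summit + 250` to the gene end. The pause
#' index is pause density (signal/bp) over body density.
#'
#' @param genes tibble from [read_genes()] (needs `chrom, start, end,
#'   gene, strand, tss`).
#' @param track `signal_track`.
#' @param search_bp summit search window downstream of the TSS.
#' @param pause_halfwidth half-width of the pause region (25 bp).
#' @param body_offset distance from summit to the body start (250 bp
#'   clears the pause peak and its shoulder).
#' @return tibble `gene, summit_p` (bp downstream of TSS), `summit_pos`
#'   (genomic), `pause_density, body_density, pause_index, flagged`
#'   (TRUE when the search window has no signal or the body density is
#'   zero; such genes are excluded from PI summaries).
#' @export
pause_metrics <- function(genes, track, search_bp = 1000,
                          pause_halfwidth = 25, body_offset = 250) {
  purrr::pmap_dfr(genes, function(chrom, start, end, gene, strand, tss, ...) {
    g <- list(chrom = chrom, start = start, end = end, gene = gene,
              strand = strand, tss = tss)
    glen <- if (strand == "+") end - tss else tss - start + 1
    if (glen < 2 * pause_halfwidth + body_offset + 500)
      stop_kn("gene %s too short for pause + body regions (%d bp)", gene, glen)
    v <- sense_vector(track, g, 0, search_bp)
    if (all(v == 0)) {
      return(tibble(gene = gene, summit_p = NA_integer_, summit_pos = NA_real_,
                    pause_density = NA_real_, body_density = NA_real_,
                    pause_index = NA_real_, flagged = TRUE))
    }
    sp <- which.max(v) - 1L  # leftmost max in transcription direction
    pause <- sense_vector(track, g, sp - pause_halfwidth, sp + pause_halfwidth)
    body <- sense_vector(track, g, sp + body_offset, glen)
    pd <- sum(pause) / length(pause)
    bd <- sum(body) / length(body)
    tibble(gene = gene,
           summit_p = sp,
           summit_pos = if (strand == "+") tss + sp else tss - sp,
           pause_density = pd, body_density = bd,
           pause_index = if (bd > 0) pd / bd else NA_real_,
           flagged = bd == 0)
  })
}

#' Pause metrics across all time points of a track set
#' @param genes gene tibble.
#' @param tracks tibble of signal with a `time` column (as produced by
#'   [simulate_proseq()]), or a named list of `signal_track`s.
#' @inheritParams pause_metrics
#' @export
pause_metrics_series <- function(genes, tracks, ...) {
  if (is.data.frame(tracks)) {
    tracks <- split(dplyr::select(tracks, -"time"), tracks$time)
  }
  purrr::imap_dfr(tracks, function(tr, tm) {
    dplyr::mutate(pause_metrics(genes, as_tibble(tr), ...),
                  time = as.numeric(tm), .before = 1)
  })
}

#' Differential nascent transcription between two time points
#'
#' The same count machinery as accessibility testing, applied to
#' gene-body counts; genes with zero counts in both groups are excluded
#' rather than called. Directions map to activated / repressed.
#'
#' @inheritParams differential_test
#' @export
differential_transcription <- function(counts, design, time_a, time_b,
                                       q_threshold = 0.05, factors = NULL) {
  m <- counts_to_matrix(counts)
  grp <- design$sample[design$time %in% c(time_a, time_b)]
  keep <- rowSums(m[, grp, drop = FALSE]) > 0
  res <- differential_test(m[keep, , drop = FALSE], design, time_a, time_b,
                           q_threshold = q_threshold, factors = factors)
  dplyr::mutate(res, call = dplyr::case_when(
    .data$direction == "up" ~ "activated",
    .data$direction == "down" ~ "repressed",
    TRUE ~ "unchanged"))
}

#' @rdname differential_transcription
#' @inheritParams differential_series
#' @export
transcription_series <- function(counts, design, comparisons = "all",
                                 q_threshold = 0.05) {
  m <- counts_to_matrix(counts)
  keep <- rowSums(m) > 0
  res <- differential_series(m[keep, , drop = FALSE], design, comparisons,
                             q_threshold = q_threshold)
  dplyr::mutate(res, call = dplyr::case_when(
    .data$direction == "up" ~ "activated",
    .data$direction == "down" ~ "repressed",
    TRUE ~ "unchanged"))
}

#' Composite signal profile around anchor positions
#'
#' Averages strand-specific signal over a symmetric window around each
#' anchor, in the anchor's orientation: "sense" is the anchor strand
#' and "antisense" the other; for minus-strand anchors offsets run
#' against the genomic axis so composites from mirrored anchors align.
#' Anchors whose window would cross position 0 are clipped, with
#' per-offset denominators.
#'
#' @param anchors tibble with `chrom, pos, strand` (0-based positions).
#' @param track `signal_track`.
#' @param half_window window half-width, bp.
#' @return tibble `offset, orientation, mean_signal, n`; class
#'   `composite_profile`.
#' @export
composite_profile <- function(anchors, track, half_window = 500) {
  assert_that(nrow(anchors) > 0, "composite_profile: empty anchor list")
  offs <- -half_window:half_window
  acc <- matrix(0, nrow = length(offs), ncol = 2,
                dimnames = list(NULL, c("sense", "antisense")))
  cnt <- matrix(0L, nrow = length(offs), ncol = 2,
                dimnames = list(NULL, c("sense", "antisense")))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    dirn <- if (a$strand == "-") -1L else 1L
    pos <- a$pos + dirn * offs
    ok <- pos >= 0
    for (orient in c("sense", "antisense")) {
      st <- if (orient == "sense") a$strand else setdiff(c("+", "-"), a$strand)
      v <- signal_query(track, a$chrom, pos[ok], st)
      acc[ok, orient] <- acc[ok, orient] + v
      cnt[ok, orient] <- cnt[ok, orient] + 1L
    }
  }
  out <- tidyr::expand_grid(orientation = c("sense", "antisense"), offset = offs) |>
    dplyr::mutate(
      mean_signal = purrr::map2_dbl(.data$orientation, .data$offset, function(o, d) {
        i <- match(d, offs)
        if (cnt[i, o] == 0) 0 else acc[i, o] / cnt[i, o]
      }),
      n = purrr::map2_int(.data$orientation, .data$offset,
                          function(o, d) cnt[match(d, offs), o]))
  structure(out, class = c("composite_profile", class(tibble())))
}

#' Simple divergent-transcription peak caller
#'
#' Labels positions where both strands exceed `threshold` within
#' `max_gap` bp and the minus-strand peak lies upstream of the
#' plus-strand peak. This is a deliberately simple bidirectional-signal
#' heuristic for synthetic data and is not equivalent to SVM-based
#' regulatory-element detection on real nascent-transcription data.
#'
#' @param track `signal_track`.
#' @param threshold minimum signal on each strand.
#' @param max_gap maximum distance between the paired peaks, bp.
#' @return tibble `chrom, minus_pos, plus_pos, center`.
#' @export
call_divergent_peaks <- function(track, threshold = 0.1, max_gap = 300) {
  plus <- dplyr::filter(track, .data$strand == "+", .data$value >= threshold)
  minus <- dplyr::filter(track, .data$strand == "-", .data$value >= threshold)
  if (nrow(plus) == 0 || nrow(minus) == 0)
    return(tibble(chrom = character(), minus_pos = numeric(),
                  plus_pos = numeric(), center = numeric()))
  plus <- dplyr::mutate(plus, peak_pos = (.data$start + .data$end) / 2)
  minus <- dplyr::mutate(minus, peak_pos = (.data$start + .data$end) / 2)
  dplyr::inner_join(
    dplyr::select(minus, "chrom", minus_pos = "peak_pos"),
    dplyr::select(plus, "chrom", plus_pos = "peak_pos"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$plus_pos - .data$minus_pos >= 0,
                  .data$plus_pos - .data$minus_pos <= max_gap) |>
    dplyr::mutate(center = (.data$minus_pos + .data$plus_pos) / 2)
}
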
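# Log-odds PWM scanning with exact score-distribution p-values.
#
# Scores are log2(p_base / background) summed over positions; N bases
# contribute 0 (background). P-values come from the exact distribution
# of the score of a random background window, computed by dynamic
# programming on a discretized score lattice (FIMO's approach).

pwm_logodds <- function(pwm, pseudo = 1e-3) {
  # small pseudo-probability keeps log-odds finite for 0 entries
  p <- (pwm$mat + pseudo) / (1 + 4 * pseudo)
  log2(sweep(p, 2, pwm$background, "/"))
}

#' Exact null distribution of PWM window scores
#'
#' Discretizes per-position log-odds scores onto an integer lattice of
#' `bins` steps spanning the full score range, then convolves the
#' per-position distributions under the background model. The returned
#' table maps every achievable lattice score to its tail probability
#' `P(score >= s)` for a random background window.
#'
#' @param pwm a `pwm_model`.
#' @param bins lattice resolution (default 1000).
#' @return list with `delta` (lattice step in score units), `offsets`
#'   (integer per-position score matrix), and `tail` (tibble of
#'   `score_int`, `prob`, `pvalue`).
#' @export
pwm_score_distribution <- function(pwm, bins = 1000) {
  lo <- pwm_logodds(pwm)
  rng <- sum(apply(lo, 1, max)) - sum(apply(lo, 1, min))
  delta <- if (rng > 0) rng / bins else 1
  oi <- round(sweep(lo, 1, apply(lo, 1, min)) / delta)  # >= 0 integers
  base_int <- sum(round(apply(lo, 1, min) / delta))     # lattice origin
  # DP convolution over positions
  dist <- 1
  for (i in seq_len(nrow(oi))) {
    pos <- numeric(max(oi[i, ]) + 1)
    for (j in 1:4) pos[oi[i, j] + 1] <- pos[oi[i, j] + 1] + pwm$background[j]
    dist <- if (length(dist) == 1L && identical(dist, 1)) pos else
      stats::convolve(dist, rev(pos), type = "open")
  }
  dist <- pmax(dist, 0)
  dist <- dist / sum(dist)
  score_int <- seq_along(dist) - 1 + base_int
  tail <- rev(cumsum(rev(dist)))
  list(delta = delta, offsets = oi, base_int = base_int,
       tail = tibble(score_int = score_int, prob = dist, pvalue = pmin(tail, 1)))
}

revcomp <- function(seqs) {
  vapply(seqs, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

scan_one_strand <- function(seq_int, lo) {
  L <- nrow(lo)
  n <- length(seq_int)
  if (n < L) return(tibble(offset = integer(), score = numeric()))
  nw <- n - L + 1
  scores <- numeric(nw)
  for (j in seq_len(L)) {
    col <- unname(lo[j, ])[seq_int[j:(j + nw - 1)]]
    col[is.na(col)] <- 0  # N contributes background odds
    scores <- scores + col
  }
  tibble(offset = 0:(nw - 1), score = scores)
}

#' Scan sequences with a PWM on both strands
#'
#' Reports windows whose exact p-value is at most `p_threshold`
#' (default 1e-4, the standard genome-scanning regime). The p-value is
#' evaluated on the discretized score lattice of
#' [pwm_score_distribution()].
#'
#' @param sequences tibble with columns `peak` and `seq` (A/C/G/T/N),
#'   or a named character vector.
#' @param pwm a `pwm_model`.
#' @param p_threshold report hits with `pvalue <= p_threshold`.
#' @param bins score-lattice resolution.
#' @return tibble of hits: `peak, offset` (0-based motif start on the
#'   forward sequence), `strand, score, pvalue, score_fraction`
#'   (score / maximum achievable score).
#' @export
scan_pwm <- function(sequences, pwm, p_threshold = 1e-4, bins = 1000) {
  if (is.character(sequences))
    sequences <- tibble(peak = names(sequences) %||% as.character(seq_along(sequences)),
                        seq = unname(sequences))
  lo <- pwm_logodds(pwm)
  L <- nrow(lo)
  sd <- pwm_score_distribution(pwm, bins = bins)
  # minimal lattice score with tail probability <= threshold
  ok <- sd$tail$pvalue <= p_threshold
  if (!any(ok)) return(tibble(peak = character(), offset = integer(), strand = character(),
                              score = numeric(), pvalue = numeric(), score_fraction = numeric()))
  min_int <- min(sd$tail$score_int[ok])
  max_score <- sum(apply(lo, 1, max))
  to_int <- function(seq_int, sc_tbl) {
    # recompute on the lattice for exact threshold/pvalue agreement
    nw <- nrow(sc_tbl)
    if (nw == 0) return(integer())
    ints <- integer(nw)
    for (j in seq_len(L)) {
      col <- unname(sd$offsets[j, ])[seq_int[j:(j + nw - 1)]]
      col[is.na(col)] <- round(-min(lo[j, ]) / sd$delta) # N ~ score 0
      ints <- ints + col
    }
    ints + sd$base_int
  }
  pv_lookup <- setNames(sd$tail$pvalue, sd$tail$score_int)
  out <- purrr::map2_dfr(sequences$peak, sequences$seq, function(id, sq) {
    fwd_int <- match(strsplit(toupper(sq), "")[[1]], c("A", "C", "G", "T"))
    rev_int <- match(strsplit(revcomp(toupper(sq)), "")[[1]], c("A", "C", "G", "T"))
    n <- length(fwd_int)
    res <- list()
    for (st in c("+", "-")) {
      si <- if (st == "+") fwd_int else rev_int
      sc <- scan_one_strand(si, lo)
      if (nrow(sc) == 0) next
      ints <- to_int(si, sc)
      keep <- ints >= min_int
      if (!any(keep)) next
      off <- sc$offset[keep]
      if (st == "-") off <- n - L - off
      res[[st]] <- tibble(peak = id, offset = off, strand = st,
                          score = sc$score[keep],
                          pvalue = unname(pv_lookup[as.character(ints[keep])]),
                          score_fraction = sc$score[keep] / max_score)
    }
    dplyr::bind_rows(res)
  })
  if (nrow(out) == 0)
    return(tibble(peak = character(), offset = integer(), strand = character(),
                  score = numeric(), pvalue = numeric(), score_fraction = numeric()))
  dplyr::arrange(out, .data$peak, .data$offset, .data$strand)
}

#' Scan a set of PWMs and label hits by family
#' @param sequences as in [scan_pwm()].
#' @param pwms named list of `pwm_model` objects.
#' @inheritParams scan_pwm
#' @return tibble of hits with a `family` column.
#' @export
scan_pwm_set <- function(sequences, pwms, p_threshold = 1e-4, bins = 1000) {
  purrr::imap_dfr(pwms, function(m, nm) {
    h <- scan_pwm(sequences, m, p_threshold = p_threshold, bins = bins)
    if (nrow(h)) dplyr::mutate(h, family = nm, width = nrow(m$mat), .before = 1) else NULL
  })
}

#' Motif density around peak summits, by peak class
#'
#' For each class, the trace value at offset `d` is the sum over peaks
#' of score-fraction-weighted hits whose motif midpoint falls at
#' `summit + d`, divided by the number of peaks in the class.
#'
#' @param peaks tibble with `peak, summit` (offset from start) and a
#'   `class` column (e.g. increased / decreased / nondynamic).
#' @param hits tibble from [scan_pwm()] (plus `width` column or pass
#'   `motif_width`).
#' @param half_window window half-width in bp.
#' @param motif_width motif length used to place the hit midpoint.
#' @return tibble `class, offset, density`; class `motif_density`.
#' @export
motif_density <- function(peaks, hits, half_window = 500, motif_width = NULL) {
  assert_that(nrow(peaks) > 0, "motif_density: empty peak set")
  cls <- dplyr::count(peaks, .data$class, name = "n_peaks")
  assert_that(all(cls$n_peaks > 0), "motif_density: empty class")
  w <- motif_width %||% hits$width[1] %||% 0
  joined <- dplyr::inner_join(hits, dplyr::select(peaks, "peak", "summit", "class"),
                              by = "peak") |>
    dplyr::mutate(offset_from_summit = .data$offset + floor(w / 2) - .data$summit) |>
    dplyr::filter(abs(.data$offset_from_summit) <= half_window)
  grid <- tidyr::expand_grid(class = cls$class, offset = -half_window:half_window)
  dens <- joined |>
    dplyr::group_by(.data$class, offset = .data$offset_from_summit) |>
    dplyr::summarise(wsum = sum(.data$score_fraction), .groups = "drop")
  out <- grid |>
    dplyr::left_join(dens, by = c("class", "offset")) |>
    dplyr::left_join(cls, by = "class") |>
    dplyr::mutate(density = dplyr::coalesce(.data$wsum, 0) / .data$n_peaks) |>
    dplyr::select("class", "offset", "density")
  structure(out, class = c("motif_density", class(tibble())))
}

#' Assign opener/closer function to TF families from single-motif peaks
#'
#' Restricting to dynamic peaks that contain exactly one family's motif
#' isolates each family's association with accessibility direction: a
#' family is an `opener` if more than half of its single-motif dynamic
#' peaks fall in increase classes, a `closer` if more than half fall in
#' decrease classes, and `unassigned` otherwise (including exact ties).
#'
#' @param peaks tibble with `peak` and `class` columns (kinetic classes
#'   from [classify_kinetics()]).
#' @param hits multi-family hit table from [scan_pwm_set()].
#' @return list with `functions` (tibble `family, n_single_motif,
#'   frac_increase, frac_decrease, role`) and `single_motif_peaks`.
#' @export
assign_direction <- function(peaks, hits) {
  inc <- c("immediate_increase", "transient_increase", "gradual_increase")
  dec <- c("transient_decrease", "gradual_decrease")
  dynamic <- dplyr::filter(peaks, .data$class %in% c(inc, dec))
  fam_per_peak <- hits |>
    dplyr::distinct(.data$peak, .data$family) |>
    dplyr::count(.data$peak, name = "n_families")
  single <- dynamic |>
    dplyr::inner_join(fam_per_peak, by = "peak") |>
    dplyr::filter(.data$n_families == 1L) |>
    dplyr::inner_join(dplyr::distinct(hits, .data$peak, .data$family), by = "peak")
  fns <- single |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_single_motif = dplyr::n(),
      frac_increase = mean(.data$class %in% inc),
      frac_decrease = mean(.data$class %in% dec),
      .groups = "drop") |>
    dplyr::mutate(role = dplyr::case_when(
      .data$frac_increase > 0.5 ~ "opener",
      .data$frac_decrease > 0.5 ~ "closer",
      TRUE ~ "unassigned"))
  all_fams <- sort(unique(hits$family))
  missing <- setdiff(all_fams, fns$family)
  if (length(missing))
    fns <- dplyr::bind_rows(fns, tibble(family = missing, n_single_motif = 0L,
                                        frac_increase = NA_real_, frac_decrease = NA_real_,
                                        role = "unassigned"))
  list(functions = dplyr::arrange(fns, .data$family),
       single_motif_peaks = dplyr::select(single, "peak", "family", "class"))
}
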
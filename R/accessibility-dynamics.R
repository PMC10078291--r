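# Count normalization, differential testing, and kinetic classification
# for replicated accessibility (and nascent transcription) time courses.

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  assert_that("peak" %in% names(counts) || "gene" %in% names(counts),
              "counts must be a matrix or a tibble with a peak/gene id column")
  id_col <- if ("peak" %in% names(counts)) "peak" else "gene"
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  rownames(m) <- counts[[id_col]]
  m
}

#' Median-of-ratios size factors
#'
#' For each sample `j`, `factor_j` is the median over features `i` of
#' `counts_ij / g_i`, where `g_i` is the geometric mean of feature `i`
#' across samples; only features positive in every sample contribute.
#' Multiplying one column by `c` multiplies its factor by `c` and leaves
#' the others unchanged.
#'
#' @param counts feature x sample count matrix, or tibble with a
#'   `peak`/`gene` id column.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop_kn("no feature with positive counts in every sample; consider adding a pseudocount")
  lg <- log(m[pos, , drop = FALSE])
  gmean <- rowMeans(lg)
  apply(exp(sweep(lg, 1, gmean)), 2, median)
}

#' @rdname size_factors
#' @param factors optional precomputed factors.
#' @return `normalize_counts()`: matrix of counts divided by their
#'   sample's size factor.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- counts_to_matrix(counts)
  sf <- factors %||% size_factors(m)
  sweep(m, 2, sf, "/")
}

# method-of-moments NB dispersion with log-linear trend shrinkage:
# alpha_hat_i = max(0, (s2_i - mu_i)/mu_i^2), shrunk 50/50 on the log
# scale toward a log-linear fit of alpha_hat on mean
shrunk_dispersion <- function(mu, s2, floor = 1e-8) {
  alpha_raw <- pmax((s2 - mu) / mu^2, 0)
  use <- is.finite(alpha_raw) & alpha_raw > 0 & mu > 0
  alpha_fit <- rep(if (any(use)) mean(alpha_raw[use]) else floor, length(mu))
  if (sum(use) >= 10) {
    fit <- lm(log(alpha_raw[use]) ~ log(mu[use]))
    alpha_fit <- exp(coef(fit)[1] + coef(fit)[2] * log(pmax(mu, floor)))
  }
  alpha_floor <- pmax(alpha_raw, floor)
  exp(0.5 * log(alpha_floor) + 0.5 * log(pmax(alpha_fit, floor)))
}

#' Differential test between two time points
#'
#' Per-feature negative-binomial Wald test on the log2 ratio of
#' normalized group means. Dispersion is estimated by method of moments
#' from within-group residuals and shrunk 50/50 (log scale) toward a
#' log-linear mean-dispersion trend. P-values are Benjamini-Hochberg
#' corrected within the comparison.
#'
#' @param counts feature x sample counts (matrix or tibble with
#'   `peak`/`gene` column).
#' @param design tibble with `sample`, `time` (and optionally
#'   `replicate`) matching the count columns.
#' @param time_a,time_b the two time points to compare (minutes).
#' @param q_threshold BH threshold for calling a direction.
#' @param factors optional size factors (defaults to median-of-ratios
#'   over the full matrix).
#' @return tibble with `feature, time_a, time_b, base_mean, log2fc,
#'   stat, pvalue, qvalue, direction` (`up`/`down`/`none`).
#' @export
differential_test <- function(counts, design, time_a, time_b,
                              q_threshold = 0.05, factors = NULL) {
  m <- counts_to_matrix(counts)
  assert_that(all(design$sample %in% colnames(m)),
              "design samples missing from count columns")
  sa <- design$sample[design$time == time_a]
  sb <- design$sample[design$time == time_b]
  assert_that(length(sa) >= 2 && length(sb) >= 2,
              "at least two replicates per time point are required (no dispersion estimate otherwise)")
  norm <- normalize_counts(m, factors = factors %||% size_factors(m))
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(norm[, sa, drop = FALSE])
  mb <- rowMeans(norm[, sb, drop = FALSE])
  # pooled within-group second moment
  ssa <- rowSums((norm[, sa, drop = FALSE] - ma)^2)
  ssb <- rowSums((norm[, sb, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / (na + nb - 2)
  mu <- (na * ma + nb * mb) / (na + nb)
  alpha <- shrunk_dispersion(mu, s2)
  # Haldane-style continuity on the group means stabilizes zero groups
  ma2 <- ma + 0.5; mb2 <- mb + 0.5
  lfc <- log2(mb2 / ma2)
  se_ln <- sqrt(1 / (na * ma2) + alpha / na + 1 / (nb * mb2) + alpha / nb)
  stat <- (lfc * log(2)) / se_ln
  p <- 2 * pnorm(-abs(stat))
  p[mu == 0] <- 1
  q <- p.adjust(p, method = "BH")
  feature <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tibble(feature = feature, time_a = time_a, time_b = time_b,
         base_mean = unname(mu), log2fc = unname(lfc), stat = unname(stat),
         pvalue = unname(p), qvalue = unname(q),
         direction = dplyr::case_when(
           q <= q_threshold & lfc > 0 ~ "up",
           q <= q_threshold & lfc < 0 ~ "down",
           TRUE ~ "none"))
}

#' All-pairs differential calls across a time course
#'
#' Runs [differential_test()] for every requested pair of time points,
#' with size factors computed once from the full matrix.
#'
#' @inheritParams differential_test
#' @param comparisons "all", "baseline" (each vs the first time point)
#'   or "consecutive"; or a tibble with `time_a`, `time_b` columns.
#' @export
differential_series <- function(counts, design, comparisons = "all",
                                q_threshold = 0.05) {
  m <- counts_to_matrix(counts)
  sf <- size_factors(m)
  cmp <- if (is.character(comparisons))
    time_comparisons(design$time, comparisons) else as_tibble(comparisons)
  purrr::pmap_dfr(cmp, function(time_a, time_b) {
    differential_test(m, design, time_a, time_b,
                      q_threshold = q_threshold, factors = sf)
  })
}

#' Assign kinetic response classes to peaks
#'
#' Deterministic rules replace model-based trajectory clustering so the
#' classes are reproducible:
#' * nondynamic: no significant comparison at all;
#' * onset: the earliest significant baseline comparison (0 vs t);
#'   onset at the first post-baseline time point is "immediate",
#'   later onsets are "gradual";
#' * transient: a significant reversal after onset AND the final level
#'   returns within 50% of the peak excursion from baseline.
#'
#' Classes: immediate_increase, transient_increase, gradual_increase,
#' transient_decrease, gradual_decrease, nondynamic. Sustained
#' decreases with an immediate onset fold into gradual_decrease (five
#' dynamic classes in total).
#'
#' @param trajectories tibble `peak, time, mean_norm` of normalized
#'   mean accessibility.
#' @param calls all-pairs calls from [differential_series()].
#' @param return_fraction a trajectory is "returned" when the final
#'   excursion from baseline is below this fraction of the maximum
#'   excursion.
#' @return tibble `peak, class, onset_time, direction`; class
#'   `kinetic_classes` with the trajectories attached as an attribute.
#' @export
classify_kinetics <- function(trajectories, calls, return_fraction = 0.5) {
  tp <- sort(unique(trajectories$time))
  t0 <- tp[1]; t_first <- tp[2]; t_final <- tp[length(tp)]
  sig <- dplyr::filter(calls, .data$direction != "none")
  traj_stats <- trajectories |>
    dplyr::group_by(.data$peak) |>
    dplyr::summarise(
      baseline = .data$mean_norm[.data$time == t0][1],
      final = .data$mean_norm[.data$time == t_final][1],
      excursion = max(abs(.data$mean_norm - .data$mean_norm[.data$time == t0][1])),
      .groups = "drop")
  onset <- sig |>
    dplyr::filter(.data$time_a == t0) |>
    dplyr::group_by(peak = .data$feature) |>
    dplyr::arrange(.data$time_b, .by_group = TRUE) |>
    dplyr::summarise(onset_time = .data$time_b[1], direction = .data$direction[1],
                     .groups = "drop")
  # peaks significant only between interior time points: onset at the
  # earliest significant comparison's endpoint
  interior <- sig |>
    dplyr::filter(!.data$feature %in% onset$peak) |>
    dplyr::group_by(peak = .data$feature) |>
    dplyr::arrange(.data$time_b, .data$time_a, .by_group = TRUE) |>
    dplyr::summarise(onset_time = .data$time_b[1], direction = .data$direction[1],
                     .groups = "drop")
  onset <- dplyr::bind_rows(onset, interior)
  reversal <- sig |>
    dplyr::select(peak = "feature", "time_a", "time_b", rev_dir = "direction") |>
    dplyr::inner_join(onset, by = "peak") |>
    dplyr::filter(.data$time_a >= .data$onset_time, .data$rev_dir != .data$direction) |>
    dplyr::distinct(.data$peak) |>
    dplyr::mutate(has_reversal = TRUE)
  out <- tibble(peak = unique(trajectories$peak)) |>
    dplyr::left_join(onset, by = "peak") |>
    dplyr::left_join(reversal, by = "peak") |>
    dplyr::left_join(traj_stats, by = "peak") |>
    dplyr::mutate(
      has_reversal = dplyr::coalesce(.data$has_reversal, FALSE),
      returned = abs(.data$final - .data$baseline) <=
        .env$return_fraction * pmax(.data$excursion, .Machine$double.eps),
      transient = .data$has_reversal & .data$returned,
      class = dplyr::case_when(
        is.na(.data$direction) ~ "nondynamic",
        .data$direction == "up" & .data$transient ~ "transient_increase",
        .data$direction == "up" & .data$onset_time == t_first ~ "immediate_increase",
        .data$direction == "up" ~ "gradual_increase",
        .data$transient ~ "transient_decrease",
        TRUE ~ "gradual_decrease")) |>
    dplyr::select("peak", "class", "onset_time", "direction")
  structure(out, class = c("kinetic_classes", class(tibble())),
            trajectories = trajectories)
}

#' Collapse kinetic classes to increased / decreased / nondynamic
#' @param class character vector of kinetic class labels.
#' @export
class_direction <- function(class) {
  dplyr::case_when(
    class %in% c("immediate_increase", "transient_increase", "gradual_increase") ~ "increased",
    class %in% c("transient_decrease", "gradual_decrease") ~ "decreased",
    TRUE ~ "nondynamic")
}
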
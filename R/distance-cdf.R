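# Actionable-distance estimation: distance CDFs of dynamic vs unchanged
# genes around factor peak summits, plateau of the CDF difference, and
# per-factor cis-edge constraints.

#' Distance from each gene's TSS to the nearest factor-peak summit
#'
#' Absolute TSS-to-summit distance; a summit exactly at the TSS gives 0.
#'
#' @param genes tibble with `chrom`, `tss`, `gene`.
#' @param peaks tibble with `chrom`, `start`, `summit` (offset from
#'   start).
#' @return input genes with a `distance` column (Inf for genes on
#'   chromosomes without any factor peak).
#' @export
nearest_factor_distance <- function(genes, peaks) {
  assert_that(nrow(peaks) > 0, "nearest_factor_distance: no factor peaks")
  pk <- dplyr::mutate(peaks, summit_pos = .data$start + .data$summit)
  out <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(g, key) {
      s <- sort(pk$summit_pos[pk$chrom == key$chrom])
      if (length(s) == 0) return(dplyr::mutate(g, distance = Inf))
      i <- findInterval(g$tss, s)
      left <- ifelse(i >= 1, g$tss - s[pmax(i, 1)], Inf)
      right <- ifelse(i < length(s), s[pmin(i + 1, length(s))] - g$tss, Inf)
      dplyr::mutate(g, distance = pmin(left, right))
    }) |>
    dplyr::ungroup()
  out[match(genes$gene, out$gene), ]
}

#' Empirical distance CDF for a gene class
#' @param distances numeric vector of TSS-to-summit distances (bp).
#' @param label class label carried through to plots.
#' @export
distance_cdf <- function(distances, label = "genes") {
  d <- sort(distances[is.finite(distances)])
  structure(list(distances = d, label = label, n = length(d)),
            class = "distance_cdf")
}

#' @export
print.distance_cdf <- function(x, ...) {
  cat(sprintf("<distance_cdf> %s: n=%d, median %.0f bp\n",
              x$label, x$n, median(x$distances)))
  invisible(x)
}

cdf_eval <- function(cdf, d) {
  if (cdf$n == 0) return(rep(0, length(d)))
  findInterval(d, cdf$distances) / cdf$n
}

#' Maximal actionable distance from a CDF difference plateau
#'
#' Evaluates `delta(d) = CDF_dynamic(d) - CDF_unchanged(d)` on a grid
#' (default 500-bp bins to 200 kb) and reports the smallest `d` at
#' which `delta` reaches 99% of its maximum -- the distance beyond
#' which factor peaks accumulate at the same rate near dynamic and
#' unchanged genes. Significance of `max delta` is assessed by a
#' permutation test that shuffles gene class labels.
#'
#' @param cdf_dynamic,cdf_unchanged [distance_cdf()] objects.
#' @param grid_step,grid_max evaluation grid (bp).
#' @param n_permutations label permutations for the p-value.
#' @param plateau_fraction plateau criterion (0.99 of max delta).
#' @param seed seed for the permutation draw.
#' @return object of class `cdf_plateau`: list with `distance_bp`
#'   (NA when there is no proximity signal), `max_delta`, `pvalue`,
#'   `signal` (logical), and the evaluated `delta` curve.
#' @export
plateau_distance <- function(cdf_dynamic, cdf_unchanged, grid_step = 500,
                             grid_max = 2e5, n_permutations = 1000,
                             plateau_fraction = 0.99, seed = 1L) {
  assert_that(cdf_dynamic$n > 0 && cdf_unchanged$n > 0,
              "both gene classes must be nonempty")
  grid <- seq(0, grid_max, by = grid_step)
  delta <- cdf_eval(cdf_dynamic, grid) - cdf_eval(cdf_unchanged, grid)
  max_delta <- max(delta)
  pooled <- c(cdf_dynamic$distances, cdf_unchanged$distances)
  n_dyn <- cdf_dynamic$n
  perm_max <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      lab <- sample.int(length(pooled), n_dyn)
      dd <- distance_cdf(pooled[lab])
      du <- distance_cdf(pooled[-lab])
      max(cdf_eval(dd, grid) - cdf_eval(du, grid))
    }, 0)
  })
  pvalue <- (1 + sum(perm_max >= max_delta)) / (n_permutations + 1)
  signal <- max_delta > 0
  distance_bp <- if (signal)
    grid[which(delta >= plateau_fraction * max_delta)[1]] else NA_real_
  structure(list(distance_bp = distance_bp, max_delta = max_delta,
                 pvalue = pvalue, signal = signal,
                 curve = tibble(distance = grid, delta = delta),
                 labels = c(cdf_dynamic$label, cdf_unchanged$label)),
            class = "cdf_plateau")
}

#' @export
print.cdf_plateau <- function(x, ...) {
  if (x$signal)
    cat(sprintf("<cdf_plateau> %s vs %s: plateau %.0f bp (max delta %.3f, p = %.3g)\n",
                x$labels[1], x$labels[2], x$distance_bp, x$max_delta, x$pvalue))
  else
    cat(sprintf("<cdf_plateau> %s vs %s: no proximity signal (max delta %.3f)\n",
                x$labels[1], x$labels[2], x$max_delta))
  invisible(x)
}

#' @method tidy cdf_plateau
#' @export
tidy.cdf_plateau <- function(x, ...) x$curve

#' @method glance cdf_plateau
#' @export
glance.cdf_plateau <- function(x, ...) {
  tibble(distance_bp = x$distance_bp, max_delta = x$max_delta,
         pvalue = x$pvalue, signal = x$signal)
}

#' Per-factor cis-edge constraints from the CDF analysis
#'
#' For each factor and each time-point comparison, genes are split into
#' dynamic (direction matching the factor's regulatory sign: activated
#' for openers binding, repressed for closers and dissociating openers)
#' and unchanged; the CDF difference against distance to the factor's
#' dynamic peak summits gives a plateau distance and permutation
#' p-value. Comparisons with `p < alpha` form the factor's allowed
#' cis-edge comparison set; the factor's distance limit is the largest
#' plateau among them.
#'
#' @param genes gene tibble with `gene, chrom, tss`.
#' @param gene_calls transcription calls from [transcription_series()].
#' @param peaks peak tibble with `chrom, start, summit`.
#' @param hits motif hits with `peak, family` columns.
#' @param families family rule tibble from [family_rules()].
#' @param dynamic_peaks character vector of dynamic peak ids (factor
#'   peaks are restricted to dynamic peaks carrying the family motif).
#' @param comparisons tibble of `time_a, time_b` to evaluate (defaults
#'   to baseline comparisons present in `gene_calls`).
#' @param alpha permutation significance threshold.
#' @param n_permutations permutations per comparison.
#' @param seed integer seed.
#' @inheritParams plateau_distance
#' @return tibble `family, time_a, time_b, distance_bp, max_delta,
#'   pvalue` with one row per significant comparison; class
#'   `cdf_constraints`.
#' @export
cdf_constraints <- function(genes, gene_calls, peaks, hits, families,
                            dynamic_peaks, comparisons = NULL, alpha = 0.05,
                            n_permutations = 200, grid_step = 500,
                            grid_max = 2e5, seed = 1L) {
  cmp <- comparisons %||% dplyr::distinct(
    dplyr::filter(gene_calls, .data$time_a == min(gene_calls$time_a)),
    .data$time_a, .data$time_b)
  rows <- list()
  for (fi in seq_len(nrow(families))) {
    fam <- families$name[fi]
    want_call <- if (families$role[fi] == "opener" && !isTRUE(families$dissociates[fi]))
      "activated" else "repressed"
    fam_peaks <- dplyr::filter(peaks, .data$peak %in% hits$peak[hits$family == fam],
                               .data$peak %in% dynamic_peaks)
    if (nrow(fam_peaks) == 0) next
    dist <- nearest_factor_distance(genes, fam_peaks)
    for (ci in seq_len(nrow(cmp))) {
      cc <- dplyr::filter(gene_calls, .data$time_a == cmp$time_a[ci],
                          .data$time_b == cmp$time_b[ci])
      dyn_genes <- cc$feature[cc$call == want_call]
      unch_genes <- cc$feature[cc$call == "unchanged"]
      if (length(dyn_genes) < 3 || length(unch_genes) < 3) next
      pl <- plateau_distance(
        distance_cdf(dist$distance[dist$gene %in% dyn_genes], want_call),
        distance_cdf(dist$distance[dist$gene %in% unch_genes], "unchanged"),
        grid_step = grid_step, grid_max = grid_max,
        n_permutations = n_permutations,
        seed = seed + 1000L * fi + ci)
      if (pl$signal && pl$pvalue < alpha)
        rows[[length(rows) + 1]] <- tibble(
          family = fam, time_a = cmp$time_a[ci], time_b = cmp$time_b[ci],
          distance_bp = pl$distance_bp, max_delta = pl$max_delta,
          pvalue = pl$pvalue)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(family = character(), time_a = numeric(), time_b = numeric(),
           distance_bp = numeric(), max_delta = numeric(), pvalue = numeric())
  structure(out, class = c("cdf_constraints", class(tibble())))
}
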
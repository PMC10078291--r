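# Factor cooperation: stratified 2x2 tables of genes by proximity to
# two factors' inferred REs and dynamic status, with Woolf odds-ratio
# confidence intervals.

#' Stratified 2x2 contingency tables for factor cooperation
#'
#' Genes are stratified by proximity to factor A's REs; within each
#' stratum a 2x2 table counts dynamic status against proximity to
#' factor B: `a` = dynamic & B-proximal, `b` = dynamic & not,
#' `c` = non-dynamic & B-proximal, `d` = non-dynamic & not.
#'
#' @param genes tibble with `gene` and logical `dynamic` columns.
#' @param proximal_a,proximal_b character vectors of gene ids proximal
#'   to each factor's inferred REs (dynamic peaks carrying the factor
#'   motif, within the factor's distance limit).
#' @return tibble with one row per stratum (`a_present` FALSE/TRUE) and
#'   cells `a, b, c, d`; zero-count strata are flagged.
#' @export
stratified_tables <- function(genes, proximal_a, proximal_b) {
  g <- dplyr::mutate(genes,
                     in_a = .data$gene %in% proximal_a,
                     in_b = .data$gene %in% proximal_b)
  purrr::map_dfr(c(FALSE, TRUE), function(stratum) {
    s <- dplyr::filter(g, .data$in_a == stratum)
    tibble(a_present = stratum,
           a = sum(s$dynamic & s$in_b), b = sum(s$dynamic & !s$in_b),
           c = sum(!s$dynamic & s$in_b), d = sum(!s$dynamic & !s$in_b),
           n = nrow(s), empty = nrow(s) == 0)
  })
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad/bc`; the interval is
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. The
#' Haldane-Anscombe correction (+0.5 to every cell) is applied when any
#' cell is zero.
#'
#' @param table one row of [stratified_tables()] or a tibble with
#'   columns `a, b, c, d` (one row per table).
#' @param conf_level confidence level (0.95).
#' @return tibble with `or, lower, upper, corrected` per input row.
#' @export
odds_ratio_ci <- function(table, conf_level = 0.95) {
  z <- -stats::qnorm((1 - conf_level) / 2)
  purrr::pmap_dfr(dplyr::select(table, "a", "b", "c", "d"), function(a, b, c, d) {
    corrected <- any(c(a, b, c, d) == 0)
    if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    tibble(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
           corrected = corrected)
  })
}

#' Cooperation odds ratios between two factors
#'
#' Convenience wrapper: builds the A-absent and A-present strata and
#' returns both tables with their odds-ratio confidence intervals. An
#' A-present interval lying above the A-absent interval indicates that
#' factor B's association with dynamic genes strengthens in the
#' presence of factor A (cooperation).
#'
#' @inheritParams stratified_tables
#' @inheritParams odds_ratio_ci
#' @export
cooperation_odds <- function(genes, proximal_a, proximal_b, conf_level = 0.95) {
  tabs <- stratified_tables(genes, proximal_a, proximal_b)
  dplyr::bind_cols(tabs, odds_ratio_ci(tabs, conf_level))
}
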
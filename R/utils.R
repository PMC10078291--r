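# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_kn <- function(msg, ...) abort(sprintf(msg, ...), class = "kineticnet_error")

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_kn(msg, ...)
  invisible(TRUE)
}

# closed-interval overlap on minutes; intervals are (time_a, time_b) pairs
intervals_overlap <- function(a1, b1, a2, b2, strict = FALSE) {
  if (strict) a1 == a2 & b1 == b2 else pmax(a1, a2) <= pmin(b1, b2)
}

# gap between two 0-based half-open intervals; 0 if they overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

geometric_mean <- function(x) exp(mean(log(x)))

# comparisons between time points: all ordered pairs, or each vs baseline,
# or consecutive only
time_comparisons <- function(time_points, which = c("all", "baseline", "consecutive")) {
  which <- match.arg(which)
  tp <- sort(unique(time_points))
  grid <- tidyr::expand_grid(time_a = tp, time_b = tp) |>
    dplyr::filter(.data$time_a < .data$time_b)
  switch(which,
    all = grid,
    baseline = dplyr::filter(grid, .data$time_a == min(tp)),
    consecutive = tibble(time_a = tp[-length(tp)], time_b = tp[-1])
  )
}
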
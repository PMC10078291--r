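#' Two-compartment model of RNA polymerase II occupancy
#'
#' The transcription unit is split into a promoter-proximal pause
#' compartment and a gene-body compartment. Polymerases enter the pause
#' compartment at rate `k_init` (polymerases/min), leave it by premature
#' termination (`k_pre`, /min) or pause release (`k_rel`, /min), and
#' traverse the body of length `L` bp at `k_elong` bp/min:
#'
#' \deqn{dP/dt = k_{init} - (k_{pre} + k_{rel}) P}
#' \deqn{dB/dt = k_{rel} P - (k_{elong}/L) B}
#'
#' `P` is the polymerase count in the pause region and `B` the count in
#' the body (`b = B/L` is the per-bp body density that PRO-seq measures).
#'
#' @param k_init initiation/recruitment rate, polymerases per minute.
#' @param k_pre premature termination rate per minute (may be 0).
#' @param k_rel pause release rate per minute.
#' @param k_elong elongation rate, bp per minute.
#' @param L gene-body length in bp.
#' @return A tibble of validated rate parameters (one row per gene).
#' @export
rate_params <- function(k_init, k_pre, k_rel, k_elong = 2500, L = 10000) {
  p <- tibble(k_init = as.numeric(k_init), k_pre = as.numeric(k_pre),
              k_rel = as.numeric(k_rel), k_elong = as.numeric(k_elong),
              L = as.numeric(L))
  assert_that(all(p$k_init > 0) && all(p$k_rel > 0) && all(p$k_elong > 0) &&
                all(p$L > 0), "rate constants k_init, k_rel, k_elong and L must be positive")
  assert_that(all(p$k_pre >= 0), "k_pre must be non-negative")
  p
}

#' Steady-state occupancy and pause residency time
#'
#' Closed-form fixed point of the two-compartment model:
#' `P* = k_init / (k_pre + k_rel)`, `b* = k_rel P* / k_elong`,
#' residency `tau = 1 / (k_pre + k_rel)` (reported in seconds).
#'
#' @param params tibble from [rate_params()].
#' @return tibble with columns `P` (pause polymerase count), `b` (body
#'   density, polymerases/bp), `B` (body polymerase count) and
#'   `residency_sec`.
#' @export
steady_state <- function(params) {
  kexit <- params$k_pre + params$k_rel
  P <- params$k_init / kexit
  b <- params$k_rel * P / params$k_elong
  tibble(P = P, b = b, B = b * params$L, residency_sec = 60 / kexit)
}

#' Integrate the compartment ODEs numerically
#'
#' @param params single-row tibble from [rate_params()].
#' @param P0,B0 initial pause and body polymerase counts.
#' @param times minutes at which to report the solution.
#' @return tibble with columns `time`, `P`, `B`, `b`.
#' @export
integrate_occupancy <- function(params, P0 = 0, B0 = 0,
                                times = seq(0, 60, by = 1)) {
  assert_that(nrow(params) == 1L, "integrate_occupancy() takes one parameter set")
  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      list(c(P = k_init - (k_pre + k_rel) * P,
             B = k_rel * P - (k_elong / L) * B))
    })
  }
  out <- deSolve::ode(y = c(P = P0, B = B0), times = times, func = deriv,
                      parms = as.list(params[1, ]),
                      rtol = 1e-10, atol = 1e-12)
  tibble(time = out[, "time"], P = out[, "P"], B = out[, "B"],
         b = out[, "B"] / params$L)
}

#' Apply multiplicative fold-changes to initiation and pause release
#'
#' `k_pre` and `k_elong` are held fixed, mirroring the fitting
#' assumptions (elongation and premature termination constant between
#' time points).
#'
#' @param params tibble from [rate_params()].
#' @param f_init,f_rel positive fold-changes on `k_init` and `k_rel`.
#' @export
apply_fold_changes <- function(params, f_init = 1, f_rel = 1) {
  assert_that(all(f_init > 0) && all(f_rel > 0),
              "fold-changes must be positive")
  dplyr::mutate(params, k_init = .data$k_init * f_init,
                k_rel = .data$k_rel * f_rel)
}

#' Base-parameter grid for occupancy fitting
#'
#' Regular grid over the four rate constants: `k_init`, `k_pre`, `k_rel`
#' log-spaced over two orders of magnitude (25 points per decade) and
#' `k_elong` linear from 600 to 6000 bp/min (10 points). Used as the
#' candidate pool that [fit_fold_changes()] filters for consistency with
#' the first occupancy snapshot.
#'
#' @param k_init_range,k_pre_range,k_rel_range two-element ranges (/min).
#' @param k_elong_range two-element range (bp/min).
#' @param per_decade log-grid density for the first three rates.
#' @param n_elong number of linear `k_elong` values.
#' @param L gene-body length bp.
#' @export
param_grid <- function(k_init_range = c(0.5, 50), k_pre_range = c(0.005, 0.5),
                       k_rel_range = c(0.1, 10), k_elong_range = c(600, 6000),
                       per_decade = 25, n_elong = 10, L = 10000) {
  logseq <- function(r) {
    n <- round(per_decade * log10(r[2] / r[1])) + 1L
    10^seq(log10(r[1]), log10(r[2]), length.out = n)
  }
  tidyr::expand_grid(
    k_init = logseq(k_init_range), k_pre = logseq(k_pre_range),
    k_rel = logseq(k_rel_range),
    k_elong = seq(k_elong_range[1], k_elong_range[2], length.out = n_elong)
  ) |> dplyr::mutate(L = L)
}

# Construct base sets exactly consistent with an occupancy snapshot:
# for each (k_pre, k_elong) on the grid, k_rel and k_init are solved from
# (P, b); sets whose solved rates leave the stated two-decade ranges are
# dropped. This is the 2-D manifold of parameter sets that reproduce the
# initial densities.
consistent_base_sets <- function(occ, k_pre_grid = c(0, 10^seq(log10(0.005), log10(0.5), length.out = 51)),
                                 k_elong_grid = seq(600, 6000, length.out = 10),
                                 k_init_range = c(0.05, 500),
                                 k_rel_range = c(0.01, 100), L = 10000) {
  base <- tidyr::expand_grid(k_pre = k_pre_grid, k_elong = k_elong_grid)
  base <- dplyr::mutate(base,
    k_rel = occ$b * .data$k_elong / occ$P,
    k_init = occ$P * (.data$k_pre + .data$k_rel),
    L = L)
  dplyr::filter(base,
    .data$k_rel >= k_rel_range[1], .data$k_rel <= k_rel_range[2],
    .data$k_init >= k_init_range[1], .data$k_init <= k_init_range[2]) |>
    dplyr::select("k_init", "k_pre", "k_rel", "k_elong", "L")
}

#' Fit initiation and pause-release fold-changes between two snapshots
#'
#' Both snapshots are treated as steady states. For every base parameter
#' set consistent with the first snapshot, the fold-changes on `k_init`
#' and `k_rel` that reproduce the second snapshot (with `k_pre` and
#' `k_elong` held fixed) are solved in closed form:
#' `f_rel = b2 k_elong / (k_rel P2)` and
#' `f_init = P2 (k_pre + f_rel k_rel) / k_init`. With `k_pre = 0` these
#' reduce to `f_rel = (b2/b1)/(P2/P1)` and `f_init = b2/b1`, and the
#' fitted fold-changes are identical for every base set; the spread
#' across the grid grows with `k_pre / k_rel` (the model's
#' identifiability caveat).
#'
#' @param occ1,occ2 lists or single-row tibbles with elements `P`
#'   (pause polymerase count) and `b` (body density, polymerases/bp).
#' @param base optional explicit base-parameter grid (e.g. from
#'   [param_grid()]); it is filtered to sets whose steady state matches
#'   `occ1` within `tol` (relative) on both `P` and `b`. When `NULL`,
#'   exactly consistent base sets are constructed from a
#'   `(k_pre, k_elong)` grid.
#' @param tol relative tolerance for the consistency filter.
#' @param k_pre_grid,k_elong_grid grids used when `base` is `NULL`.
#' @return object of class `rate_fit`: a list with `fits` (one row per
#'   retained base set, columns `k_init, k_pre, k_rel, k_elong, f_init,
#'   f_rel`) plus the snapshots. `tidy()` returns the per-set fits,
#'   `glance()` the median and range.
#' @export
fit_fold_changes <- function(occ1, occ2, base = NULL, tol = 0.01,
                             k_pre_grid = c(0, 10^seq(log10(0.005), log10(0.5), length.out = 51)),
                             k_elong_grid = seq(600, 6000, length.out = 10)) {
  occ1 <- as.list(occ1)[c("P", "b")]
  occ2 <- as.list(occ2)[c("P", "b")]
  assert_that(all(unlist(occ1) > 0) && all(unlist(occ2) > 0),
              "occupancies must be positive in both snapshots")
  if (is.null(base)) {
    keep <- consistent_base_sets(occ1, k_pre_grid, k_elong_grid)
    if (nrow(keep) == 0L)
      stop_kn("no consistent base parameter set: solved k_rel/k_init fall outside the grid ranges (P=%.3g, b=%.3g)",
              occ1$P, occ1$b)
  } else {
    ss <- steady_state(base)
    ok <- abs(ss$P - occ1$P) <= tol * occ1$P & abs(ss$b - occ1$b) <= tol * occ1$b
    keep <- base[ok, , drop = FALSE]
    if (nrow(keep) == 0L)
      stop_kn(paste0("no base parameter set within %.2g%% of the first snapshot ",
                     "(closest: %.2g%% on P, %.2g%% on b); consider base = NULL"),
              100 * tol, 100 * min(abs(ss$P - occ1$P) / occ1$P),
              100 * min(abs(ss$b - occ1$b) / occ1$b))
  }
  fits <- dplyr::mutate(keep,
    f_rel = occ2$b * .data$k_elong / (.data$k_rel * occ2$P),
    f_init = occ2$P * (.data$k_pre + .data$f_rel * .data$k_rel) / .data$k_init)
  structure(list(fits = as_tibble(fits), occ1 = occ1, occ2 = occ2),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %d consistent base sets\n", nrow(x$fits)))
  cat(sprintf("  f_init: median %.4g [%.4g, %.4g]\n",
              median(x$fits$f_init), min(x$fits$f_init), max(x$fits$f_init)))
  cat(sprintf("  f_rel : median %.4g [%.4g, %.4g]\n",
              median(x$fits$f_rel), min(x$fits$f_rel), max(x$fits$f_rel)))
  invisible(x)
}

#' @method tidy rate_fit
#' @export
tidy.rate_fit <- function(x, ...) x$fits

#' @method glance rate_fit
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(
    n_base_sets = nrow(x$fits),
    f_init = median(x$fits$f_init),
    f_init_min = min(x$fits$f_init), f_init_max = max(x$fits$f_init),
    f_rel = median(x$fits$f_rel),
    f_rel_min = min(x$fits$f_rel), f_rel_max = max(x$fits$f_rel)
  )
}

#' Simulated polymerase density profile along a gene
#'
#' Pause-region density is `P*/w` polymerases per bp over the `w`-bp
#' pause window and `b*` along the body; an optional Gaussian kernel
#' (sd `sigma` bp) smooths the pause peak, preserving its area.
#'
#' @param params single-row tibble from [rate_params()].
#' @param pause_width pause-region width, bp (50 by convention).
#' @param sigma Gaussian sd in bp; 0 disables smoothing.
#' @param upstream bp of zero signal to include upstream of the pause.
#' @return tibble with `position` (bp, pause region starts at 0) and
#'   `density` (polymerases per bp); class `polii_profile`.
#' @export
simulate_profile <- function(params, pause_width = 50, sigma = 0, upstream = 250) {
  assert_that(nrow(params) == 1L, "simulate_profile() takes one parameter set")
  ss <- steady_state(params)
  pos <- seq(-upstream, params$L + pause_width - 1)
  dens <- numeric(length(pos))
  in_pause <- pos >= 0 & pos < pause_width
  dens[in_pause] <- ss$P / pause_width
  dens[pos >= pause_width] <- ss$b
  if (sigma > 0) {
    pause_part <- numeric(length(pos))
    pause_part[in_pause] <- ss$P / pause_width
    kern <- dnorm(seq(-4 * sigma, 4 * sigma), sd = sigma)
    kern <- kern / sum(kern)
    sm <- stats::convolve(pause_part, rev(kern), type = "open")
    off <- (length(kern) - 1) / 2
    dens <- sm[(off + 1):(off + length(pos))] + (pos >= pause_width) * ss$b
  }
  structure(tibble(position = pos, density = dens), class = c("polii_profile", class(tibble())))
}
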
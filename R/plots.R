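# ggplot2 visualizations for the main result types.

#' @method autoplot kinetic_classes
#' @export
autoplot.kinetic_classes <- function(object, ...) {
  traj <- attr(object, "trajectories")
  df <- dplyr::inner_join(traj, as_tibble(object), by = "peak")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean_norm, group = .data$peak)) +
    ggplot2::geom_line(alpha = 0.25, color = "grey30") +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "normalized accessibility",
                  title = "Kinetic response classes")
}

#' @method autoplot motif_density
#' @export
autoplot.motif_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$offset, .data$density,
                                       color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from peak summit (bp)",
                  y = "weighted motif density / peak")
}

#' @method autoplot composite_profile
#' @export
autoplot.composite_profile <- function(object, ...) {
  df <- dplyr::mutate(object, signal = dplyr::if_else(
    .data$orientation == "antisense", -.data$mean_signal, .data$mean_signal))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$signal,
                                   color = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "offset (bp)", y = "mean signal (antisense negated)")
}

#' @method autoplot cdf_plateau
#' @export
autoplot.cdf_plateau <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(.data$distance, .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TSS-to-summit distance (bp)",
                  y = expression(Delta ~ "CDF (dynamic - unchanged)"))
  if (object$signal)
    p <- p + ggplot2::geom_vline(xintercept = object$distance_bp,
                                 linetype = "dashed", color = "red")
  p
}

#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fits, c("f_init", "f_rel"),
                            names_to = "rate", values_to = "fold_change")
  ggplot2::ggplot(df, ggplot2::aes(.data$rate, .data$fold_change)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(y = "fitted fold-change across base grid", x = NULL)
}

#' @method autoplot polii_profile
#' @export
autoplot.polii_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "position (bp, pause region at 0)",
                  y = "Pol II density (polymerases/bp)")
}
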
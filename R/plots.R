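#' Plot an hourly divergence series with its recovery band
#'
#' Hourly Jensen-Shannon divergences (points), the region-of-recovery band
#' (shaded), and, when supplied, the bootstrapped return time (dashed) with
#' its confidence interval (solid verticals).
#'
#' @param labelled a [label_series()] result (columns `hour`, `J`, `label`).
#' @param ror a [region_of_recovery()] band.
#' @param breakpoint optional [block_bootstrap_breakpoint()] estimate.
#' @return A ggplot object.
#' @export
plot_entropy_series <- function(labelled, ror, breakpoint = NULL) {
  gp <- ggplot2::ggplot(labelled, ggplot2::aes(x = .data$hour, y = .data$J)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = ror$lo, ymax = ror$hi,
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$label)),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`-1` = 6, `1` = 2),
                                name = "label") +
    ggplot2::labs(x = "hours since release",
                  y = "Jensen-Shannon divergence (bits)") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint) && isTRUE(breakpoint$detected)) {
    gp <- gp +
      ggplot2::geom_vline(xintercept = breakpoint$t_R_h, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = c(breakpoint$ci_lower_h,
                                         breakpoint$ci_upper_h))
  }
  gp
}

#' Plot return-time curves over the recovery threshold
#'
#' The solution of the recovery equation for a grid of thresholds `delta`,
#' drawn against the recovered percentage `(1 - delta) * 100`, one curve
#' per group/quantile.
#'
#' @param curves a `recovery_estimate` tibble from [recovery_curve()]
#'   (possibly several, row-bound, with distinct `tau`/`group`).
#' @return A ggplot object.
#' @export
plot_recovery_curve <- function(curves) {
  curves$pct <- (1 - curves$delta) * 100
  curves$which <- paste0(curves$group, ", tau=", curves$tau)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$t_R_h, y = .data$pct,
                                       colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours since release",
                  y = "% of baseline behaviour reached",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
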
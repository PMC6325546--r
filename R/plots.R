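# ggplot2 graphics for the main result types.

#' Plot a fitted psychometric function
#'
#' Observed group-median points with the fitted logistic overlaid; the
#' dotted guides mark the 0.25 and 0.75 response rates whose half-span
#' defines the 75% JND.
#'
#' @param object a `toj_psychfit` from [fit_sigmoid()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot toj_psychfit
#' @export
autoplot.toj_psychfit <- function(object, ...) {
  pts <- object$points
  xr <- range(pts$asynchrony_ms)
  curve <- tibble::tibble(
    asynchrony_ms = seq(xr[1], xr[2], length.out = 200),
    p_left = logistic2(seq(xr[1], xr[2], length.out = 200),
                       object$k, object$xo)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$asynchrony_ms,
                                    y = .data$p_left)) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.75), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(data = curve, colour = "#2166ac") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Asynchrony (ms, positive = left leading)",
      y = "Proportion left-first responses",
      title = sprintf("75%% JND = %.1f ms  (K = %.4g, Xo = %.3g ms)",
                      object$threshold_ms, object$k, object$xo)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the simulated null statistics with the observed statistic
#' (solid) and the null 95th percentile (dashed) marked.
#'
#' @param object a `toj_perm`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot toj_perm
#' @export
autoplot.toj_perm <- function(object, bins = 50, ...) {
  df <- tibble::tibble(stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = object$null_q95, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "#b2182b") +
    ggplot2::labs(
      x = sprintf("Simulated %s (d' units)", object$type),
      y = "Count",
      title = sprintf("observed = %.3f, p = %.4g (%d simulations)",
                      object$observed_stat, object$p_value, object$n_sims)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group median reaction times across the design
#'
#' One panel per motion x initial-directions condition; lines join each
#' group's median RT across the seven asynchronies, making the slowing at
#' the uninformative zero asynchrony visible.
#'
#' @param rt_group output of [group_rt_medians()].
#' @return a ggplot.
#' @export
plot_rt_medians <- function(rt_group) {
  ggplot2::ggplot(rt_group,
                  ggplot2::aes(x = .data$asynchrony_ms,
                               y = .data$rt_median_ms,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$motion_type),
      cols = ggplot2::vars(.data$initial_directions)) +
    ggplot2::labs(x = "Asynchrony (ms)", y = "Group median RT (ms)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot group psychometric thresholds
#'
#' Bar chart of the 75% JND thresholds per group and condition with +/- 1 SE
#' error bars.
#'
#' @param fits output of [fit_psychometric()].
#' @return a ggplot.
#' @export
plot_thresholds <- function(fits) {
  ggplot2::ggplot(fits,
                  ggplot2::aes(x = interaction(.data$motion_type,
                                               .data$initial_directions,
                                               sep = " / "),
                               y = .data$threshold_ms, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$threshold_ms - .data$threshold_se_ms,
                   ymax = .data$threshold_ms + .data$threshold_se_ms),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = "Motion condition", y = "75% JND threshold (ms)",
                  fill = "Group") +
    ggplot2::theme_minimal()
}
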
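# broom-style tidiers and print methods for fitted objects.

#' Tidy a fitted psychometric function
#'
#' @param x a `toj_psychfit` from [fit_sigmoid()].
#' @param ... unused.
#' @return a tibble with one row per parameter (`k`, `xo`): `term`,
#'   `estimate`, `std.error`.
#' @method tidy toj_psychfit
#' @export
tidy.toj_psychfit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "xo"),
    estimate = c(x$k, x$xo),
    std.error = c(x$k_se, x$xo_se)
  )
}

#' One-row summary of a fitted psychometric function
#'
#' @param x a `toj_psychfit` from [fit_sigmoid()].
#' @param ... unused.
#' @return a one-row tibble: `k`, `xo`, `r`, `r.squared`, `threshold_ms`,
#'   `threshold_se_ms`, `n_points`.
#' @method glance toj_psychfit
#' @export
glance.toj_psychfit <- function(x, ...) {
  tibble::tibble(
    k = x$k, xo = x$xo, r = x$r, r.squared = x$r_squared,
    threshold_ms = x$threshold_ms, threshold_se_ms = x$threshold_se_ms,
    n_points = x$n_points
  )
}

#' @export
print.toj_psychfit <- function(x, ...) {
  cat("Psychometric fit: p = 1 / (1 + exp(-K (X - Xo)))\n")
  cat(sprintf("  K  = %.5g 1/ms (SE %.3g)\n", x$k, x$k_se))
  cat(sprintf("  Xo = %.4g ms (SE %.3g)\n", x$xo, x$xo_se))
  cat(sprintf("  r = %.4f (r^2 = %.4f) over %d points\n",
              x$r, x$r_squared, x$n_points))
  cat(sprintf("  75%% JND threshold = %.4g ms (SE %.3g)\n",
              x$threshold_ms, x$threshold_se_ms))
  invisible(x)
}

#' Tidy a permutation test result
#'
#' @param x a `toj_perm` from [permute_groups()] or [permute_interaction()].
#' @param ... unused.
#' @return a one-row tibble: `type`, `observed_stat`, `p_value`,
#'   `significant`, `null_q95`, `n_sims`, `seed`, `direction`.
#' @method tidy toj_perm
#' @export
tidy.toj_perm <- function(x, ...) {
  tibble::tibble(
    type = x$type, observed_stat = x$observed_stat, p_value = x$p_value,
    significant = x$significant, null_q95 = x$null_q95, n_sims = x$n_sims,
    seed = x$seed, direction = x$direction
  )
}

#' One-row summary of a permutation test's null distribution
#'
#' @param x a `toj_perm`.
#' @param ... unused.
#' @return a one-row tibble: null mean, SD, and the 5th/50th/95th
#'   percentiles alongside the observed statistic and p-value.
#' @method glance toj_perm
#' @export
glance.toj_perm <- function(x, ...) {
  q <- quantile(x$null_stats, c(0.05, 0.5, 0.95))
  tibble::tibble(
    observed_stat = x$observed_stat, p_value = x$p_value,
    null_mean = mean(x$null_stats), null_sd = stats::sd(x$null_stats),
    null_q05 = unname(q[1]), null_q50 = unname(q[2]), null_q95 = unname(q[3]),
    n_sims = x$n_sims
  )
}

#' @export
print.toj_perm <- function(x, ...) {
  cat(sprintf("Monte Carlo permutation test (%s)\n", x$type))
  cat(sprintf("  observed = %.4f, null 95th percentile = %.4f\n",
              x$observed_stat, x$null_q95))
  cat(sprintf("  p = %.4g over %d simulations (seed %d, %s)%s\n",
              x$p_value, x$n_sims, x$seed, x$direction,
              if (x$significant) "  *" else ""))
  invisible(x)
}
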
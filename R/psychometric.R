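# Group-level psychometric functions: median proportion of left-first
# responses at each signed asynchrony, fit by least squares with the
# two-parameter logistic 1 / (1 + exp(-K (X - Xo))). The 75% JND is half the
# asynchrony change that moves the curve from 0.25 to 0.75, i.e. ln(3)/K.

#' Build group psychometric points
#'
#' For every group x motion x initial-directions combination (or an
#' optionally restricted subset), computes each participant's proportion of
#' left-first responses at each of the seven asynchronies, then takes the
#' median across participants.
#'
#' @param trials a validated `toj_trials` tibble (analysis blocks only are
#'   used).
#' @param motion_type,initial_directions,group optional filters; leave `NULL`
#'   to get points for every combination present.
#' @return a tibble with columns `group`, `motion_type`,
#'   `initial_directions`, `asynchrony_ms`, `p_left` (the group median
#'   proportion) and `n_participants`.
#' @export
build_points <- function(trials, motion_type = NULL, initial_directions = NULL,
                         group = NULL) {
  trials <- analysis_trials(trials)
  if (!is.null(motion_type))
    trials <- dplyr::filter(trials, .data$motion_type %in% !!motion_type)
  if (!is.null(initial_directions))
    trials <- dplyr::filter(trials,
                            .data$initial_directions %in% !!initial_directions)
  if (!is.null(group))
    trials <- dplyr::filter(trials, .data$group %in% !!group)
  if (nrow(trials) == 0) stop("no trials left after filtering", call. = FALSE)

  trials |>
    dplyr::group_by(.data$group, .data$motion_type, .data$initial_directions,
                    .data$asynchrony_ms, .data$participant_id) |>
    dplyr::summarise(p = mean(.data$response == "left_first"),
                     .groups = "drop") |>
    dplyr::group_by(.data$group, .data$motion_type, .data$initial_directions,
                    .data$asynchrony_ms) |>
    dplyr::summarise(p_left = median(.data$p),
                     n_participants = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$group, .data$motion_type, .data$initial_directions,
                   .data$asynchrony_ms)
}

logistic2 <- function(x, k, xo) 1 / (1 + exp(-k * (x - xo)))

# logit-linear starting values; proportions clamped away from 0/1
psy_start <- function(x, p) {
  pc <- pmin(pmax(p, 0.01), 0.99)
  sl <- tryCatch(unname(coef(lm(log(pc / (1 - pc)) ~ x))[2]),
                 error = function(e) NA_real_)
  k0 <- if (is.finite(sl) && sl > 0) sl else 0.01
  xo0 <- x[which.min(abs(p - 0.5))]
  c(k = k0, xo = xo0)
}

#' Fit the two-parameter logistic to psychometric points
#'
#' Unweighted least squares of `p_left` against
#' `1 / (1 + exp(-K (X - Xo)))`. The sum of squared residuals is minimized
#' over `(log K, Xo)` by quasi-Newton iteration from a logit-linear starting
#' value, with a grid of additional K starting values always tried and the
#' best optimum kept (the 2-parameter surface can have plateaus when the
#' curve is much shallower than the sampled asynchrony range). Standard
#' errors follow the usual nonlinear least-squares approximation from the
#' Hessian of the residual sum of squares at the optimum. Goodness of fit is
#' the Pearson correlation between observed and fitted ordinates. The 75%
#' JND threshold `ln(3)/K` and its delta-method standard error
#' `ln(3) SE(K) / K^2` are attached.
#'
#' @param points a tibble with columns `asynchrony_ms` and `p_left` (one
#'   curve, e.g. one row-group of [build_points()]).
#' @return a `toj_psychfit` object; see [tidy.toj_psychfit()] and
#'   [glance.toj_psychfit()].
#' @export
fit_sigmoid <- function(points) {
  x <- points$asynchrony_ms
  p <- points$p_left
  if (length(x) < 3) stop("need at least 3 points to fit", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p_left must lie in [0, 1]", call. = FALSE)

  sse_log <- function(theta) {           # theta = (log k, xo)
    sum((p - logistic2(x, exp(theta[1]), theta[2]))^2)
  }
  try_fit <- function(start) {
    res <- tryCatch(
      optim(start, sse_log, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- tryCatch(optim(start, sse_log, control = list(maxit = 2000)),
                      error = function(e) NULL)
    }
    res
  }

  start <- psy_start(x, p)
  starts <- c(list(c(log(start[["k"]]), start[["xo"]])),
              lapply(10 ^ seq(-4, 0, length.out = 9),
                     function(k0) c(log(k0), start[["xo"]])))
  fits <- purrr::compact(lapply(starts, try_fit))
  if (length(fits) == 0) {
    stop("psychometric fit failed to converge from all starting values; ",
         "points: ", paste(sprintf("(%g, %.3f)", x, p), collapse = " "),
         call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  k_hat <- exp(best$par[1])
  xo_hat <- best$par[2]

  # Gauss-Newton style covariance: for least squares, the SSE Hessian at the
  # optimum is ~ 2 J'J, so cov(k, xo) ~ sigma^2 solve(H / 2)
  sse_kxo <- function(par) sum((p - logistic2(x, par[1], par[2]))^2)
  n <- length(x)
  sigma2 <- best$value / max(n - 2, 1)
  se <- tryCatch({
    h <- stats::optimHess(c(k_hat, xo_hat), sse_kxo)
    v <- sigma2 * solve(h / 2)
    sqrt(pmax(diag(v), 0))
  }, error = function(e) c(NA_real_, NA_real_))

  fitted_p <- logistic2(x, k_hat, xo_hat)
  r <- if (stats::sd(fitted_p) > 0) cor(p, fitted_p) else NA_real_

  structure(list(
    k = k_hat, xo = xo_hat,
    k_se = se[1], xo_se = se[2],
    r = r, r_squared = r^2,
    threshold_ms = log(3) / k_hat,
    threshold_se_ms = log(3) * se[1] / k_hat^2,
    points = tibble::tibble(asynchrony_ms = x, p_left = p,
                            fitted = fitted_p),
    n_points = length(x)
  ), class = "toj_psychfit")
}

#' 75% JND threshold from a fitted psychometric function
#'
#' The threshold is half the asynchrony change required to move the fitted
#' left-first rate from 0.25 to 0.75. For the logistic used here this is
#' `ln(3)/K` in closed form; the standard error comes from the delta method,
#' `SE = ln(3) SE(K) / K^2`.
#'
#' @param fit a `toj_psychfit`, or a plain list with elements `k` and
#'   optionally `k_se`.
#' @return a named list with `threshold_ms` and `threshold_se_ms`.
#' @export
threshold_from_fit <- function(fit) {
  k <- fit$k
  if (is.null(k) || !is.finite(k) || k <= 0) {
    stop("threshold requires a positive fitted slope K", call. = FALSE)
  }
  k_se <- if (!is.null(fit$k_se)) fit$k_se else NA_real_
  list(threshold_ms = log(3) / k, threshold_se_ms = log(3) * k_se / k^2)
}

#' Fit psychometric functions for every group and condition
#'
#' Convenience wrapper running [build_points()] then [fit_sigmoid()] per
#' group x motion x initial-directions combination.
#'
#' @param trials a validated `toj_trials` tibble.
#' @return a tibble with one row per fitted curve: `group`, `motion_type`,
#'   `initial_directions`, `k`, `xo`, `r`, `r_squared`, `threshold_ms`,
#'   `threshold_se_ms`, and a list-column `fit` of `toj_psychfit` objects.
#' @export
fit_psychometric <- function(trials) {
  pts <- build_points(trials)
  pts |>
    dplyr::group_by(.data$group, .data$motion_type,
                    .data$initial_directions) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_sigmoid(df)
      tibble::tibble(k = f$k, xo = f$xo, r = f$r, r_squared = f$r_squared,
                     threshold_ms = f$threshold_ms,
                     threshold_se_ms = f$threshold_se_ms, fit = list(f))
    }) |>
    dplyr::ungroup()
}
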
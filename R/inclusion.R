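# Inclusion screening: a participant enters the analyses only if their TOJ
# accuracy over the 480 nonzero-asynchrony analysis trials exceeds chance by
# an exact one-tailed binomial test at p < 0.001. Zero-asynchrony trials have
# no objectively correct answer and never count.

#' Exact one-tailed binomial tail probability against chance
#'
#' `P(X >= n_correct)` for `X ~ Binomial(n_trials, 0.5)`.
#'
#' @param n_correct number of correct responses.
#' @param n_trials number of scorable trials.
#' @return the upper-tail probability.
#' @export
binomial_tail_p <- function(n_correct, n_trials) {
  pbinom(n_correct - 1, n_trials, 0.5, lower.tail = FALSE)
}

#' Minimal correct count (and percentage) passing the inclusion screen
#'
#' The smallest `k` such that `P(X >= k) < alpha` for
#' `X ~ Binomial(n_trials, 0.5)`, found by exact tail summation.
#'
#' @param n_trials number of scorable trials (default 480).
#' @param alpha significance level of the screen (default 0.001).
#' @return a list with `k`, `percent` (`100 k / n_trials`), and `p` (the
#'   exact tail probability at `k`).
#' @export
minimal_inclusion_count <- function(n_trials = 480L, alpha = 0.001) {
  k <- seq(0L, n_trials)
  p <- binomial_tail_p(k, n_trials)
  k_star <- k[match(TRUE, p < alpha)]
  list(k = k_star, percent = 100 * k_star / n_trials,
       p = binomial_tail_p(k_star, n_trials))
}

#' Screen one participant's trials against chance
#'
#' @param trials the trials of a single participant (practice trials are
#'   dropped internally); the participant must contribute exactly 480
#'   nonzero-asynchrony analysis trials.
#' @param alpha significance level (default 0.001; inclusion requires the
#'   exact tail p to fall strictly below it).
#' @return a one-row tibble: `participant_id`, `group`, `n_correct`,
#'   `n_trials`, `percent_correct`, `p_value`, `included`.
#' @export
screen_participant <- function(trials, alpha = 0.001) {
  nz <- trials |>
    analysis_trials() |>
    dplyr::filter(.data$asynchrony_ms != 0)
  if (length(unique(nz$participant_id)) != 1) {
    stop("screen_participant expects trials from exactly one participant",
         call. = FALSE)
  }
  n_expected <- toj_design$nonzero_analysis_trials
  if (nrow(nz) != n_expected) {
    stop("expected ", n_expected, " nonzero-asynchrony analysis trials, got ",
         nrow(nz), call. = FALSE)
  }
  n_correct <- sum(nz$designated_correct)
  p <- binomial_tail_p(n_correct, n_expected)
  tibble::tibble(
    participant_id = nz$participant_id[1],
    group = nz$group[1],
    n_correct = n_correct,
    n_trials = n_expected,
    percent_correct = 100 * n_correct / n_expected,
    p_value = p,
    included = p < alpha
  )
}

#' Screen a whole cohort
#'
#' Applies [screen_participant()] to every participant; the group-level
#' inclusion counts and percentages are attached as the `"group_summary"`
#' attribute.
#'
#' @param trials a validated `toj_trials` tibble.
#' @param alpha significance level (default 0.001).
#' @return a tibble with one row per participant (see
#'   [screen_participant()]); attribute `"group_summary"` holds per-group
#'   `n_total`, `n_included`, `percent_included`.
#' @export
screen_cohort <- function(trials, alpha = 0.001) {
  report <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(screen_participant, alpha = alpha) |>
    dplyr::arrange(.data$participant_id)
  summary <- report |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_included = sum(.data$included),
                     percent_included = 100 * mean(.data$included),
                     .groups = "drop")
  attr(report, "group_summary") <- summary
  report
}

#' Keep only included participants' trials
#'
#' @param trials a validated `toj_trials` tibble.
#' @param report output of [screen_cohort()] on the same trials (recomputed
#'   if omitted).
#' @return the trials of included participants only.
#' @export
included_trials <- function(trials, report = NULL) {
  if (is.null(report)) report <- screen_cohort(trials)
  keep <- report$participant_id[report$included]
  dplyr::filter(trials, .data$participant_id %in% keep)
}
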
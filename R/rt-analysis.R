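# Reaction-time medians over the 28 design cells, group difference lists,
# and rank-based (Spearman) correlation analyses. The RT clock convention of
# the data model: rt_ms runs from stimulus offset to the response key press.

#' Per-participant median reaction times in the 28 design cells
#'
#' Medians are taken over each participant's analysis trials within every
#' motion x initial-directions x asynchrony cell (nominally 20 trials).
#'
#' @param trials a validated `toj_trials` tibble.
#' @return a tibble with one row per participant x cell: `participant_id`,
#'   `group`, `motion_type`, `initial_directions`, `asynchrony_ms`,
#'   `rt_median_ms`, `n_trials`.
#' @export
rt_medians <- function(trials) {
  out <- trials |>
    analysis_trials() |>
    dplyr::group_by(.data$participant_id, .data$group, .data$motion_type,
                    .data$initial_directions, .data$asynchrony_ms) |>
    dplyr::summarise(rt_median_ms = median(.data$rt_ms),
                     n_trials = dplyr::n(), .groups = "drop")
  n_cells <- length(toj_design$motion_types) *
    length(toj_design$initial_directions) * length(toj_design$asynchronies_ms)
  short <- out |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n != n_cells)
  if (nrow(short) > 0) {
    stop("participant(s) missing design cells: ",
         paste(short$participant_id, collapse = ", "), call. = FALSE)
  }
  out
}

#' Group median reaction times per design cell
#'
#' The group value in each cell is the median across that group's
#' participants of the participant-level cell medians.
#'
#' @param rt_tbl output of [rt_medians()].
#' @return a tibble with one row per group x cell.
#' @export
group_rt_medians <- function(rt_tbl) {
  rt_tbl |>
    dplyr::group_by(.data$group, .data$motion_type, .data$initial_directions,
                    .data$asynchrony_ms) |>
    dplyr::summarise(rt_median_ms = median(.data$rt_median_ms),
                     n_participants = dplyr::n(), .groups = "drop")
}

#' Group differences in median reaction time (28-cell difference lists)
#'
#' For each ordered group pair (percussion - brass, brass - color guard,
#' percussion - color guard, restricted to groups present), lists the 28
#' cell-wise differences of group median RTs and summarizes each list by its
#' median and by the differences of smallest and largest magnitude (signs
#' retained). The magnitude convention matches how such lists are usually
#' reported when one group is uniformly faster: "minimum" is the difference
#' closest to zero, "maximum" the most extreme.
#'
#' @param rt_tbl output of [rt_medians()] (participant level).
#' @return a tibble with one row per group pair: `comparison`,
#'   `median_diff_ms`, `min_diff_ms`, `max_diff_ms`, `n_conditions`; the full
#'   cell-wise difference lists are attached as the `"cellwise"` attribute.
#' @export
group_rt_differences <- function(rt_tbl) {
  grp <- group_rt_medians(rt_tbl)
  groups <- intersect(toj_design$groups, unique(grp$group))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  wide <- grp |>
    dplyr::select(-"n_participants") |>
    tidyr::pivot_wider(names_from = "group", values_from = "rt_median_ms")

  cellwise <- purrr::map_dfr(pairs, function(pr) {
    wide |>
      dplyr::mutate(comparison = paste(pr[1], "-", pr[2]),
                    diff_ms = .data[[pr[1]]] - .data[[pr[2]]]) |>
      dplyr::select("comparison", "motion_type", "initial_directions",
                    "asynchrony_ms", "diff_ms")
  })

  out <- cellwise |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      median_diff_ms = median(.data$diff_ms),
      min_diff_ms = .data$diff_ms[which.min(abs(.data$diff_ms))],
      max_diff_ms = .data$diff_ms[which.max(abs(.data$diff_ms))],
      n_conditions = dplyr::n(), .groups = "drop"
    )
  attr(out, "cellwise") <- cellwise
  out
}

#' Chance probability of one fixed group ordering recurring everywhere
#'
#' Under independent uniformly random orderings of `n_groups` values in each
#' of `n_conditions` conditions, one pre-specified strict ordering recurs in
#' every condition with probability `(1 / n_groups!)^n_conditions`. With 3
#' groups and 28 conditions this is (1/6)^28, about 1.63e-22.
#'
#' @param n_conditions number of independent conditions (>= 1).
#' @param n_groups number of groups ordered within each condition (>= 2).
#' @return the probability.
#' @export
ordering_probability <- function(n_conditions, n_groups) {
  if (n_groups < 2 || n_conditions < 1) {
    stop("need n_groups >= 2 and n_conditions >= 1", call. = FALSE)
  }
  (1 / factorial(n_groups))^n_conditions
}

#' Spearman rank correlation of two paired metrics
#'
#' Both metrics are rank transformed (average ranks on ties) and their
#' Pearson correlation returned, together with the asymptotic p-value.
#'
#' @param a,b paired numeric vectors, `n >= 4`, neither constant.
#' @return a list with `r`, `p_value`, `n`.
#' @export
rank_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant metric: rank correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' Rank correlations between reaction time and d' per motion condition
#'
#' For each motion x initial-directions condition: each included
#' participant's median analysis-trial RT in that condition is paired with
#' their pooled d' for the condition, both are rank transformed across all
#' participants jointly, and the Spearman correlation computed. RT ranks
#' ascend with slowness and d' ranks descend with sensitivity
#' (rank 1 = fastest / most sensitive), so speed-accuracy coupling appears
#' as a positive correlation. Per-group trendline slopes on the ranks are
#' included.
#'
#' @param trials a validated `toj_trials` tibble (included participants).
#' @param dprime_tbl output of [dprime_table()] on the same trials.
#' @return a list with `correlations` (one row per condition: `r`,
#'   `p_value`, `n`) and `ranks` (the per-participant rank pairs with
#'   per-group slopes joined).
#' @export
rt_dprime_rank_correlations <- function(trials, dprime_tbl) {
  rt_cond <- trials |>
    analysis_trials() |>
    dplyr::group_by(.data$participant_id, .data$group, .data$motion_type,
                    .data$initial_directions) |>
    dplyr::summarise(rt_ms = median(.data$rt_ms), .groups = "drop")
  dp_cond <- dprime_tbl |>
    dplyr::filter(.data$asynchrony_class == "pooled") |>
    dplyr::select("participant_id", "motion_type", "initial_directions",
                  "dprime")
  dat <- dplyr::inner_join(
    rt_cond, dp_cond,
    by = c("participant_id", "motion_type", "initial_directions"))

  ranks <- dat |>
    dplyr::group_by(.data$motion_type, .data$initial_directions) |>
    dplyr::mutate(rt_rank = rank(.data$rt_ms),
                  dprime_rank = rank(-.data$dprime)) |>
    dplyr::ungroup()

  correlations <- ranks |>
    dplyr::group_by(.data$motion_type, .data$initial_directions) |>
    dplyr::group_modify(function(df, key) {
      rc <- rank_correlation(df$rt_rank, df$dprime_rank)
      tibble::as_tibble(rc)
    }) |>
    dplyr::ungroup()

  slopes <- ranks |>
    dplyr::group_by(.data$motion_type, .data$initial_directions,
                    .data$group) |>
    dplyr::group_modify(function(df, key) {
      sl <- unname(coef(lm(dprime_rank ~ rt_rank, data = df))[2])
      tibble::tibble(slope = sl, n = nrow(df))
    }) |>
    dplyr::ungroup()

  list(correlations = correlations, ranks = ranks, group_slopes = slopes)
}

#' Within-group rank-correlation matrix across motion conditions
#'
#' For a per-participant, per-condition metric (d' or median RT), computes
#' the Spearman correlation between every pair of the four motion x
#' initial-directions conditions, separately within each group — the shape
#' of the within-group consistency tables.
#'
#' @param values a tibble with columns `participant_id`, `group`,
#'   `motion_type`, `initial_directions`, and the metric named by `metric`.
#' @param metric name of the metric column (e.g. `"dprime"` or
#'   `"rt_median_ms"`).
#' @return a tibble with one row per group and condition pair: `group`,
#'   `condition_a`, `condition_b`, `r`, `p_value`, `n`.
#' @export
condition_rank_cor_matrix <- function(values, metric = "dprime") {
  cells <- c("radial_same", "radial_opposite",
             "rotational_same", "rotational_opposite")
  wide <- values |>
    dplyr::mutate(cell = paste(.data$motion_type, .data$initial_directions,
                               sep = "_")) |>
    dplyr::select("participant_id", "group", "cell",
                  value = dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
  if (!all(cells %in% names(wide)) || anyNA(wide[cells])) {
    stop("every participant needs the metric in all four conditions",
         call. = FALSE)
  }
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  wide |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      purrr::map_dfr(pairs, function(pr) {
        rc <- rank_correlation(df[[pr[1]]], df[[pr[2]]])
        tibble::tibble(condition_a = pr[1], condition_b = pr[2],
                       r = rc$r, p_value = rc$p_value, n = rc$n)
      })
    }) |>
    dplyr::ungroup()
}
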
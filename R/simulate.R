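# Synthetic TOJ observers: a logistic response model with lapses plus a
# shifted-lognormal reaction-time model, arranged in the experiment's
# 2 (motion) x 2 (initial directions) x 7 (asynchrony) x 20 (repeat) design.

#' Specify a synthetic cohort
#'
#' Defines the generative parameters for a cohort of synthetic TOJ observers.
#' Each observer responds "left first" with probability
#' `lambda/2 + (1 - lambda) / (1 + exp(-K (X - Xo)))` at signed asynchrony
#' `X`, so the 75% JND of a lapse-free observer is `ln(3)/K`. Observers in a
#' group share a target median threshold; an observer-level lognormal factor
#' (common to all four motion x direction cells, so individual differences
#' are consistent across conditions) scatters thresholds around the target,
#' and per-condition multipliers impose the radial/rotational by
#' same/opposite difficulty profile. Reaction times are lognormal around a
#' group-level base, with an additive slowing at the uninformative zero
#' asynchrony.
#'
#' Defaults emulate a drum-corps-style cohort: group sizes 25/67/29
#' (percussion, brass, color guard), target median thresholds 30/80/200 ms,
#' radial-opposite cells twice as hard and rotational-opposite cells slightly
#' easier than the rest, and group reaction-time bases ordered
#' percussion < brass < color guard.
#'
#' @param n named integer vector of group sizes.
#' @param threshold_ms named numeric vector of target group median 75% JNDs, ms.
#' @param threshold_sdlog lognormal dispersion (sdlog) of the observer-level
#'   threshold factor; 0 makes every observer hit the group target exactly.
#' @param condition_multiplier named numeric vector of threshold multipliers
#'   for the four `motion_initialdirections` cells; all 1 gives a flat
#'   difficulty profile.
#' @param xo_sd SD (ms) of the observer-level midpoint (bias) `Xo`.
#' @param lapse lapse rate in `[0, 0.1]`, shared by all observers.
#' @param rt_base_ms named numeric vector of group median reaction times, ms.
#' @param rt_base_sdlog lognormal dispersion of the observer-level RT base.
#' @param rt_zero_penalty_ms additive median RT slowing at zero asynchrony, ms.
#' @param rt_noise_scale trial-level lognormal RT noise (sdlog).
#' @param seed integer seed for cohort sampling.
#' @return a `toj_cohort_spec` list.
#' @export
cohort_spec <- function(n = c(percussion = 25L, brass = 67L, color_guard = 29L),
                        threshold_ms = c(percussion = 30, brass = 80,
                                         color_guard = 200),
                        threshold_sdlog = 0.3,
                        condition_multiplier = c(radial_same = 1,
                                                 radial_opposite = 2,
                                                 rotational_same = 1,
                                                 rotational_opposite = 0.9),
                        xo_sd = 10,
                        lapse = 0.02,
                        rt_base_ms = c(percussion = 400, brass = 474,
                                       color_guard = 540),
                        rt_base_sdlog = 0.15,
                        rt_zero_penalty_ms = 150,
                        rt_noise_scale = 0.12,
                        seed = 1L) {
  groups <- names(n)
  if (is.null(groups) || !all(groups %in% toj_design$groups)) {
    stop("n must be named with groups among: ",
         paste(toj_design$groups, collapse = ", "), call. = FALSE)
  }
  if (any(n < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  if (threshold_sdlog < 0 || rt_base_sdlog < 0 || rt_noise_scale < 0) {
    stop("dispersions must be non-negative", call. = FALSE)
  }
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]", call. = FALSE)
  if (any(threshold_ms[groups] <= 0) || any(condition_multiplier <= 0)) {
    stop("thresholds and condition multipliers must be positive", call. = FALSE)
  }
  if (any(rt_base_ms[groups] <= 0) || rt_zero_penalty_ms < 0) {
    stop("rt_base_ms must be positive and rt_zero_penalty_ms non-negative",
         call. = FALSE)
  }
  cells <- paste(rep(toj_design$motion_types, each = 2),
                 toj_design$initial_directions, sep = "_")
  if (!setequal(names(condition_multiplier), cells)) {
    stop("condition_multiplier must be named: ", paste(cells, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n = n, threshold_ms = threshold_ms, threshold_sdlog = threshold_sdlog,
    condition_multiplier = condition_multiplier, xo_sd = xo_sd, lapse = lapse,
    rt_base_ms = rt_base_ms, rt_base_sdlog = rt_base_sdlog,
    rt_zero_penalty_ms = rt_zero_penalty_ms, rt_noise_scale = rt_noise_scale,
    seed = as.integer(seed)
  ), class = "toj_cohort_spec")
}

#' Read a cohort specification from a YAML or JSON config file
#'
#' The file may set any argument of [cohort_spec()]; unset fields keep their
#' defaults. Named vectors are given as mappings.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `toj_cohort_spec`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(cfg$n)) cfg$n <- setNames(as.integer(round(cfg$n)), names(cfg$n))
  do.call(cohort_spec, cfg)
}

#' Sample a cohort of synthetic observers
#'
#' Draws one observer per participant from the group-level distributions in
#' `spec`. The result is tidy: one row per participant and motion x direction
#' cell, carrying the cell's generating slope `k` (1/ms), midpoint `xo` (ms),
#' threshold (`ln(3)/k`, ms), and the observer's lapse and reaction-time
#' parameters.
#'
#' @param spec a [cohort_spec()].
#' @return a tibble with `n_total * 4` rows.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "toj_cohort_spec"))
  withr::with_seed(spec$seed, {
    groups <- names(spec$n)
    obs <- purrr::map_dfr(groups, function(g) {
      ng <- spec$n[[g]]
      tibble::tibble(
        participant_id = sprintf("%s_%03d", g, seq_len(ng)),
        group = g,
        thr_factor = exp(rnorm(ng, 0, spec$threshold_sdlog)),
        xo = rnorm(ng, 0, spec$xo_sd),
        lapse = spec$lapse,
        rt_base = spec$rt_base_ms[[g]] * exp(rnorm(ng, 0, spec$rt_base_sdlog)),
        rt_zero_penalty = spec$rt_zero_penalty_ms,
        rt_noise_scale = spec$rt_noise_scale
      )
    })
    cells <- tidyr::expand_grid(
      motion_type = toj_design$motion_types,
      initial_directions = toj_design$initial_directions
    )
    out <- tidyr::crossing(obs, cells) |>
      dplyr::mutate(
        cell = paste(.data$motion_type, .data$initial_directions, sep = "_"),
        threshold_ms = spec$threshold_ms[.data$group] *
          spec$condition_multiplier[.data$cell] * .data$thr_factor,
        k = log(3) / .data$threshold_ms
      ) |>
      dplyr::select("participant_id", "group", "motion_type",
                    "initial_directions", "threshold_ms", "k", "xo", "lapse",
                    "rt_base", "rt_zero_penalty", "rt_noise_scale") |>
      dplyr::arrange(.data$participant_id)
    attr(out, "cohort_seed") <- spec$seed
    out
  })
}

#' Simulate trial-level TOJ data from a cohort of observers
#'
#' Runs each observer through the full experiment: one practice block
#' (`block == 0`) and five analysis blocks of 112 trials, each block built
#' from four randomized 28-trial sets crossing motion type, initial
#' directions, and the seven asynchronies. Responses follow
#' `P(left_first | X) = lambda/2 + (1 - lambda) / (1 + exp(-k (X - xo)))`;
#' reaction times are lognormal around the observer's base (sdlog =
#' `rt_noise_scale`) plus `rt_zero_penalty` at `X == 0`. On zero-asynchrony
#' trials the designated "correct" response is chosen left/right with equal
#' probability, mirroring the neutral feedback those trials carry.
#'
#' @param observers a cohort tibble from [sample_cohort()].
#' @param seed integer seed for trial simulation (kept separate from the
#'   cohort seed, and recorded in the result's provenance).
#' @param include_practice simulate the practice block too (default `TRUE`).
#' @return a validated `toj_trials` tibble.
#' @export
simulate_trials <- function(observers, seed = 1L, include_practice = TRUE) {
  if (nrow(observers) == 0) stop("empty observer collection", call. = FALSE)
  stopifnot(all(observers$k > 0), all(observers$rt_base > 0))
  blocks <- if (include_practice) 0:5 else 1:5
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::crossing(
      observers,
      asynchrony_ms = toj_design$asynchronies_ms,
      block = as.integer(blocks),
      set = 1:4
    )
    m <- nrow(grid)
    p_left <- grid$lapse / 2 +
      (1 - grid$lapse) / (1 + exp(-grid$k * (grid$asynchrony_ms - grid$xo)))
    response <- ifelse(runif(m) < p_left, "left_first", "right_first")
    designated <- ifelse(grid$asynchrony_ms > 0, "left_first",
                  ifelse(grid$asynchrony_ms < 0, "right_first",
                         ifelse(runif(m) < 0.5, "left_first", "right_first")))
    # recorded at microsecond resolution so trial tables serialize stably
    rt <- round(exp(log(grid$rt_base) + rnorm(m, 0, grid$rt_noise_scale)) +
      grid$rt_zero_penalty * (grid$asynchrony_ms == 0), 3)
    trials <- tibble::tibble(
      participant_id = grid$participant_id,
      group = grid$group,
      motion_type = grid$motion_type,
      initial_directions = grid$initial_directions,
      asynchrony_ms = grid$asynchrony_ms,
      response = response,
      designated_correct = response == designated,
      rt_ms = rt,
      block = grid$block
    )
    # randomize trial order within each 28-trial set, then order blocks/sets
    trials <- trials[order(grid$participant_id, grid$block, grid$set,
                           runif(m)), ]
    trials <- validate_trials(trials)
    attr(trials, "provenance") <- list(
      generator = "tojlab::simulate_trials",
      cohort_seed = attr(observers, "cohort_seed"),
      trial_seed = as.integer(seed)
    )
    trials
  })
}
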
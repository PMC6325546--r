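# Median-statistic Monte Carlo permutation inference. Two procedures:
# (1) pairwise group differences in d', with null distributions built by
#     shuffling group labels over the pooled participants; and
# (2) the 2x2 motion-type by initial-directions interaction, with null
#     distributions built by shuffling each participant's four cell values
#     across the cell labels (individual differences are preserved exactly).
# Significance follows the 95th-percentile rule: the observed statistic must
# strictly exceed the 95th percentile of the simulated null.

new_perm_result <- function(type, observed, null_stats, n_sims, seed,
                            direction, plus_one) {
  p_num <- if (direction == "greater") {
    sum(null_stats >= observed)
  } else {
    sum(abs(null_stats) >= abs(observed))
  }
  p_value <- if (plus_one) (p_num + 1) / (n_sims + 1) else p_num / n_sims
  structure(list(
    type = type,
    observed_stat = observed,
    null_stats = null_stats,
    p_value = p_value,
    n_sims = n_sims,
    seed = seed,
    direction = direction,
    plus_one = plus_one,
    null_q95 = unname(quantile(null_stats, 0.95)),
    significant = observed > unname(quantile(null_stats, 0.95))
  ), class = "toj_perm")
}

#' Median group difference
#'
#' `median(d1) - median(d2)`, with the usual midpoint-of-the-middle-two
#' convention for even-sized groups.
#'
#' @param d1,d2 numeric vectors of per-participant d' values (non-empty).
#' @return the median difference.
#' @export
group_median_diff <- function(d1, d2) {
  if (length(d1) == 0 || length(d2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  median(d1) - median(d2)
}

#' Permutation test for a median group difference
#'
#' Builds the null by repeatedly re-partitioning the pooled values into the
#' original group sizes (shuffling group labels) and recomputing the median
#' difference. The default direction is one-sided: the test is significant
#' when the observed difference strictly exceeds the 95th percentile of the
#' simulated null, and `p_value` is the proportion of simulated statistics
#' at or above the observed one.
#'
#' @param d1,d2 numeric vectors of per-participant values.
#' @param n_sims number of simulated shuffles (default 10,000).
#' @param seed integer seed; identical seed and `n_sims` reproduce the
#'   result exactly.
#' @param direction `"greater"` (default) or `"two_sided"`.
#' @param plus_one use the `(count + 1) / (n_sims + 1)` p-value convention
#'   instead of the plain rank proportion (off by default).
#' @return a `toj_perm` object.
#' @export
permute_groups <- function(d1, d2, n_sims = 10000L, seed = 1L,
                           direction = c("greater", "two_sided"),
                           plus_one = FALSE) {
  direction <- match.arg(direction)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  pool <- c(d1, d2)
  n1 <- length(d1)
  n <- length(pool)
  if (n < 2 || n1 == 0 || n1 == n) {
    stop("need two non-empty groups", call. = FALSE)
  }
  observed <- group_median_diff(d1, d2)
  null_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_sims), function(i) {
      idx <- sample.int(n, n1)
      median(pool[idx]) - median(pool[-idx])
    }, numeric(1))
  })
  new_perm_result("group_median_diff", observed, null_stats,
                  as.integer(n_sims), as.integer(seed), direction, plus_one)
}

# the 24 permutations of 4 labels, one per row (computed once per session)
perm_table_4 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
      tab <<- unname(g[apply(g, 1, function(r) length(unique(r)) == 4L), ,
                       drop = FALSE])
      storage.mode(tab) <- "integer"
    }
    tab
  }
})

# coerce a long (participant x 4 cells) d' table to an n x 4 matrix with
# columns radial_same, radial_opposite, rotational_same, rotational_opposite
interaction_matrix <- function(cond_values) {
  cells <- c("radial_same", "radial_opposite",
             "rotational_same", "rotational_opposite")
  wide <- cond_values |>
    dplyr::mutate(cell = paste(.data$motion_type, .data$initial_directions,
                               sep = "_")) |>
    dplyr::select("participant_id", "cell", "dprime") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "dprime")
  if (!all(cells %in% names(wide)) || anyNA(wide[cells])) {
    stop("every participant needs d' values for all four motion x direction ",
         "cells", call. = FALSE)
  }
  as.matrix(wide[cells])
}

#' 2x2 motion-type by initial-directions interaction statistic
#'
#' On the group medians of the four cell values:
#' `(median radial-same - median radial-opposite) -
#'  (median rotational-same - median rotational-opposite)`.
#'
#' @param cond_values a tibble with columns `participant_id`, `motion_type`,
#'   `initial_directions`, `dprime` — four rows (cells) per participant, e.g.
#'   the pooled rows of [dprime_table()].
#' @return the interaction magnitude in d' units.
#' @export
interaction_stat <- function(cond_values) {
  m <- interaction_matrix(cond_values)
  meds <- apply(m, 2, median)
  (meds[["radial_same"]] - meds[["radial_opposite"]]) -
    (meds[["rotational_same"]] - meds[["rotational_opposite"]])
}

#' Within-participant permutation test for the 2x2 interaction
#'
#' Each simulation independently permutes, within every participant, that
#' participant's four cell values across the four condition labels, then
#' recomputes the median-based interaction statistic. Shuffling within
#' participants preserves each individual's multiset of values exactly, so
#' consistent individual differences survive into every simulation.
#' Significance follows the same strict 95th-percentile rule as
#' [permute_groups()].
#'
#' @inheritParams permute_groups
#' @inheritParams interaction_stat
#' @return a `toj_perm` object.
#' @export
permute_interaction <- function(cond_values, n_sims = 10000L, seed = 1L,
                                direction = c("greater", "two_sided"),
                                plus_one = FALSE) {
  direction <- match.arg(direction)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  m <- interaction_matrix(cond_values)
  n <- nrow(m)
  observed <- {
    meds <- apply(m, 2, median)
    (meds[1] - meds[2]) - (meds[3] - meds[4])
  }
  mt <- t(m)                      # 4 x n; columns are participants
  offs <- 4L * (seq_len(n) - 1L)
  ptab <- perm_table_4()          # the 24 permutations of 4 labels
  null_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_sims), function(i) {
      pid <- sample.int(24L, n, replace = TRUE)
      idx <- as.vector(t(ptab[pid, , drop = FALSE])) + rep(offs, each = 4L)
      mp <- matrix(mt[idx], 4L, n)
      meds <- apply(mp, 1, median)
      (meds[1] - meds[2]) - (meds[3] - meds[4])
    }, numeric(1))
  })
  new_perm_result("interaction", unname(observed), null_stats,
                  as.integer(n_sims), as.integer(seed), direction, plus_one)
}

#' Lilliefors normality test with a Monte Carlo null
#'
#' Kolmogorov-Smirnov distance between the sample's empirical CDF and a
#' normal CDF whose mean and SD are estimated from the same sample. Because
#' the parameters are estimated, the classical KS null does not apply; the
#' p-value is instead the proportion of `n_mc` simulated standard-normal
#' samples of the same size whose statistic meets or exceeds the observed
#' one.
#'
#' @param values numeric sample, `n >= 4`, non-constant.
#' @param n_mc Monte Carlo replicates for the null table (default 10,000).
#' @param seed integer seed for the null table.
#' @return a list with `statistic`, `p_value`, `n`, `n_mc`, `seed`.
#' @export
lilliefors <- function(values, n_mc = 10000L, seed = 1L) {
  n <- length(values)
  if (n < 4) stop("Lilliefors test requires n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) stop("sample is constant", call. = FALSE)
  stat <- function(x) {
    nx <- length(x)
    z <- pnorm(sort(x), mean(x), stats::sd(x))
    i <- seq_len(nx)
    max(pmax(i / nx - z, z - (i - 1) / nx))
  }
  d_obs <- stat(values)
  null_d <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_mc), function(i) stat(rnorm(n)), numeric(1))
  })
  list(statistic = d_obs, p_value = mean(null_d >= d_obs), n = n,
       n_mc = as.integer(n_mc), seed = as.integer(seed))
}

#' Run the pairwise permutation tests for every condition and group pair
#'
#' Applies [permute_groups()] to the per-participant d' values of each
#' motion x initial-directions condition (at the requested asynchrony
#' classes) for each ordered pair of groups, mirroring the layout of the
#' pairwise-comparison results table.
#'
#' @param dprime_tbl output of [dprime_table()].
#' @param asynchrony_class which classes to test (default `"pooled"`).
#' @param n_sims,seed,plus_one passed to [permute_groups()]; each test uses
#'   a distinct seed derived deterministically from `seed`.
#' @return a tibble with one row per condition x class x group pair:
#'   observed median difference, p-value, significance flag, seeds.
#' @export
pairwise_group_tests <- function(dprime_tbl, asynchrony_class = "pooled",
                                 n_sims = 10000L, seed = 1L,
                                 plus_one = FALSE) {
  groups <- intersect(toj_design$groups, unique(dprime_tbl$group))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  dat <- dplyr::filter(dprime_tbl,
                       .data$asynchrony_class %in% !!asynchrony_class)
  combos <- tidyr::expand_grid(
    motion_type = toj_design$motion_types,
    initial_directions = toj_design$initial_directions,
    class = asynchrony_class,
    pair = pairs
  )
  purrr::pmap_dfr(combos, function(motion_type, initial_directions, class,
                                   pair) {
    sub <- dplyr::filter(dat, .data$motion_type == !!motion_type,
                         .data$initial_directions == !!initial_directions,
                         .data$asynchrony_class == !!class)
    d1 <- sub$dprime[sub$group == pair[1]]
    d2 <- sub$dprime[sub$group == pair[2]]
    test_seed <- as.integer((seed * 7919 +
      match(motion_type, toj_design$motion_types) * 101 +
      match(initial_directions, toj_design$initial_directions) * 211 +
      match(class, c("67", "133", "200", "pooled")) * 307 +
      match(pair[1], toj_design$groups) * 401 +
      match(pair[2], toj_design$groups) * 503) %% .Machine$integer.max)
    res <- permute_groups(d1, d2, n_sims = n_sims, seed = test_seed,
                          plus_one = plus_one)
    tibble::tibble(
      motion_type = motion_type, initial_directions = initial_directions,
      asynchrony_class = class,
      comparison = paste(pair[1], "vs", pair[2]),
      median_difference = res$observed_stat, p_value = res$p_value,
      significant = res$significant, n_sims = res$n_sims, seed = res$seed
    )
  })
}

#' Run the 2x2 interaction permutation test per group and combined
#'
#' Applies [permute_interaction()] to each group separately and to all
#' groups combined, at the requested asynchrony classes, mirroring the
#' layout of the interaction results table.
#'
#' @inheritParams pairwise_group_tests
#' @return a tibble with one row per group (plus `"all"`) and class.
#' @export
interaction_tests <- function(dprime_tbl, asynchrony_class = "pooled",
                              n_sims = 10000L, seed = 1L, plus_one = FALSE) {
  groups <- intersect(toj_design$groups, unique(dprime_tbl$group))
  combos <- tidyr::expand_grid(group = c("all", groups),
                               class = asynchrony_class)
  purrr::pmap_dfr(combos, function(group, class) {
    sub <- dplyr::filter(dprime_tbl, .data$asynchrony_class == !!class)
    if (group != "all") sub <- dplyr::filter(sub, .data$group == !!group)
    test_seed <- as.integer((seed * 6271 +
      match(group, c("all", toj_design$groups)) * 109 +
      match(class, c("67", "133", "200", "pooled")) * 419) %%
        .Machine$integer.max)
    res <- permute_interaction(sub, n_sims = n_sims, seed = test_seed,
                               plus_one = plus_one)
    tibble::tibble(
      group = group, asynchrony_class = class,
      interaction_magnitude = res$observed_stat, p_value = res$p_value,
      significant = res$significant, n_sims = res$n_sims, seed = res$seed
    )
  })
}
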
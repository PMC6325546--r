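test_that("participant cell medians follow the usual median conventions", {
  tr <- make_participant_trials(rt = 400)
  # give one cell the RTs 300/400/500 (padded with 400s -> median 400)
  idx <- which(tr$asynchrony_ms == 67 & tr$motion_type == "radial" &
                 tr$initial_directions == "same")
  tr$rt_ms[idx[1:3]] <- c(300, 500, 400)
  rt <- rt_medians(validate_trials(tr))
  expect_equal(nrow(rt), 28)
  cell <- dplyr::filter(rt, asynchrony_ms == 67, motion_type == "radial",
                        initial_directions == "same")
  expect_equal(cell$rt_median_ms, 400)
  expect_true(all(rt$rt_median_ms > 0))
})

test_that("the generator's zero-asynchrony slowing is recovered from group medians", {
  spec <- cohort_spec(n = c(brass = 8L), rt_base_ms = c(brass = 450),
                      rt_base_sdlog = 0.05, rt_zero_penalty_ms = 150,
                      rt_noise_scale = 0.1, seed = 91L)
  tr <- simulate_trials(sample_cohort(spec), seed = 92L)
  grp <- group_rt_medians(rt_medians(tr))
  zero <- dplyr::filter(grp, asynchrony_ms == 0)
  nonzero <- dplyr::filter(grp, asynchrony_ms != 0)
  gap <- mean(zero$rt_median_ms) - mean(nonzero$rt_median_ms)
  expect_lt(abs(gap - 150), 25)
})

test_that("a uniform group shift appears as a constant difference list", {
  a <- make_participant_trials("a", "percussion", rt = 400)
  b <- make_participant_trials("b", "brass", rt = 474)
  diffs <- group_rt_differences(rt_medians(validate_trials(
    dplyr::bind_rows(a, b))))
  expect_equal(nrow(diffs), 1)
  expect_equal(diffs$comparison, "percussion - brass")
  expect_equal(diffs$median_diff_ms, -74)
  expect_equal(diffs$min_diff_ms, -74)
  expect_equal(diffs$max_diff_ms, -74)
  expect_equal(diffs$n_conditions, 28)
  cellwise <- attr(diffs, "cellwise")
  expect_equal(nrow(cellwise), 28)
  expect_true(all(cellwise$diff_ms == -74))
})

test_that("difference summaries are invariant to participant order and need two groups", {
  tr <- small_cohort_trials(seed_cohort = 93L, seed_trials = 94L)
  rt <- rt_medians(tr)
  shuffled <- rt[withr::with_seed(1, sample(nrow(rt))), ]
  expect_equal(group_rt_differences(rt), group_rt_differences(shuffled),
               ignore_attr = TRUE)
  solo <- dplyr::filter(rt, group == "brass")
  expect_error(group_rt_differences(solo), "two groups")
})

test_that("generator RT offsets between groups are recovered", {
  spec <- cohort_spec(n = c(percussion = 8L, brass = 8L, color_guard = 8L),
                      rt_base_ms = c(percussion = 400, brass = 470,
                                     color_guard = 535),
                      rt_base_sdlog = 0.05, rt_noise_scale = 0.1, seed = 95L)
  tr <- simulate_trials(sample_cohort(spec), seed = 96L)
  diffs <- group_rt_differences(rt_medians(tr))
  pb <- diffs$median_diff_ms[diffs$comparison == "percussion - brass"]
  bc <- diffs$median_diff_ms[diffs$comparison == "brass - color_guard"]
  expect_lt(abs(pb - (-70)), 30)
  expect_lt(abs(bc - (-65)), 30)
})

test_that("the chance probability of a fixed group ordering is (1/g!)^c", {
  expect_equal(ordering_probability(1, 3), 1 / 6)
  expect_equal(ordering_probability(2, 2), 1 / 4)
  expect_equal(ordering_probability(28, 3), (1 / 6)^28)
  expect_lt(ordering_probability(28, 3), 1.63e-22)
  expect_error(ordering_probability(0, 3), "n_conditions")
})

test_that("rank correlations hit the concordant/discordant extremes and track rho", {
  expect_equal(rank_correlation(1:10, 1:10 * 3)$r, 1)
  expect_equal(rank_correlation(1:10, 10:1)$r, -1)
  withr::with_seed(97, {
    n <- 500
    x <- rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
    rc <- rank_correlation(x, y)
    # Spearman's rho for bivariate normal rho=0.8 is (6/pi) asin(0.8/2) = 0.786
    expect_lt(abs(rc$r - 0.786), 0.04)
  })
  expect_error(rank_correlation(rep(1, 10), 1:10), "constant")
  expect_error(rank_correlation(1:3, 1:3), "at least 4")
})

test_that("rank correlations are invariant under strictly monotone transforms", {
  withr::with_seed(98, {
    x <- rexp(40)
    y <- x + rnorm(40, 0, 0.5)
  })
  base <- rank_correlation(x, y)$r
  expect_equal(rank_correlation(log(x), y)$r, base)
  expect_equal(rank_correlation(x, y^3)$r, base)
  expect_equal(rank_correlation(exp(x), sqrt(y - min(y) + 1))$r, base)
})

test_that("RT-by-d' correlations and condition matrices have the reported shapes", {
  tr <- small_cohort_trials(seed_cohort = 99L, seed_trials = 100L,
                            n = c(percussion = 4L, brass = 4L,
                                  color_guard = 4L))
  dp <- dprime_table(tr)
  res <- rt_dprime_rank_correlations(tr, dp)
  expect_equal(nrow(res$correlations), 4)      # one row per condition
  expect_true(all(res$correlations$n == 12))
  expect_equal(nrow(res$group_slopes), 12)     # 4 conditions x 3 groups
  # ranks within a condition are a permutation of 1..n (up to tie averages)
  r1 <- dplyr::filter(res$ranks, motion_type == "radial",
                      initial_directions == "same")
  expect_equal(sort(r1$rt_rank), 1:12)

  dmat <- condition_rank_cor_matrix(
    dplyr::filter(dp, asynchrony_class == "pooled"), "dprime")
  expect_equal(nrow(dmat), 18)                 # 3 groups x 6 condition pairs
  expect_true(all(dmat$r >= -1 & dmat$r <= 1))
})
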
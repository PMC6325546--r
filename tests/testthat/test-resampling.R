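test_that("the median group difference uses midpoint medians and is antisymmetric", {
  expect_equal(group_median_diff(c(1.0, 1.2, 1.4), c(0.4, 0.6, 0.8)), 0.6)
  d <- c(0.2, 0.9, 1.1)
  expect_equal(group_median_diff(d, d), 0)
  expect_equal(group_median_diff(c(1, 2), c(3, 4)),
               -group_median_diff(c(3, 4), c(1, 2)))
  expect_equal(group_median_diff(c(1, 3), c(0, 2)), 1)  # even-n midpoints
  expect_error(group_median_diff(numeric(0), 1), "non-empty")
})

test_that("permutation results are fully determined by seed and n_sims", {
  d1 <- c(1.2, 0.8, 1.5, 0.9)
  d2 <- c(0.3, 0.7, 0.2)
  a <- permute_groups(d1, d2, n_sims = 500, seed = 11)
  b <- permute_groups(d1, d2, n_sims = 500, seed = 11)
  expect_identical(a$null_stats, b$null_stats)
  expect_identical(a$p_value, b$p_value)
  c2 <- permute_groups(d1, d2, n_sims = 500, seed = 12)
  expect_false(identical(a$null_stats, c2$null_stats))
  expect_length(a$null_stats, 500)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
})

test_that("Monte-Carlo pairwise p agrees with exhaustive enumeration on small groups", {
  withr::with_seed(21, {
    for (case in 1:4) {
      d1 <- round(rnorm(3, 1), 3)
      d2 <- round(rnorm(3, 0.3), 3)
      exact <- exact_pairwise_p(d1, d2)
      mc <- permute_groups(d1, d2, n_sims = 4000, seed = 500 + case)
      se <- sqrt(exact * (1 - exact) / 4000)
      expect_lt(abs(mc$p_value - exact), max(3 * se, 0.005))
    }
  })
})

test_that("complete separation yields the minimal attainable p", {
  r <- permute_groups(c(3, 4, 5), c(0, 1, 2), n_sims = 2000, seed = 3)
  # only the identity among the 20 partitions reproduces a difference this large
  expect_lte(r$p_value, 0.12)
  expect_gt(r$p_value, 0)  # the identity partition always recurs
})

test_that("the plus-one p-value convention is available but off by default", {
  d1 <- c(2, 2, 2); d2 <- c(0, 0, 0)
  plain <- permute_groups(d1, d2, n_sims = 100, seed = 5)
  plus <- permute_groups(d1, d2, n_sims = 100, seed = 5, plus_one = TRUE)
  expect_equal(plus$p_value, (plain$p_value * 100 + 1) / 101)
})

test_that("the 2x2 interaction contrast is the difference of cell-median differences", {
  # medians (RS, RO, RotS, RotO) = (1.0, 0.5, 0.8, 0.9) -> 0.6
  m <- rbind(c(1.0, 0.5, 0.8, 0.9),
             c(1.0, 0.5, 0.8, 0.9),
             c(1.0, 0.5, 0.8, 0.9))
  expect_equal(interaction_stat(cells_from_matrix(m)), 0.6)
  # all four cell medians equal -> 0
  expect_equal(interaction_stat(cells_from_matrix(
    matrix(0.7, 3, 4) + cbind(c(-.1, 0, .1), c(-.1, 0, .1),
                              c(-.1, 0, .1), c(-.1, 0, .1)))), 0)
  # exchanging radial and rotational labels flips the sign
  expect_equal(interaction_stat(cells_from_matrix(m[, c(3, 4, 1, 2)])), -0.6)
  expect_error(interaction_stat(cells_from_matrix(m)[-1, ]), "four")
})

test_that("within-participant shuffling preserves each participant's multiset of values", {
  withr::with_seed(31, {
    m <- matrix(rnorm(5 * 4), 5, 4)
    cells <- cells_from_matrix(m)
    r <- permute_interaction(cells, n_sims = 50, seed = 7)
    # re-derive the shuffles from the same seed and check multisets directly
    ptab <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    ptab <- ptab[apply(ptab, 1, function(x) length(unique(x)) == 4), ]
    withr::with_seed(7L, {
      for (i in 1:50) {
        pid <- sample.int(24L, 5, replace = TRUE)
        for (j in 1:5) {
          expect_equal(sort(m[j, ptab[pid[j], ]]), sort(m[j, ]))
        }
      }
    })
  })
})

test_that("Monte-Carlo interaction p agrees with exhaustive enumeration for 3 participants", {
  withr::with_seed(41, {
    m <- matrix(round(rnorm(12, 0, 0.5) + rep(c(1, 0.4, 0.8, 0.9), each = 3),
                      3), 3, 4)
    exact <- exact_interaction_p(m)
    mc <- permute_interaction(cells_from_matrix(m), n_sims = 4000, seed = 9)
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(mc$p_value - exact), max(3 * se, 0.005))
  })
})

test_that("an injected interaction of 1 d' at n=25 is detected", {
  withr::with_seed(51, {
    hits <- 0
    for (s in 1:10) {
      base <- rnorm(25, 1.5, 0.4)
      m <- cbind(base + 0.5 + rnorm(25, 0, 0.4),
                 base - 0.5 + rnorm(25, 0, 0.4),
                 base + rnorm(25, 0, 0.4),
                 base + rnorm(25, 0, 0.4))
      r <- permute_interaction(cells_from_matrix(m), n_sims = 2000,
                               seed = 600 + s)
      if (r$p_value < 0.01) hits <- hits + 1
    }
    expect_gte(hits, 9)
  })
})

test_that("Lilliefors flags exponential but not normal samples, and rejects degenerate input", {
  withr::with_seed(61, {
    x_norm <- rnorm(100)
    x_exp <- rexp(100)
  })
  r_norm <- lilliefors(x_norm, n_mc = 2000, seed = 1)
  r_exp <- lilliefors(x_exp, n_mc = 2000, seed = 1)
  expect_gt(r_norm$p_value, 0.05)
  expect_lt(r_exp$p_value, 0.05)
  expect_error(lilliefors(c(1, 2, 3)), "n >= 4")
  expect_error(lilliefors(rep(1, 10)), "constant")
})

test_that("the Lilliefors statistic matches the nortest implementation", {
  skip_if_not_installed("nortest")
  withr::with_seed(71, {
    for (i in 1:3) {
      x <- rnorm(40) + rexp(40) * (i - 1)
      ours <- lilliefors(x, n_mc = 2000, seed = 2)
      ref <- nortest::lillie.test(x)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      # MC p and the analytic approximation should broadly agree
      expect_lt(abs(ours$p_value - ref$p.value), 0.08)
    }
  })
})

test_that("pairwise_group_tests and interaction_tests mirror the results-table layout", {
  tr <- small_cohort_trials(seed_cohort = 81L, seed_trials = 82L)
  dp <- dprime_table(tr)
  pt <- pairwise_group_tests(dp, n_sims = 200, seed = 4)
  expect_equal(nrow(pt), 12)  # 4 conditions x 3 group pairs
  expect_setequal(unique(pt$comparison),
                  c("percussion vs brass", "brass vs color_guard",
                    "percussion vs color_guard"))
  it <- interaction_tests(dp, n_sims = 200, seed = 4)
  expect_equal(nrow(it), 4)   # all + 3 groups
  expect_identical(pt, pairwise_group_tests(dp, n_sims = 200, seed = 4))
})
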
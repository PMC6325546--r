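nominal_x <- c(-200, -133, -67, 0, 67, 133, 200)

points_from <- function(k, xo, noise = 0, seed = NULL) {
  p <- 1 / (1 + exp(-k * (nominal_x - xo)))
  if (noise > 0) {
    p <- withr::with_seed(seed, pmin(pmax(p + rnorm(7, 0, noise), 0), 1))
  }
  tibble::tibble(asynchrony_ms = nominal_x, p_left = p)
}

test_that("noiseless logistic points are recovered exactly, with translation equivariance", {
  f <- fit_sigmoid(points_from(0.02, 0))
  expect_equal(f$k, 0.02, tolerance = 1e-6)
  expect_equal(f$xo, 0, tolerance = 1e-4)
  expect_equal(f$r, 1, tolerance = 1e-9)
  expect_gt(f$r_squared, 0.999999)

  f30 <- fit_sigmoid(points_from(0.02, 30))
  expect_equal(f30$k, 0.02, tolerance = 1e-6)
  expect_equal(f30$xo, 30, tolerance = 1e-4)
})

test_that("small added noise still recovers the generating slope within 10%", {
  for (s in 903:906) {
    f <- fit_sigmoid(points_from(0.02, 0, noise = 0.02, seed = s))
    expect_lt(abs(f$k - 0.02) / 0.02, 0.10)
  }
})

test_that("the threshold is ln(3)/K and matches a brute-force scan of the fitted curve", {
  for (thr in c(29, 100, 250)) {
    f <- fit_sigmoid(points_from(log(3) / thr, 0))
    expect_equal(f$threshold_ms, thr, tolerance = 1e-6)
    # independent oracle: locate p = 0.25 and 0.75 on the fitted curve by
    # root-finding and halve the span
    x25 <- stats::uniroot(function(x) 1 / (1 + exp(-f$k * (x - f$xo))) - 0.25,
                          c(-5000, 5000), tol = 1e-12)$root
    x75 <- stats::uniroot(function(x) 1 / (1 + exp(-f$k * (x - f$xo))) - 0.75,
                          c(-5000, 5000), tol = 1e-12)$root
    expect_equal((x75 - x25) / 2, log(3) / f$k, tolerance = 1e-9)
  }
})

test_that("steeper generating slopes give smaller thresholds, down to the step limit", {
  ks <- log(3) / c(400, 200, 100, 50, 25)
  thr <- vapply(ks, function(k) fit_sigmoid(points_from(k, 0))$threshold_ms,
                numeric(1))
  expect_true(all(diff(thr) < 0))
  # near-step data: threshold approaches zero
  steep <- fit_sigmoid(points_from(1, 0))
  expect_lt(steep$threshold_ms, 5)
})

test_that("threshold_from_fit applies the closed form and rejects K <= 0", {
  expect_equal(threshold_from_fit(list(k = log(3) / 29))$threshold_ms, 29)
  expect_equal(threshold_from_fit(list(k = log(3) / 100, k_se = 0.001)),
               list(threshold_ms = 100,
                    threshold_se_ms = log(3) * 0.001 / (log(3) / 100)^2))
  expect_error(threshold_from_fit(list(k = -1)), "positive")
  expect_error(threshold_from_fit(list(k = 0)), "positive")
})

test_that("group points are per-participant proportions medianed across participants", {
  # single participant: points equal that participant's proportions
  tr <- validate_trials(make_participant_trials())
  pts <- build_points(tr, motion_type = "radial", initial_directions = "same",
                      group = "percussion")
  expect_equal(nrow(pts), 7)
  expect_equal(pts$p_left, c(0, 0, 0, 1, 1, 1, 1))

  # three participants with left-first rates 0.2 / 0.5 / 0.8 at +67 in
  # every design cell; the group point there must be the median, 0.5
  mk <- function(id, rate) {
    tr <- make_participant_trials(id, "brass")
    for (m in toj_design$motion_types) {
      for (d in toj_design$initial_directions) {
        idx <- which(tr$asynchrony_ms == 67 & tr$motion_type == m &
                       tr$initial_directions == d)
        resp <- rep("right_first", length(idx))
        resp[seq_len(round(rate * length(idx)))] <- "left_first"
        tr$response[idx] <- resp
        tr$designated_correct[idx] <- resp == "left_first"
      }
    }
    tr
  }
  trio <- dplyr::bind_rows(mk("a", 0.2), mk("b", 0.5), mk("c", 0.8))
  pts <- build_points(validate_trials(trio), group = "brass")
  at67 <- dplyr::filter(pts, asynchrony_ms == 67)
  expect_true(all(at67$p_left == 0.5))
})

test_that("a synthetic lapse-free cohort's points track the generating logistic", {
  k_true <- log(3) / 80
  spec <- cohort_spec(n = c(brass = 10L), threshold_ms = c(brass = 80),
                      threshold_sdlog = 0, xo_sd = 0, lapse = 0,
                      condition_multiplier = c(radial_same = 1,
                                               radial_opposite = 1,
                                               rotational_same = 1,
                                               rotational_opposite = 1),
                      seed = 81L)
  tr <- simulate_trials(sample_cohort(spec), seed = 82L)
  pts <- build_points(tr, motion_type = "radial", initial_directions = "same",
                      group = "brass")
  truth <- 1 / (1 + exp(-k_true * pts$asynchrony_ms))
  # median of 10 participants' 20-trial proportions: generous sampling band
  expect_true(all(abs(pts$p_left - truth) < 0.12))
})

test_that("fit_psychometric returns one tidy row per group and condition", {
  tr <- small_cohort_trials(n = c(percussion = 3L, brass = 3L))
  fits <- fit_psychometric(tr)
  expect_equal(nrow(fits), 8)  # 2 groups x 4 conditions
  expect_true(all(fits$k > 0))
  expect_equal(fits$threshold_ms, log(3) / fits$k)
  g <- glance(fits$fit[[1]])
  expect_named(g, c("k", "xo", "r", "r.squared", "threshold_ms",
                    "threshold_se_ms", "n_points"))
  td <- tidy(fits$fit[[1]])
  expect_equal(td$term, c("k", "xo"))
})

test_that("group fits explain >97% of response variability at realistic difficulty", {
  # full-size cohort whose hardest cell (radial-opposite, slowest group)
  # sits near a 290 ms generating threshold
  spec <- cohort_spec(threshold_ms = c(percussion = 30, brass = 80,
                                       color_guard = 145), seed = 3L)
  tr <- simulate_trials(sample_cohort(spec), seed = 1003L)
  fits <- fit_psychometric(included_trials(tr))
  expect_equal(nrow(fits), 12)
  expect_gt(min(fits$r_squared), 0.97)
})

test_that("degenerate point sets raise fit errors", {
  expect_error(fit_sigmoid(tibble::tibble(asynchrony_ms = c(-67, 0),
                                          p_left = c(0.2, 0.5))),
               "at least 3")
  expect_error(fit_sigmoid(tibble::tibble(asynchrony_ms = nominal_x,
                                          p_left = rep(1.2, 7))),
               "0, 1")
})
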
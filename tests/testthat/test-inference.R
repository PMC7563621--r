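test_that("paired t-test matches the hand-computed statistic", {
  out <- paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4)) # differences 1,2,3,4
  expect_equal(out$mean_diff, 2.5)
  expect_equal(out$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-10) # 3.872983
  expect_equal(out$t, 3.872983, tolerance = 1e-6)
  expect_equal(out$n, 4L)
  expect_false(out$degenerate)
  expect_true(out$ci_lo < 2.5 && out$ci_hi > 2.5)
})

test_that("paired t-test is antisymmetric and handles degeneracy", {
  x <- c(10, 12, 15, 9, 11)
  y <- c(8, 13, 12, 7, 10)
  a <- paired_t(x, y)
  b <- paired_t(y, x)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  d <- paired_t(c(3, 4, 5), c(2, 3, 4)) # constant difference
  expect_true(d$degenerate)
  expect_equal(d$mean_diff, 1)
  expect_true(is.na(d$t))
  expect_error(paired_t(1, 2), "pairs")
})

test_that("pooled two-sample t matches the hand-computed statistic", {
  out <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$mean_diff, -3)
  expect_equal(out$t, -3 / sqrt(2 / 3), tolerance = 1e-10) # -3.674235
  expect_equal(out$t, -3.674235, tolerance = 1e-6)
  w <- two_sample_t(c(1, 2, 3), c(4, 5, 6), welch = TRUE)
  expect_equal(w$mean_diff, -3)
})

test_that("OLS of cluster-B on cluster-A SSRT recovers an exact line", {
  # an exact line makes lm's summary warn about the perfect fit; that is
  # the point of the oracle, so the warning is silenced
  out <- suppressWarnings(
    regress_b_on_a(data.frame(ssrt_a = c(0, 1, 2), ssrt_b = c(1, 3, 5)))
  )
  expect_equal(out$estimate[out$term == "intercept"], 1)
  expect_equal(out$estimate[out$term == "slope"], 2)
  expect_equal(attr(out, "residual_sd"), 0, tolerance = 1e-10)
  expect_error(regress_b_on_a(data.frame(ssrt_a = c(1, 1, 1),
                                         ssrt_b = c(1, 2, 3))),
               "Constant predictor")
})

test_that("regression residuals are orthogonal to the predictor", {
  set.seed(3)
  pairs <- data.frame(ssrt_a = rnorm(20, 180, 15))
  pairs$ssrt_b <- 20 + 0.9 * pairs$ssrt_a + rnorm(20, sd = 5)
  out <- regress_b_on_a(pairs)
  b0 <- out$estimate[1]; b1 <- out$estimate[2]
  resid <- pairs$ssrt_b - b0 - b1 * pairs$ssrt_a
  expect_equal(sum(resid), 0, tolerance = 1e-8)
  expect_equal(sum(resid * pairs$ssrt_a), 0, tolerance = 1e-6)
})

test_that("comparison sweep pairs the indices per session length", {
  coh <- build_cohort(trial_counts = 96, base_seed = 2,
                      grid = cohort_grid()[c(1, 12, 23, 34), ])
  sw <- run_comparison_sweep(coh)
  expect_s3_class(sw, "ssrt_sweep")
  expect_setequal(sw$pair, c("ss - logan1994", "ss - mixture", "ss - weighted"))
  expect_true(all(sw$n + sw$n_excluded == 4))
  expect_true(all(sw$m_stop == 24))
  est <- attr(sw, "estimates")
  expect_equal(nrow(est), 4)
  # the paired mean difference is reproducible from the estimate table
  ok <- !is.na(est$ss_logan_lognormal) & est$converged_lognormal
  row <- sw[sw$pair == "ss - logan1994", ]
  expect_equal(row$mean_diff,
               mean(est$ss_logan_lognormal[ok] - est$logan1994[ok]))
})

test_that("Weighted and Mixture agree more closely as sessions lengthen", {
  # with identical cluster distributions both indices estimate the same
  # population quantity, so their gap must shrink with the stop-trial count
  d_small <- sst_design(96, gort_b = exg_params(300, 35, 30),
                        ssrt_b = exg_params(130, 70, 60))
  d_large <- sst_design(960, gort_b = exg_params(300, 35, 30),
                        ssrt_b = exg_params(130, 70, 60))
  gap <- function(design, seed) {
    s <- simulate_session(design, seed = seed)
    abs(estimate_weighted(s) - estimate_mixture(s))
  }
  g_small <- mean(purrr::map_dbl(1:10, ~ gap(d_small, 300 + .x)))
  g_large <- mean(purrr::map_dbl(1:10, ~ gap(d_large, 400 + .x)))
  expect_lt(g_large, g_small)
})
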
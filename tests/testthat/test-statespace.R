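toy_params <- function() {
  ss_params(
    phi = matrix(c(0.7, 0.1, -0.2, 0.5), 2, 2),
    Q = matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2),
    R = diag(c(0.3, 0.6)),
    mu0 = c(1, -1),
    Sigma0 = diag(c(2, 1.5))
  )
}

toy_data <- function(Tn = 5) {
  y <- matrix(c(0.9, -0.4,
                1.2, NA,
                NA, 0.3,
                0.4, 0.1,
                NA, NA)[seq_len(2 * Tn)], ncol = 2, byrow = TRUE)
  obs <- !is.na(y)
  list(y = y, obs = obs)
}

test_that("ss_params validates shapes, symmetry, and stationarity", {
  expect_error(ss_params(diag(2), diag(2), diag(2), c(0, 0, 0), diag(3)),
               "must be 3 x 3")
  expect_error(ss_params(diag(2), matrix(c(1, 0.2, 0, 1), 2), diag(2),
                         c(0, 0), diag(2)), "symmetric")
  expect_warning(ss_params(diag(1.2, 2), diag(2), diag(2), c(0, 0), diag(2)),
                 "spectral radius")
})

test_that("filter log-likelihood equals brute-force Gaussian conditioning", {
  p <- toy_params()
  td <- toy_data()
  kf <- kalman_filter(td$y, td$obs, p)
  or <- oracle_ssm(td$y, td$obs, p)
  expect_equal(kf$loglik, or$loglik, tolerance = 1e-10)
})

test_that("smoother matches brute-force conditioning, missing entries included", {
  p <- toy_params()
  td <- toy_data()
  ks <- kalman_smoother(kalman_filter(td$y, td$obs, p))
  or <- oracle_ssm(td$y, td$obs, p)
  expect_equal(ks$xs, or$xs, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ks$Ps, or$Ps, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ks$xs0, or$xs0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ks$Ps0, or$Ps0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ks$Pcs, or$Pcs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a fully observed single-channel model matches the oracle too", {
  p <- ss_params(matrix(0.9), matrix(0.2), matrix(0.1), 0.5, matrix(1))
  y <- matrix(c(0.3, 0.8, -0.1, 1.4))
  obs <- matrix(TRUE, 4, 1)
  kf <- kalman_filter(y, obs, p)
  or <- oracle_ssm(y, obs, p)
  expect_equal(kf$loglik, or$loglik, tolerance = 1e-10)
  ks <- kalman_smoother(kf)
  expect_equal(ks$xs, or$xs, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ks$Pcs, or$Pcs, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("smoothing never inflates the filtered variance", {
  p <- toy_params()
  td <- toy_data()
  kf <- kalman_filter(td$y, td$obs, p)
  ks <- kalman_smoother(kf)
  Pf <- kf$Pf; dim(Pf) <- c(2, 2, 5)
  for (t in 1:5) {
    expect_true(all(diag(ks$Ps[, , t]) <= diag(Pf[, , t]) + 1e-10))
  }
})

test_that("with static dynamics the smoothed state is the sample mean", {
  # phi = I, Q ~ 0, diffuse prior: every trial sees the same latent constant
  p <- ss_params(matrix(1), matrix(1e-12), matrix(1), 0, matrix(1e6))
  y <- matrix(c(1, 2, 3, 6))
  ks <- kalman_smoother(kalman_filter(y, matrix(TRUE, 4, 1), p))
  expect_equal(as.numeric(ks$xs), rep(3, 4), tolerance = 1e-3)
})

test_that("filter rejects NA entries marked observed", {
  p <- toy_params()
  y <- matrix(NA_real_, 3, 2)
  expect_error(kalman_filter(y, matrix(TRUE, 3, 2), p), "Observed entry is NA")
})

test_that("EM increases the log-likelihood monotonically", {
  set.seed(10)
  s <- simulate_session(sst_design(192), seed = 10)
  ps <- prepare_series(s)
  fit <- em_fit(ps$y, ps$obs, rel_tol = 0, max_iter = 40)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))))
})

test_that("EM recovers a known diagonal transition matrix", {
  phi_true <- c(0.8, 0.7, 0.9)
  errs <- purrr::map_dbl(1:20, function(sd) {
    set.seed(100 + sd)
    Tn <- 500
    x <- matrix(0, Tn + 1, 3)
    for (t in 1:Tn + 1) x[t, ] <- phi_true * x[t - 1, ] + rnorm(3, sd = sqrt(0.3))
    y <- x[-1, ] + matrix(rnorm(3 * Tn, sd = sqrt(0.1)), Tn, 3)
    fit <- em_fit(y, matrix(TRUE, Tn, 3), rel_tol = 1e-6, max_iter = 300,
                  structure = "diagonal")
    max(abs(diag(fit$params$phi) - phi_true))
  })
  expect_lt(median(errs), 0.1)
})

test_that("EM flags non-convergence instead of erroring", {
  s <- simulate_session(sst_design(96), seed = 21)
  ps <- prepare_series(s)
  fit <- em_fit(ps$y, ps$obs, rel_tol = 0, max_iter = 5)
  expect_false(fit$converged)
  expect_s3_class(fit, "ss_fit")
})

test_that("EM refuses a never-observed channel", {
  y <- matrix(rnorm(20), 10, 2)
  obs <- cbind(rep(TRUE, 10), rep(FALSE, 10))
  expect_error(em_fit(y, obs), "never observed")
})

test_that("tidy and glance summarize a fit", {
  s <- simulate_session(sst_design(96), seed = 2)
  ps <- prepare_series(s)
  fit <- em_fit(ps$y, ps$obs)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true(any(grepl("^phi\\[", td$term)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.finite(gl$logLik))
})
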
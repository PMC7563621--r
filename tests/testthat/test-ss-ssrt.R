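test_that("observation patterns match the hand enumeration on the six-trial fixture", {
  s <- fixture_session("six") # go, stop-FI, go, stop-SI, go, go
  m <- build_observation_patterns(s)
  expected <- rbind(
    c(TRUE, FALSE, FALSE),  # go
    c(FALSE, TRUE, TRUE),   # failed stop
    c(TRUE, FALSE, FALSE),  # go
    c(FALSE, FALSE, TRUE),  # successful stop
    c(TRUE, FALSE, FALSE),  # go
    c(TRUE, FALSE, FALSE)   # go
  )
  dimnames(expected) <- list(NULL, c("gort", "srrt", "ssd"))
  expect_equal(m, expected, ignore_attr = "counts")
  expect_equal(attr(m, "counts"),
               c(go = 4L, failed_stop = 1L, successful_stop = 1L))
})

test_that("the preceding-trial pattern masks go-preceded rows", {
  s <- fixture_session("six")
  m <- build_observation_patterns(s, pattern = "preceding")
  # predecessors: -, go, stop, go, stop, go -> gort masked at 1, 2, 4, 6
  expect_identical(unname(m[, "gort"]), c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("prepare_series log-transforms present values only", {
  s <- fixture_session("six")
  ps <- prepare_series(s, assumption = "lognormal")
  expect_equal(ps$y[1, "gort"], c(gort = log(400)))
  expect_equal(ps$y[2, "srrt"], c(srrt = log(380)))
  expect_equal(ps$y[2, "ssd"], c(ssd = log(200)))
  expect_true(is.na(ps$y[2, "gort"]))
  expect_equal(ps$inverse(ps$y[1, "gort"]), c(gort = 400), tolerance = 1e-9)
  # a 1000 ms duration maps to log(1000) = 6.9078 on the analysis scale
  expect_equal(log(1000), 6.9078, tolerance = 1e-4)
  # normal mode passes through
  psn <- prepare_series(s, assumption = "normal")
  expect_equal(psn$y[1, "gort"], c(gort = 400))
})

test_that("zero delays are masked as unobserved under the lognormal assumption", {
  s <- fixture_session("six")
  s$ssd_ms[4] <- 0 # staircase floor state
  ps <- prepare_series(s, assumption = "lognormal")
  expect_equal(ps$n_masked_zero_ssd, 1L)
  expect_false(ps$obs[4, "ssd"])
  expect_true(is.na(ps$y[4, "ssd"]))
  # but a non-positive RT is a data error
  s2 <- fixture_session("six")
  s2$gort_ms[1] <- -5
  expect_error(prepare_series(s2), "Non-positive duration")
})

test_that("fit_marginal_normal is the divide-by-n MLE", {
  f <- fit_marginal_normal(c(1, 2, 3, 4, 5))
  expect_equal(f$mu_hat, 3)
  expect_equal(f$sigma_hat, sqrt(2)) # sum((x-3)^2)/5 = 10/5
  expect_error(fit_marginal_normal(1), "at least 2")
})

test_that("bypassing the smoother reproduces the back-transform arithmetic", {
  # inject smoothed log-GORT = log of 400..1100, P(SI) = 0.5, mean delay 200:
  # z = 0 so SSRT = exp(mean of logs) - 200, checked by direct arithmetic
  logs <- log(seq(400, 1100, by = 100))
  f <- fit_marginal_normal(logs)
  ssrt <- exp(f$mu_hat + f$sigma_hat * qnorm(1 - 0.5)) - 200
  expect_equal(ssrt, exp(mean(logs)) - 200)
  expect_equal(ssrt, 512.6488, tolerance = 1e-5)
})

test_that("estimate_ss_ssrt satisfies its own back-transform identity", {
  s <- simulate_session(sst_design(192), seed = 6)
  est <- estimate_ss_ssrt(s)
  expect_equal(
    est$ssrt,
    exp(est$mu_hat + est$sigma_hat * qnorm(1 - est$p_si)) - est$td_bar
  )
  estn <- estimate_ss_ssrt(s, assumption = "normal")
  expect_equal(
    estn$ssrt,
    estn$mu_hat + estn$sigma_hat * qnorm(1 - estn$p_si) - estn$td_bar
  )
  # at P(SI) exactly 1/2 the lognormal index is exp(mu_hat) - mean delay
  if (est$p_si == 0.5) expect_equal(est$ssrt, exp(est$mu_hat) - est$td_bar)
})

test_that("estimate_all returns every index with bookkeeping", {
  s <- simulate_session(sst_design(192), seed = 8)
  est <- estimate_all(s)
  expect_equal(nrow(est), 1)
  needed <- c("logan1994", "ssrt_a", "ssrt_b", "weighted", "mixture",
              "ss_logan_lognormal", "ss_logan_normal", "p_si", "td_bar",
              "w_a", "converged_lognormal", "converged_normal", "note")
  expect_true(all(needed %in% names(est)))
  expect_true(all(is.finite(unlist(est[c("logan1994", "weighted", "mixture")]))))
})

test_that("component failure is reported as NA with a note, not an error", {
  s <- fixture_session("six") # B cluster: one stop, no go trials
  est <- estimate_all(s)
  expect_true(is.na(est$ssrt_b))
  expect_match(est$note, "Degenerate B cluster")
  expect_true(is.finite(est$logan1994))
})
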
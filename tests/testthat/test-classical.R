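# deterministic 12-trial hand session: cluster labels follow predecessors
# A go RTs {400,500,700,900,1100}; A stops FI@200, SI@200, FI@250
# B go RTs {600,800,1000};          B stop  SI@150
hand_session <- function() {
  tibble::tibble(
    trial = 1:12,
    trial_type = c("go", "go", "stop", "stop", "go", "go",
                   "stop", "go", "go", "stop", "go", "go"),
    gort_ms = c(400, 500, NA, NA, 600, 700, NA, 800, 900, NA, 1000, 1100),
    ssd_ms = c(NA, NA, 200, 150, NA, NA, 200, NA, NA, 250, NA, NA),
    srrt_ms = c(NA, NA, 380, NA, NA, NA, NA, NA, NA, 420, NA, NA),
    outcome = c(NA, NA, "FI", "SI", NA, NA, "SI", NA, NA, "FI", NA, NA)
  )
}

test_that("Logan integration estimator matches hand-computed quantiles", {
  # median of 100..1000 is 550; minus the 200 ms mean delay
  expect_equal(ssrt_logan(seq(100, 1000, by = 100), p_si = 0.5, td_bar = 200), 350)
  # perfect inhibition reads off the minimum go RT
  expect_equal(ssrt_logan(seq(100, 1000, by = 100), p_si = 1, td_bar = 40), 60)
  expect_error(ssrt_logan(numeric(0), 0.5, 0), "Empty")
  expect_error(ssrt_logan(1:10, 1.5, 0), "p_si")
})

test_that("cluster partition computes predecessor labels and stop weights", {
  p <- partition_clusters(hand_session())
  expect_equal(p$weights$w_a, 0.75)
  expect_equal(p$weights$n_stop_a, 3L)
  expect_equal(p$weights$n_stop_b, 1L)
  expect_equal(sort(p$B$gort_ms[p$B$trial_type == "go"]), c(600, 800, 1000))
  expect_error(partition_clusters(tibble::tibble(trial = 1:2,
                                                 trial_type = c("go", "go"))),
               "no stop trials")
})

test_that("session estimators reproduce frozen hand-oracle values", {
  s <- hand_session()
  expect_equal(estimate_logan1994(s), 550)            # Q_.5(8 RTs)=750, td=200
  expect_equal(estimate_weighted(s), 575)             # .75*616.667 + .25*450
  expect_equal(estimate_mixture(s), 537.46594, tolerance = 1e-6)
  ii <- internal_indices(s)
  expect_equal(ii$delta_gort, 80)                     # 800 - 720
  expect_equal(ii$ssrt_a, 1850 / 3)
  expect_equal(ii$ssrt_b, 450)
  expect_equal(ii$delta_ssrt_ba, 450 - 1850 / 3)
})

test_that("weighted quantile reduces to type-7 under equal weights", {
  expect_equal(weighted_quantile(1:10, rep(1, 10), 0.5), 5.5)
  set.seed(1)
  x <- rnorm(37)
  probs <- c(0, 0.1, 0.25, 0.5, 0.8, 0.95, 1)
  expect_equal(weighted_quantile(x, rep(2, 37), probs),
               unname(quantile(x, probs, type = 7)))
})

test_that("weighted quantile pools disjoint clusters correctly", {
  # two disjoint 10-value clusters, equal weights: pooled median 1050
  x <- c(seq(100, 1000, by = 100), seq(1100, 2000, by = 100))
  expect_equal(weighted_quantile(x, rep(1, 20), 0.5), 1050)
  # all weight on the second cluster: its own median
  expect_equal(weighted_quantile(x, rep(c(0, 1), each = 10), 0.5), 1550)
})

test_that("weighted quantile is monotone in the probability", {
  set.seed(2)
  x <- rexgauss(50, exg_params(300, 35, 30))
  w <- runif(50)
  q <- weighted_quantile(x, w, seq(0, 1, by = 0.01))
  expect_true(all(diff(q) >= 0))
  expect_equal(q[1], min(x))
  expect_equal(q[101], max(x))
})

test_that("all classical indices are shift-equivariant", {
  s <- hand_session()
  shift <- 123.5
  s2 <- s
  s2$gort_ms <- s2$gort_ms + shift
  s2$srrt_ms <- s2$srrt_ms + shift
  expect_equal(estimate_logan1994(s2), estimate_logan1994(s) + shift)
  expect_equal(estimate_weighted(s2), estimate_weighted(s) + shift)
  expect_equal(estimate_mixture(s2), estimate_mixture(s) + shift)
})

test_that("Logan, Weighted and Mixture coincide on duplicated clusters", {
  # hand-assigned labels: both clusters identical in go RTs, P(SI), delays
  s <- tibble::tibble(
    trial = 1:8,
    trial_type = rep(c("go", "go", "stop", "stop"), 2),
    cluster_type = rep(c("A", "B"), each = 4),
    gort_ms = c(400, 600, NA, NA, 400, 600, NA, NA),
    ssd_ms = c(NA, NA, 200, 200, NA, NA, 200, 200),
    srrt_ms = c(NA, NA, 390, NA, NA, NA, 390, NA),
    outcome = c(NA, NA, "FI", "SI", NA, NA, "FI", "SI")
  )
  logan <- estimate_logan1994(s)
  expect_equal(logan, 300) # Q_.5{400,400,600,600} = 500, td = 200
  expect_equal(estimate_weighted(s), logan)
  expect_equal(estimate_mixture(s), logan)
})

test_that("degenerate clusters raise informative errors", {
  s <- hand_session()[1:4, ] # B cluster has a stop trial but no go trials
  expect_error(estimate_weighted(s), "Degenerate B cluster")
  expect_error(estimate_mixture(s), "Degenerate B cluster")
})
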
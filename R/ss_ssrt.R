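#' Per-trial observation patterns for the 3-channel SST model
#'
#' Maps each trial to the boolean triple (GORT observed, SRRT observed,
#' SSD observed) that defines the selection matrix of the observation
#' equation: go trials observe only the go RT `(1,0,0)`; failed stop
#' trials observe the emitted signal-respond RT and the delay `(0,1,1)`;
#' successful stop trials observe only the delay `(0,0,1)`.
#'
#' By default observability is keyed to the *current* trial's recorded
#' data (`pattern = "current"`). The alternative `"preceding"` keys the
#' masked rows to the previous trial's type instead — zeroing the GORT row
#' whenever the preceding trial was a go trial — retained for sensitivity
#' checks because the trial-history information otherwise flows only
#' through the state recursion.
#'
#' @inheritParams estimate_logan1994
#' @param pattern `"current"` or `"preceding"`, see Details.
#'
#' @return Logical `n_trials` x 3 matrix with columns `gort`, `srrt`,
#'   `ssd`, plus an attribute `counts` with the (go, failed-stop,
#'   successful-stop) trial counts.
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' colSums(build_observation_patterns(s))
#' @export
build_observation_patterns <- function(session, pattern = c("current", "preceding")) {
  pattern <- match.arg(pattern)
  session <- ensure_clusters(session)
  ok <- session$trial_type %in% c("go", "stop") &
    (session$trial_type == "go" |
       (!is.na(session$outcome) & session$outcome %in% c("SI", "FI")))
  if (!all(ok)) {
    abort(sprintf("Unknown trial type/outcome code at trial(s) %s.",
                  paste(head(session$trial[!ok], 5), collapse = ", ")))
  }
  go <- session$trial_type == "go"
  fi <- !go & session$outcome == "FI"
  si <- !go & session$outcome == "SI"
  m <- cbind(gort = go, srrt = fi, ssd = fi | si)
  if (pattern == "preceding") {
    # mask the GORT row wherever the preceding trial was a go trial
    prev_go <- c(TRUE, go[-length(go)])
    m[prev_go, "gort"] <- FALSE
  }
  attr(m, "counts") <- c(go = sum(go), failed_stop = sum(fi), successful_stop = sum(si))
  m
}

#' Assemble the 3-channel series on the analysis scale
#'
#' Builds the per-trial (GORT, SRRT, SSD) observation matrix and, under the
#' lognormal assumption, log-transforms every present value (reaction-time
#' data are strongly right-skewed; the log transform makes the channels
#' near normal as the linear-Gaussian model requires). Under the normal
#' assumption values pass through unchanged.
#'
#' A non-positive go RT or signal-respond RT is a data error under the
#' lognormal assumption. A stop-signal delay of exactly 0 ms, however, is
#' a legitimate staircase state with no log-scale representation: such
#' delays are treated as unobserved in the state-space model (their count
#' is returned as `n_masked_zero_ssd`).
#'
#' @inheritParams build_observation_patterns
#' @param assumption `"lognormal"` (log-transform, back-transform with
#'   `exp`) or `"normal"` (identity).
#'
#' @return A list with `y` (T x 3 numeric matrix, `NA` where unobserved),
#'   `obs` (the pattern matrix), `assumption`, and `inverse` (the
#'   back-transform function).
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' ps <- prepare_series(s)
#' head(ps$y)
#' @export
prepare_series <- function(session, assumption = c("lognormal", "normal"),
                           pattern = "current") {
  assumption <- match.arg(assumption)
  session <- ensure_clusters(session)
  obs <- build_observation_patterns(session, pattern = pattern)
  y <- cbind(gort = session$gort_ms,
             srrt = session$srrt_ms,
             ssd = session$ssd_ms)
  n_masked <- 0L
  if (assumption == "lognormal") {
    present <- obs & !is.na(y)
    bad_rt <- present & y <= 0
    bad_rt[, "ssd"] <- FALSE
    if (any(bad_rt)) {
      abort(sprintf("Non-positive duration under the lognormal assumption at trial(s) %s.",
                    paste(head(which(rowSums(bad_rt) > 0), 5), collapse = ", ")))
    }
    # a staircase delay floored at 0 ms is a valid task state but has no
    # log-scale value: treat those entries as unobserved
    zero_ssd <- present[, "ssd"] & y[, "ssd"] <= 0
    if (any(zero_ssd)) {
      obs[zero_ssd, "ssd"] <- FALSE
      y[zero_ssd, "ssd"] <- NA_real_
      n_masked <- sum(zero_ssd)
      present <- obs & !is.na(y)
    }
    y[present] <- log(y[present])
    inverse <- exp
  } else {
    inverse <- identity
  }
  list(y = y, obs = obs, assumption = assumption, inverse = inverse,
       n_masked_zero_ssd = n_masked)
}

#' MLE normal fit to a smoothed channel
#'
#' Fits `N(mu, sigma^2)` by maximum likelihood: `mu_hat` is the sample
#' mean and `sigma_hat` the divide-by-n standard deviation.
#'
#' @param x Numeric vector (at least 2 values).
#' @return A list with `mu_hat`, `sigma_hat`, `n`.
#' @examples
#' fit_marginal_normal(1:5) # mu 3, sigma sqrt(2)
#' @export
fit_marginal_normal <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) abort("Need at least 2 values for the normal fit.")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  list(mu_hat = mu, sigma_hat = sigma, n = length(x))
}

#' Time-series state-space SSRT
#'
#' The four-step time-series estimator of the stop-signal reaction time:
#' (i) put the per-trial (GORT, SRRT, SSD) series on the analysis scale
#' ([prepare_series()]); (ii) fit the missing-data linear-Gaussian
#' state-space model by EM ([em_fit()], relative tolerance 1% by default);
#' (iii) fit a normal distribution by MLE to the smoothed go-RT channel
#' ([fit_marginal_normal()]); (iv) read off
#' `SSRT = exp(mu_hat + sigma_hat * z_{1 - P(SI)}) - mean(SSD)` under the
#' lognormal assumption, or the same without the `exp` under the normal
#' assumption. `P(SI)` is the session's successful-inhibition fraction and
#' the mean delay is taken over the session's stop trials.
#'
#' @inheritParams prepare_series
#' @param fit_scope `"all"` fits the marginal normal on the smoothed go-RT
#'   states at every trial (go and stop); `"go"` restricts to go trials.
#' @param td `"raw"` uses the staircase's recorded delays for the mean SSD
#'   term; `"smoothed"` uses the back-transformed smoothed SSD states at
#'   stop trials.
#' @param structure,rel_tol,max_iter Passed to [em_fit()].
#' @param pattern Passed to [build_observation_patterns()].
#'
#' @return One-row tibble: `ssrt` (ms), `assumption`, `mu_hat`,
#'   `sigma_hat`, `p_si`, `td_bar`, `converged`, `em_iterations`,
#'   `loglik`. Non-convergence is flagged, not an error.
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' estimate_ss_ssrt(s)$ssrt
#' @export
estimate_ss_ssrt <- function(session, assumption = c("lognormal", "normal"),
                             fit_scope = c("go", "all"), td = c("raw", "smoothed"),
                             structure = "full", rel_tol = 0.01, max_iter = 500L,
                             pattern = "current") {
  assumption <- match.arg(assumption)
  fit_scope <- match.arg(fit_scope)
  td <- match.arg(td)
  session <- ensure_clusters(session)
  st <- session_stats(session)
  ps <- prepare_series(session, assumption = assumption, pattern = pattern)
  fit <- em_fit(ps$y, ps$obs, rel_tol = rel_tol, max_iter = max_iter,
                structure = structure)
  sm_gort <- fit$smooth$xs[1, ]
  keep <- if (fit_scope == "go") session$trial_type == "go" else rep(TRUE, nrow(session))
  nf <- fit_marginal_normal(sm_gort[keep])
  if (nf$sigma_hat <= 0) abort("Degenerate smoothed go-RT channel (sigma_hat = 0).")
  td_bar <- if (td == "raw") {
    st$td_bar
  } else {
    mean(ps$inverse(fit$smooth$xs[3, session$trial_type == "stop"]))
  }
  z <- qnorm(1 - st$p_si)
  ssrt <- if (assumption == "lognormal") {
    exp(nf$mu_hat + nf$sigma_hat * z) - td_bar
  } else {
    nf$mu_hat + nf$sigma_hat * z - td_bar
  }
  tibble(
    ssrt = ssrt, assumption = assumption,
    mu_hat = nf$mu_hat, sigma_hat = nf$sigma_hat,
    p_si = st$p_si, td_bar = td_bar,
    converged = fit$converged, em_iterations = fit$iterations,
    loglik = tail(fit$loglik_trace, 1)
  )
}

#' All SSRT indices for one session
#'
#' Computes the classical indices (Logan-1994, cluster A/B, Weighted,
#' Mixture) and both state-space variants (lognormal and normal) with
#' shared `P(SI)` and mean-SSD bookkeeping. Component failures are
#' reported as `NA` fields with a note, not silently dropped.
#'
#' @inheritParams estimate_ss_ssrt
#' @param qtype Quantile convention for the classical estimators.
#'
#' @return One-row tibble with `logan1994`, `ssrt_a`, `ssrt_b`, `weighted`,
#'   `mixture`, `ss_logan_lognormal`, `ss_logan_normal`, `p_si`, `td_bar`,
#'   `w_a`, `converged_lognormal`, `converged_normal`, `note`.
#' @examples
#' estimate_all(simulate_session(sst_design(96), seed = 1))
#' @export
estimate_all <- function(session, qtype = 7, structure = "full",
                         rel_tol = 0.01, max_iter = 500L, pattern = "current",
                         fit_scope = "go", td = "raw") {
  session <- ensure_clusters(session)
  st <- session_stats(session)
  parts <- partition_clusters(session)
  notes <- character(0)
  try_num <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s: %s", what, conditionMessage(e)))
      NA_real_
    })
  }
  logan <- try_num(estimate_logan1994(session, qtype = qtype), "logan1994")
  ssrt_a <- try_num(cluster_ssrt(parts$A, "A", qtype = qtype), "ssrt_a")
  ssrt_b <- try_num(cluster_ssrt(parts$B, "B", qtype = qtype), "ssrt_b")
  weighted <- try_num(estimate_weighted(session, qtype = qtype), "weighted")
  mixture <- try_num(estimate_mixture(session, qtype = qtype), "mixture")
  ss_ln <- tryCatch(
    estimate_ss_ssrt(session, "lognormal", fit_scope = fit_scope, td = td,
                     structure = structure, rel_tol = rel_tol,
                     max_iter = max_iter, pattern = pattern),
    error = function(e) {
      notes <<- c(notes, sprintf("ss_lognormal: %s", conditionMessage(e)))
      NULL
    }
  )
  ss_n <- tryCatch(
    estimate_ss_ssrt(session, "normal", fit_scope = fit_scope, td = td,
                     structure = structure, rel_tol = rel_tol,
                     max_iter = max_iter, pattern = pattern),
    error = function(e) {
      notes <<- c(notes, sprintf("ss_normal: %s", conditionMessage(e)))
      NULL
    }
  )
  tibble(
    logan1994 = logan, ssrt_a = ssrt_a, ssrt_b = ssrt_b,
    weighted = weighted, mixture = mixture,
    ss_logan_lognormal = if (is.null(ss_ln)) NA_real_ else ss_ln$ssrt,
    ss_logan_normal = if (is.null(ss_n)) NA_real_ else ss_n$ssrt,
    p_si = st$p_si, td_bar = st$td_bar, w_a = parts$weights$w_a,
    converged_lognormal = if (is.null(ss_ln)) FALSE else ss_ln$converged,
    converged_normal = if (is.null(ss_n)) FALSE else ss_n$converged,
    note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_
  )
}
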
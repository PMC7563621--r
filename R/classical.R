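#' Partition a session into trial-history clusters
#'
#' Splits a trial table into the type-A cluster (trials preceded by a go
#' trial) and the type-B cluster (trials preceded by a stop trial), and
#' computes the cluster weights over stop trials:
#' `w_a = (# type-A stop trials) / (# stop trials)`, `w_b = 1 - w_a`.
#'
#' If the table has no `cluster_type` column the labels are computed from
#' the realized predecessor's `trial_type`; trial 1 is labelled A.
#'
#' @param session A trial table (tibble/data frame) with at least `trial`,
#'   `trial_type`, and for estimation `gort_ms`, `ssd_ms`, `outcome`.
#'
#' @return A list with elements `A`, `B` (tibbles of the cluster trials)
#'   and `weights`, a one-row tibble with `w_a`, `w_b`, `n_stop_a`,
#'   `n_stop_b`.
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' partition_clusters(s)$weights
#' @export
partition_clusters <- function(session) {
  session <- ensure_clusters(session)
  stops <- session$trial_type == "stop"
  if (!any(stops)) abort("Session has no stop trials: cluster weights are undefined.")
  n_a <- sum(stops & session$cluster_type == "A")
  n_b <- sum(stops & session$cluster_type == "B")
  list(
    A = session[session$cluster_type == "A", , drop = FALSE],
    B = session[session$cluster_type == "B", , drop = FALSE],
    weights = tibble(
      w_a = n_a / (n_a + n_b), w_b = n_b / (n_a + n_b),
      n_stop_a = n_a, n_stop_b = n_b
    )
  )
}

ensure_clusters <- function(session) {
  if (nrow(session) == 0L) abort("Session is empty.")
  if (!all(c("trial", "trial_type") %in% names(session))) {
    abort("Session must have `trial` and `trial_type` columns.")
  }
  session <- session[order(session$trial), , drop = FALSE]
  if (!"cluster_type" %in% names(session)) {
    n <- nrow(session)
    session$cluster_type <- c("A", ifelse(session$trial_type[-n] == "stop", "B", "A"))
  }
  session
}

#' Logan-1994 integration SSRT
#'
#' The classical integration estimator: the SSRT is the `1 - P(SI)`
#' empirical quantile of the go-trial RT distribution minus the mean
#' stop-signal delay,
#' `SSRT = Q_GORT(1 - P(SI)) - mean(SSD)`.
#'
#' @param gort Numeric vector of go-trial reaction times (ms);
#'   signal-respond RTs are not part of this sample.
#' @param p_si Probability of successful inhibition (the SI fraction over
#'   stop trials).
#' @param td_bar Mean stop-signal delay over stop trials (ms).
#' @param qtype Empirical quantile convention, passed to
#'   [stats::quantile()]'s `type`; defaults to the linear-interpolation
#'   type 7.
#'
#' @return SSRT estimate in ms (scalar).
#' @examples
#' ssrt_logan(seq(100, 1000, by = 100), p_si = 0.5, td_bar = 200) # 350
#' @export
ssrt_logan <- function(gort, p_si, td_bar, qtype = 7) {
  gort <- gort[!is.na(gort)]
  if (length(gort) == 0L) abort("Empty go-RT sample.")
  if (!is.finite(p_si) || p_si < 0 || p_si > 1) abort("`p_si` must lie in [0, 1].")
  unname(quantile(gort, probs = 1 - p_si, type = qtype)) - td_bar
}

session_stats <- function(session) {
  stops <- session[session$trial_type == "stop", , drop = FALSE]
  if (nrow(stops) == 0L) abort("Session has no stop trials.")
  list(
    gort = session$gort_ms[session$trial_type == "go" & !is.na(session$gort_ms)],
    p_si = mean(stops$outcome == "SI"),
    td_bar = mean(stops$ssd_ms),
    n_stop = nrow(stops)
  )
}

#' Session-level classical SSRT estimators
#'
#' `estimate_logan1994()` applies the integration method ([ssrt_logan()])
#' to the whole session. `estimate_weighted()` applies it within each
#' trial-history cluster (cluster-specific go-RT sample, SI fraction, and
#' mean SSD) and combines the two cluster SSRTs with the stop-trial
#' weights, `w_a * SSRT_A + w_b * SSRT_B`. `estimate_mixture()` instead
#' forms the `w_a`/`w_b`-weighted mixture of the two clusters' go-RT
#' distributions and applies the integration formula to that mixture with
#' the pooled SI fraction and pooled mean SSD.
#'
#' @inheritParams partition_clusters
#' @param qtype Quantile convention, see [ssrt_logan()].
#'
#' @return SSRT estimate in ms (scalar).
#' @examples
#' s <- simulate_session(sst_design(960), seed = 2)
#' estimate_logan1994(s)
#' estimate_weighted(s)
#' estimate_mixture(s)
#' @export
estimate_logan1994 <- function(session, qtype = 7) {
  session <- ensure_clusters(session)
  st <- session_stats(session)
  ssrt_logan(st$gort, st$p_si, st$td_bar, qtype = qtype)
}

cluster_ssrt <- function(cluster, label, qtype = 7) {
  n_go <- sum(cluster$trial_type == "go" & !is.na(cluster$gort_ms))
  n_stop <- sum(cluster$trial_type == "stop")
  if (n_stop < 1L || n_go < 2L) {
    abort(sprintf(
      "Degenerate %s cluster: %d stop and %d go trials (need >= 1 and >= 2).",
      label, n_stop, n_go
    ))
  }
  st <- session_stats(cluster)
  ssrt_logan(st$gort, st$p_si, st$td_bar, qtype = qtype)
}

#' @rdname estimate_logan1994
#' @export
estimate_weighted <- function(session, qtype = 7) {
  parts <- partition_clusters(session)
  ssrt_a <- cluster_ssrt(parts$A, "A", qtype = qtype)
  ssrt_b <- cluster_ssrt(parts$B, "B", qtype = qtype)
  parts$weights$w_a * ssrt_a + parts$weights$w_b * ssrt_b
}

#' @rdname estimate_logan1994
#' @export
estimate_mixture <- function(session, qtype = 7) {
  parts <- partition_clusters(session)
  for (cl in c("A", "B")) {
    x <- parts[[cl]]
    if (sum(x$trial_type == "stop") < 1L ||
        sum(x$trial_type == "go" & !is.na(x$gort_ms)) < 2L) {
      abort(sprintf("Degenerate %s cluster for the mixture estimator.", cl))
    }
  }
  gort_a <- parts$A$gort_ms[parts$A$trial_type == "go" & !is.na(parts$A$gort_ms)]
  gort_b <- parts$B$gort_ms[parts$B$trial_type == "go" & !is.na(parts$B$gort_ms)]
  st <- session_stats(ensure_clusters(session))
  w <- parts$weights
  q <- weighted_quantile(
    c(gort_a, gort_b),
    c(rep(w$w_a / length(gort_a), length(gort_a)),
      rep(w$w_b / length(gort_b), length(gort_b))),
    probs = 1 - st$p_si
  )
  q - st$td_bar
}

#' Weighted empirical quantile with linear interpolation
#'
#' Generalizes the type-7 sample quantile to weighted samples: sorted
#' values are placed at plotting positions `s_i = (c_i - p_i) / (1 - p_i)`
#' where `c_i` is the cumulative normalized weight, and the quantile is
#' read off by linear interpolation. With equal weights this reduces
#' exactly to `quantile(x, probs, type = 7)`.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (normalized internally).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per `probs`.
#' @examples
#' weighted_quantile(1:10, rep(1, 10), 0.5) # 5.5, same as quantile type 7
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; p <- w[o] / sum(w)
  cw <- cumsum(p)
  s <- (cw - p) / (1 - p)
  s[length(s)] <- 1  # guard against rounding at the top end
  vapply(probs, function(pr) {
    if (pr <= 0) return(x[1L])
    if (pr >= 1) return(x[length(x)])
    approx(s, x, xout = pr, ties = "ordered")$y
  }, numeric(1))
}

#' Internal (trial-history) inhibition indices
#'
#' Computes the internal proactive index `delta_gort = mean(GORT_B) -
#' mean(GORT_A)` over go trials and the internal reactive indices
#' `SSRT_B - SSRT_A`, `SSRT_Logan1994 - SSRT_A`, and
#' `SSRT_Logan1994 - SSRT_B`, all in ms.
#'
#' @inheritParams estimate_logan1994
#' @return One-row tibble with columns `delta_gort`, `delta_ssrt_ba`,
#'   `delta_logan_a`, `delta_logan_b`, `ssrt_a`, `ssrt_b`, `logan1994`.
#' @examples
#' internal_indices(simulate_session(sst_design(960), seed = 3))
#' @export
internal_indices <- function(session, qtype = 7) {
  parts <- partition_clusters(session)
  ssrt_a <- cluster_ssrt(parts$A, "A", qtype = qtype)
  ssrt_b <- cluster_ssrt(parts$B, "B", qtype = qtype)
  logan <- estimate_logan1994(session, qtype = qtype)
  mean_go <- function(x) mean(x$gort_ms[x$trial_type == "go"], na.rm = TRUE)
  tibble(
    delta_gort = mean_go(parts$B) - mean_go(parts$A),
    delta_ssrt_ba = ssrt_b - ssrt_a,
    delta_logan_a = logan - ssrt_a,
    delta_logan_b = logan - ssrt_b,
    ssrt_a = ssrt_a, ssrt_b = ssrt_b, logan1994 = logan
  )
}
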
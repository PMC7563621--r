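#' Paired and two-sample t comparisons
#'
#' `paired_t()` runs the classical paired t-test on `x - y`;
#' `two_sample_t()` compares two independent groups (pooled-variance by
#' default, Welch by request). Both return the same one-row comparison
#' table. Zero-variance (degenerate) inputs are flagged rather than
#' raising: the mean difference is still reported with `NA` test columns.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2 after removing
#'   incomplete pairs).
#' @param label Label stored in the output row.
#' @param conf_level Confidence level for the interval.
#'
#' @return One-row tibble: `label`, `n`, `mean_diff`, `ci_lo`, `ci_hi`,
#'   `t`, `p`, `degenerate`.
#' @examples
#' paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
#' @export
paired_t <- function(x, y, label = "paired", conf_level = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 2L) {
    abort("Need >= 2 complete pairs of equal length.")
  }
  d <- x - y
  if (sd(d) == 0) {
    return(tibble(label = label, n = length(d), mean_diff = mean(d),
                  ci_lo = NA_real_, ci_hi = NA_real_, t = NA_real_,
                  p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(d, conf.level = conf_level)
  tibble(label = label, n = length(d), mean_diff = unname(tt$estimate),
         ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
         t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' @rdname paired_t
#' @param g1,g2 Numeric vectors for the two groups (each >= 2 values).
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   pooled-variance test.
#' @export
two_sample_t <- function(g1, g2, label = "two-sample", welch = FALSE,
                         conf_level = 0.95) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 2L || length(g2) < 2L) abort("Each group needs >= 2 values.")
  if (sd(g1) == 0 && sd(g2) == 0) {
    return(tibble(label = label, n = length(g1) + length(g2),
                  mean_diff = mean(g1) - mean(g2),
                  ci_lo = NA_real_, ci_hi = NA_real_, t = NA_real_,
                  p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(g1, g2, var.equal = !welch, conf.level = conf_level)
  tibble(label = label, n = length(g1) + length(g2),
         mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
         ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
         t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Regress the B-cluster SSRT on the A-cluster SSRT
#'
#' Ordinary least squares of `ssrt_b ~ ssrt_a` across participants, used
#' to probe whether the two trial-history clusters carry the same stopping
#' latency (identity line) or not.
#'
#' @param pairs Data frame with columns `ssrt_a` and `ssrt_b`, one row per
#'   participant (>= 3 rows, non-constant predictor).
#' @param conf_level Confidence level for the coefficient intervals.
#'
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `ci_lo`, `ci_hi`, plus attribute `residual_sd`.
#' @examples
#' regress_b_on_a(data.frame(ssrt_a = c(0, 1, 2), ssrt_b = c(1, 3, 5)))
#' @export
regress_b_on_a <- function(pairs, conf_level = 0.95) {
  if (!all(c("ssrt_a", "ssrt_b") %in% names(pairs))) {
    abort("`pairs` needs columns `ssrt_a` and `ssrt_b`.")
  }
  pairs <- pairs[stats::complete.cases(pairs[c("ssrt_a", "ssrt_b")]), ]
  if (nrow(pairs) < 3L) abort("Need >= 3 complete pairs.")
  if (sd(pairs$ssrt_a) == 0) abort("Constant predictor `ssrt_a`.")
  fit <- lm(ssrt_b ~ ssrt_a, data = pairs)
  ci <- confint(fit, level = conf_level)
  out <- tibble(
    term = c("intercept", "slope"),
    estimate = unname(coef(fit)),
    ci_lo = ci[, 1], ci_hi = ci[, 2]
  )
  attr(out, "residual_sd") <- summary(fit)$sigma
  out
}

#' Cohort comparison sweep of SSRT indices by session length
#'
#' For every session length in a simulated cohort, estimates all SSRT
#' indices per participant (lognormal state-space pipeline plus the
#' classical indices) and runs paired t-tests of the state-space index
#' against Logan-1994, Mixture, and Weighted. Sessions whose state-space
#' fit did not converge (or failed) are excluded from the pairing and
#' counted in `n_excluded`.
#'
#' @param cohort A cohort tibble from [build_cohort()] (columns
#'   `participant_id`, `n_trials`, `session`).
#' @param assumption Distributional assumption for the state-space index.
#' @param ... Passed to [estimate_all()].
#'
#' @return A tibble with one row per (pair, session length): `pair`,
#'   `n_trials`, `m_stop` (nominal stop-trial count), `n`, `mean_diff`,
#'   `ci_lo`, `ci_hi`, `t`, `p`, `n_excluded`. The per-session estimate
#'   table is attached as attribute `estimates`.
#' @examples
#' \donttest{
#' coh <- build_cohort(trial_counts = 96, base_seed = 1,
#'                     grid = cohort_grid()[1:4, ])
#' run_comparison_sweep(coh)
#' }
#' @export
run_comparison_sweep <- function(cohort, assumption = c("lognormal", "normal"), ...) {
  assumption <- match.arg(assumption)
  ss_col <- paste0("ss_logan_", assumption)
  conv_col <- paste0("converged_", assumption)
  est <- cohort |>
    mutate(est = map(.data$session, estimate_all, ...)) |>
    select(-"session") |>
    tidyr::unnest("est")
  rows <- est |>
    group_by(.data$n_trials) |>
    group_split_compat() |>
    map(function(g) {
      ok <- !is.na(g[[ss_col]]) & g[[conv_col]]
      excl <- sum(!ok)
      g <- g[ok, , drop = FALSE]
      pairs <- c(logan1994 = "logan1994", mixture = "mixture", weighted = "weighted")
      imap(pairs, function(col, nm) {
        cmp <- paired_t(g[[ss_col]], g[[col]],
                        label = sprintf("ss_%s - %s", assumption, nm))
        cmp$pair <- sprintf("ss - %s", nm)
        cmp$n_trials <- g$n_trials[1]
        cmp$m_stop <- as.integer(round(g$n_trials[1] * 0.25))
        cmp$n_excluded <- excl
        cmp
      }) |> list_rbind()
    }) |>
    list_rbind() |>
    select("pair", "n_trials", "m_stop", "n", "mean_diff",
           "ci_lo", "ci_hi", "t", "p", "n_excluded")
  attr(rows, "estimates") <- est
  class(rows) <- c("ssrt_sweep", class(rows))
  rows
}

group_split_compat <- function(g) dplyr::group_split(g)
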
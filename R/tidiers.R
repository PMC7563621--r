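#' Tidiers for fitted state-space models
#'
#' `tidy()` returns the fitted parameters in long form (one row per matrix
#' element); `glance()` returns a one-row model summary.
#'
#' @param x An `ss_fit` from [em_fit()].
#' @param ... Ignored.
#' @return A tibble.
#' @examples
#' set.seed(1)
#' y <- matrix(cumsum(rnorm(40, sd = 0.2)) + rnorm(40, sd = 0.1), ncol = 1)
#' fit <- em_fit(y, matrix(TRUE, 40, 1))
#' tidy(fit)
#' glance(fit)
#' @method tidy ss_fit
#' @export
tidy.ss_fit <- function(x, ...) {
  p <- x$params
  d <- length(p$mu0)
  mat_rows <- function(m, name) {
    tibble(
      term = sprintf("%s[%d,%d]", name, rep(seq_len(d), d), rep(seq_len(d), each = d)),
      estimate = as.vector(m)
    )
  }
  bind_rows(
    mat_rows(p$phi, "phi"),
    mat_rows(p$Q, "Q"),
    tibble(term = sprintf("R[%d,%d]", seq_len(d), seq_len(d)),
           estimate = diag(p$R)),
    tibble(term = sprintf("mu0[%d]", seq_len(d)), estimate = p$mu0)
  )
}

#' @rdname tidy.ss_fit
#' @method glance ss_fit
#' @export
glance.ss_fit <- function(x, ...) {
  tibble(
    logLik = tail(x$loglik_trace, 1),
    iterations = x$iterations,
    converged = x$converged,
    spectral_radius = x$params$spectral_radius,
    n_obs = sum(x$n_obs)
  )
}
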
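#' Linear-Gaussian state-space parameters
#'
#' Parameter set for the d-channel linear-Gaussian state-space model
#' \deqn{x_t = \Phi x_{t-1} + w_t, \quad w_t \sim N(0, Q)}
#' \deqn{y_t = A_t x_t + v_t, \quad v_t \sim N(0, A_t R A_t')}
#' where `A_t` is a selection matrix keeping only the channels observed at
#' trial `t` (the missing-data mechanism), and the initial state is
#' `x_0 ~ N(mu0, Sigma0)`.
#'
#' @param phi d x d transition matrix. Stationarity is not enforced; a
#'   spectral radius at or above 1 triggers a warning, not an error.
#' @param Q d x d state-noise covariance (symmetric positive semi-definite).
#' @param R d x d observation-noise covariance; only its diagonal enters the
#'   likelihood on the observed channels.
#' @param mu0 Initial state mean (length d).
#' @param Sigma0 d x d initial state covariance.
#'
#' @return An object of class `ss_params`.
#' @examples
#' p <- ss_params(diag(0.8, 2), diag(0.1, 2), diag(0.2, 2), c(0, 0), diag(1, 2))
#' @export
ss_params <- function(phi, Q, R, mu0, Sigma0) {
  phi <- as.matrix(phi); Q <- as.matrix(Q); R <- as.matrix(R)
  Sigma0 <- as.matrix(Sigma0); mu0 <- as.numeric(mu0)
  d <- length(mu0)
  for (nm in c("phi", "Q", "R", "Sigma0")) {
    m <- get(nm)
    if (!all(dim(m) == d)) abort(sprintf("`%s` must be %d x %d.", nm, d, d))
  }
  for (nm in c("Q", "R", "Sigma0")) {
    m <- get(nm)
    if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m)))) {
      abort(sprintf("`%s` must be symmetric.", nm))
    }
  }
  sr <- max(Mod(eigen(phi, only.values = TRUE)$values))
  if (sr >= 1 + 1e-12) {
    warn(sprintf("Transition matrix has spectral radius %.3f (>= 1): non-stationary dynamics.", sr))
  }
  structure(list(phi = phi, Q = sym(Q), R = sym(R), mu0 = mu0, Sigma0 = sym(Sigma0),
                 spectral_radius = sr),
            class = "ss_params")
}

sym <- function(m) (m + t(m)) / 2

#' Kalman filter with per-trial missing observations
#'
#' Exact Gaussian filtering for the model in [ss_params()]: at each trial
#' only the observed channels (per `obs`) enter the update; with no
#' observed channel the step is pure prediction. Covariance updates use the
#' Joseph form and are re-symmetrized each step.
#'
#' @param y Numeric T x d matrix of observations; entries at unobserved
#'   positions are ignored (may be `NA`).
#' @param obs Logical T x d matrix: `obs[t, j]` is `TRUE` iff channel `j`
#'   is observed at trial `t`.
#' @param params An [ss_params()] object.
#'
#' @return A list of class `kfilter` with predicted (`xp`, `Pp`) and
#'   filtered (`xf`, `Pf`) means/covariances (d x T and d x d x T), the
#'   time-0 filtered moments (`xf0`, `Pf0` — the prior), `loglik` (the
#'   innovations-form Gaussian log-likelihood of the observed entries), and
#'   bookkeeping used by the smoother.
#' @examples
#' p <- ss_params(matrix(1), matrix(0), matrix(1e-8), 0, matrix(1))
#' kf <- kalman_filter(matrix(c(1, 2, 3)), matrix(TRUE, 3, 1), p)
#' kf$xf
#' @export
kalman_filter <- function(y, obs, params) {
  y <- as.matrix(y); obs <- as.matrix(obs)
  if (!inherits(params, "ss_params")) abort("`params` must be an `ss_params` object.")
  d <- length(params$mu0)
  Tn <- nrow(y)
  if (nrow(obs) != Tn || ncol(y) != d || ncol(obs) != d) {
    abort("`y` and `obs` must be T x d with d matching `params`.")
  }
  if (any(obs & is.na(y))) {
    abort(sprintf("Observed entry is NA at trial %d.",
                  which(rowSums(obs & is.na(y)) > 0)[1]))
  }
  yc <- y
  yc[is.na(yc)] <- 0  # never read: masked by `obs`
  res <- cpp_kfilter(yc, matrix(as.integer(obs), nrow(obs), ncol(obs)),
                     params$phi, params$Q, params$R, params$mu0, params$Sigma0)
  structure(c(res,
              list(xf0 = params$mu0, Pf0 = params$Sigma0,
                   y = y, obs = obs, params = params)),
            class = "kfilter")
}

#' Fixed-interval (RTS) smoother with lag-one covariances
#'
#' Runs the Rauch–Tung–Striebel backward pass on a completed
#' [kalman_filter()] output, producing smoothed means/covariances for
#' trials `0..T` and the lag-one smoothed covariances
#' `Cov(x_t, x_{t-1} | y_{1:T})` needed by the EM M-step. At the final
#' trial the smoothed and filtered moments coincide.
#'
#' @param kf A `kfilter` object.
#' @return A list of class `ksmooth` with `xs` (d x T smoothed means),
#'   `Ps` (d x d x T), `xs0`/`Ps0` (smoothed time-0 moments), and `Pcs`
#'   (d x d x T, `Pcs[,,t] = Cov(x_t, x_{t-1} | y)`).
#' @examples
#' p <- ss_params(matrix(1), matrix(0.1), matrix(0.5), 0, matrix(1))
#' ks <- kalman_smoother(kalman_filter(matrix(c(1, 2)), matrix(TRUE, 2, 1), p))
#' ks$xs
#' @export
kalman_smoother <- function(kf) {
  if (!inherits(kf, "kfilter")) abort("`kf` must come from `kalman_filter()`.")
  d <- nrow(kf$xf)
  Pp <- kf$Pp; dim(Pp) <- c(d, d, ncol(kf$xf))
  Pf <- kf$Pf; dim(Pf) <- c(d, d, ncol(kf$xf))
  res <- cpp_ksmoother(kf$xp, Pp, kf$xf, Pf, kf$xf0, kf$Pf0,
                       kf$params$phi, kf$KA_last)
  structure(list(xs = res$xs, Ps = res$Ps, xs0 = drop(res$xs0),
                 Ps0 = res$Ps0, Pcs = res$Pcs,
                 loglik = kf$loglik, filter = kf),
            class = "ksmooth")
}

default_ss_init <- function(y, obs, phi_scale = 0.5, init_cov_factor = 10) {
  d <- ncol(y)
  m <- numeric(d); v <- numeric(d)
  for (j in seq_len(d)) {
    yj <- y[obs[, j], j]
    m[j] <- mean(yj)
    v[j] <- if (length(yj) >= 2) var(yj) else 1
    if (!is.finite(v[j]) || v[j] <= 0) v[j] <- 1e-6
  }
  ss_params(
    phi = diag(phi_scale, d),
    Q = diag(v / 2, d),
    R = diag(v / 2, d),
    mu0 = m,
    Sigma0 = diag(init_cov_factor * v, d)
  )
}

#' EM estimation of the missing-data state-space model
#'
#' Maximum-likelihood fitting of the [ss_params()] model by
#' Expectation–Maximization: the E-step runs [kalman_filter()] and
#' [kalman_smoother()] under the current parameters; the M-step updates the
#' transition matrix, state-noise covariance, observation-noise variances
#' (diagonal; with this task's observation patterns the go-RT channel is
#' never observed jointly with another channel, so off-diagonal
#' observation-noise terms are unidentifiable), and the initial state
#' moments in closed form. Iterations stop when the relative change in
#' log-likelihood falls below `rel_tol` (default 1%) or at `max_iter`.
#' The log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @inheritParams kalman_filter
#' @param init Initial [ss_params()]; when `NULL`, data-driven defaults are
#'   used (per-channel observed means, `Phi = 0.5 I`, `Q = R =` half the
#'   observed per-channel variance on the diagonal, `Sigma0 = 10 x`
#'   observed variance).
#' @param rel_tol Relative log-likelihood change below which EM stops.
#' @param max_iter Iteration cap.
#' @param structure `"full"` estimates unconstrained `Phi` and `Q`;
#'   `"diagonal"` constrains both to diagonals (independent AR(1) channels).
#' @param update_init Update `mu0`/`Sigma0` in the M-step (default `TRUE`).
#'
#' @return An object of class `ss_fit`: `params` (final [ss_params()]),
#'   `smooth` (final [kalman_smoother()] output under the fitted
#'   parameters), `loglik_trace`, `converged`, `iterations`.
#' @examples
#' set.seed(1)
#' y <- matrix(cumsum(rnorm(50, sd = 0.3)) + rnorm(50, sd = 0.2), ncol = 1)
#' fit <- em_fit(y, matrix(TRUE, 50, 1))
#' fit$converged
#' @export
em_fit <- function(y, obs, init = NULL, rel_tol = 0.01, max_iter = 500L,
                   structure = c("full", "diagonal"), update_init = TRUE) {
  structure_ <- match.arg(structure)
  y <- as.matrix(y); obs <- as.matrix(obs)
  d <- ncol(y); Tn <- nrow(y)
  if (Tn < 2L) abort("Need at least 2 trials.")
  n_obs <- colSums(obs)
  if (any(n_obs == 0L)) {
    abort(sprintf("Channel(s) %s never observed: observation noise unidentifiable.",
                  paste(which(n_obs == 0L), collapse = ", ")))
  }
  params <- if (is.null(init)) default_ss_init(y, obs) else init
  if (!inherits(params, "ss_params")) abort("`init` must be an `ss_params` object.")

  ll_trace <- numeric(0)
  converged <- FALSE
  ks <- NULL
  for (it in seq_len(max_iter)) {
    kf <- kalman_filter(y, obs, params)
    ks <- kalman_smoother(kf)
    ll <- kf$loglik
    if (length(ll_trace) > 0) {
      prev <- ll_trace[length(ll_trace)]
      if (ll < prev - 1e-8 * (1 + abs(prev))) {
        abort(sprintf("EM log-likelihood decreased at iteration %d (%.6f -> %.6f).",
                      it, prev, ll))
      }
      if (abs(ll - prev) / (abs(prev) + 1e-12) < rel_tol) {
        ll_trace <- c(ll_trace, ll)
        converged <- TRUE
        break
      }
    }
    ll_trace <- c(ll_trace, ll)

    # --- M-step sufficient statistics over t = 1..T (t-1 = 0 uses xs0/Ps0)
    xs <- ks$xs; Ps <- ks$Ps; Pcs <- ks$Pcs
    xs_prev <- cbind(ks$xs0, xs[, -Tn, drop = FALSE])
    S11 <- tcrossprod(xs) + apply(Ps, c(1, 2), sum)
    S10 <- xs %*% t(xs_prev) + apply(Pcs, c(1, 2), sum)
    S00 <- tcrossprod(xs_prev) + apply(Ps[, , -Tn, drop = FALSE], c(1, 2), sum) + ks$Ps0

    if (structure_ == "diagonal") {
      phi_new <- diag(diag(S10) / diag(S00), d)
      Q_new <- diag(pmax((diag(S11) - diag(phi_new) * diag(S10)) / Tn, 1e-12), d)
    } else {
      phi_new <- S10 %*% solve(S00)
      Q_new <- sym((S11 - phi_new %*% t(S10)) / Tn)
      # guard tiny negative eigenvalues from roundoff
      eq <- eigen(Q_new, symmetric = TRUE)
      Q_new <- sym(eq$vectors %*% diag(pmax(eq$values, 1e-12), d) %*% t(eq$vectors))
    }
    r_new <- numeric(d)
    for (j in seq_len(d)) {
      tj <- which(obs[, j])
      r_new[j] <- sum((y[tj, j] - xs[j, tj])^2 + Ps[j, j, tj]) / length(tj)
      r_new[j] <- max(r_new[j], 1e-12)
    }
    mu0_new <- if (update_init) ks$xs0 else params$mu0
    Sigma0_new <- if (update_init) sym(ks$Ps0) else params$Sigma0
    params <- suppressWarnings(
      ss_params(phi_new, Q_new, diag(r_new, d), mu0_new, Sigma0_new)
    )
  }
  if (!converged && max_iter > 0) {
    # final E-step already reflects the last parameter update? re-run for consistency
    kf <- kalman_filter(y, obs, params)
    ks <- kalman_smoother(kf)
    ll_trace <- c(ll_trace, kf$loglik)
  }
  structure(list(params = params, smooth = ks, loglik_trace = ll_trace,
                 converged = converged, iterations = length(ll_trace),
                 n_obs = n_obs),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> %d EM iterations, logLik %.3f, %s\n",
              x$iterations, tail(x$loglik_trace, 1),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
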
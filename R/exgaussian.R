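#' Ex-Gaussian distribution parameters
#'
#' Constructs and validates the parameter triple of an ex-Gaussian
#' distribution, the convolution of a Normal(`mu`, `sigma^2`) and an
#' Exponential with mean `tau`. The ex-Gaussian is the standard parametric
#' model for reaction-time data: the Gaussian component captures the
#' central tendency, the exponential component the long right tail.
#' All three parameters are in milliseconds.
#'
#' The distribution mean is `mu + tau` and the variance is
#' `sigma^2 + tau^2`.
#'
#' @param mu Mean of the Gaussian component (ms).
#' @param sigma Standard deviation of the Gaussian component (ms); must be
#'   strictly positive.
#' @param tau Mean of the exponential component (ms); must be strictly
#'   positive.
#'
#' @return An object of class `exg_params`: a named list with elements
#'   `mu`, `sigma`, `tau`.
#' @examples
#' p <- exg_params(300, 35, 30)
#' exg_mean(p) # 330
#' exg_var(p)  # 35^2 + 30^2
#' @export
exg_params <- function(mu, sigma, tau) {
  if (!is.numeric(mu) || !is.numeric(sigma) || !is.numeric(tau) ||
      length(mu) != 1L || length(sigma) != 1L || length(tau) != 1L) {
    abort("`mu`, `sigma`, `tau` must be numeric scalars.")
  }
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(tau)) {
    abort("ex-Gaussian parameters must be finite.")
  }
  if (sigma <= 0) abort("`sigma` must be strictly positive.")
  if (tau <= 0) abort("`tau` must be strictly positive.")
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exg_params")
}

#' @export
format.exg_params <- function(x, ...) {
  sprintf("ExG(%g, %g, %g)", x$mu, x$sigma, x$tau)
}

#' @export
print.exg_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname exg_params
#' @export
exg_mean <- function(p) p$mu + p$tau

#' @rdname exg_params
#' @export
exg_var <- function(p) p$sigma^2 + p$tau^2

#' Sample from an ex-Gaussian distribution
#'
#' Draws independent variates as the sum of a Gaussian and an
#' exponential component.
#'
#' @param n Number of draws (positive integer).
#' @param params An [exg_params()] object.
#'
#' @return Numeric vector of `n` durations in ms.
#' @examples
#' set.seed(1)
#' x <- rexgauss(1e4, exg_params(300, 35, 30))
#' mean(x) # close to 330
#' @export
rexgauss <- function(n, params) {
  if (!inherits(params, "exg_params")) params <- do.call(exg_params, as.list(params))
  if (!is.numeric(n) || length(n) != 1L || n < 0) abort("`n` must be a non-negative count.")
  if (n == 0) return(numeric(0))
  rnorm(n, params$mu, params$sigma) + rexp(n, rate = 1 / params$tau)
}
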
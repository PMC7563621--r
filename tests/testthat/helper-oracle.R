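# Brute-force joint-Gaussian conditioning oracle for the linear-Gaussian
# state-space model. Stacks x_0..x_T into one multivariate normal, selects
# the observed entries, and conditions exactly. Independent of the
# filter/smoother implementation (plain dense linear algebra), so it serves
# as the reference on small instances.

oracle_ssm <- function(y, obs, params) {
  y <- as.matrix(y)
  obs <- as.matrix(obs)
  d <- length(params$mu0)
  Tn <- nrow(y)
  nb <- Tn + 1L # blocks: x_0 .. x_T
  idx <- function(b) ((b - 1L) * d + 1L):(b * d) # b = 1 -> x_0

  # joint prior mean and covariance of (x_0, ..., x_T)
  mu <- matrix(0, d, nb)
  mu[, 1] <- params$mu0
  V <- vector("list", nb)
  V[[1]] <- params$Sigma0
  for (b in 2:nb) {
    mu[, b] <- params$phi %*% mu[, b - 1]
    V[[b]] <- params$phi %*% V[[b - 1]] %*% t(params$phi) + params$Q
  }
  S <- matrix(0, nb * d, nb * d)
  for (s in 1:nb) {
    S[idx(s), idx(s)] <- V[[s]]
    if (s < nb) {
      M <- V[[s]]
      for (t2 in (s + 1):nb) {
        M <- params$phi %*% M # Cov(x_{t2-1}, x_{s-1}) = Phi^(t2-s) V_s
        S[idx(t2), idx(s)] <- M
        S[idx(s), idx(t2)] <- t(M)
      }
    }
  }

  # observed entries: y[t, j] = x_t[j] + v, v ~ N(0, R[j, j])
  ent <- which(obs, arr.ind = TRUE)
  ent <- ent[order(ent[, 1], ent[, 2]), , drop = FALSE]
  nob <- nrow(ent)
  H <- matrix(0, nob, nb * d)
  Rv <- numeric(nob)
  yv <- numeric(nob)
  for (i in seq_len(nob)) {
    t_i <- ent[i, 1]; j_i <- ent[i, 2]
    H[i, idx(t_i + 1L)[j_i]] <- 1
    Rv[i] <- params$R[j_i, j_i]
    yv[i] <- y[t_i, j_i]
  }
  Sy <- H %*% S %*% t(H) + diag(Rv, nob)
  Sy <- (Sy + t(Sy)) / 2
  my <- H %*% as.vector(mu)

  # exact Gaussian log-likelihood of the observed vector
  ch <- chol(Sy)
  z <- backsolve(ch, yv - my, transpose = TRUE)
  loglik <- -0.5 * (nob * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))

  # exact conditional (smoothing) distribution of all states
  K <- S %*% t(H) %*% chol2inv(ch)
  cmean <- as.vector(mu) + K %*% (yv - my)
  ccov <- S - K %*% H %*% S
  ccov <- (ccov + t(ccov)) / 2

  xs <- matrix(NA_real_, d, Tn)
  Ps <- array(NA_real_, c(d, d, Tn))
  Pcs <- array(NA_real_, c(d, d, Tn)) # Cov(x_t, x_{t-1} | y)
  for (t2 in seq_len(Tn)) {
    xs[, t2] <- cmean[idx(t2 + 1L)]
    Ps[, , t2] <- ccov[idx(t2 + 1L), idx(t2 + 1L)]
    Pcs[, , t2] <- ccov[idx(t2 + 1L), idx(t2)]
  }
  list(
    loglik = loglik,
    xs = xs, Ps = Ps, Pcs = Pcs,
    xs0 = cmean[idx(1L)], Ps0 = ccov[idx(1L), idx(1L)]
  )
}
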
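// Kalman filter and fixed-interval smoother for the missing-data
// linear-Gaussian state-space model. Per-trial selection of observed
// channels; Joseph-form covariance update; innovations-form Gaussian
// log-likelihood. Called from R/statespace.R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat symm(const arma::mat& m) { return 0.5 * (m + m.t()); }

// [[Rcpp::export]]
Rcpp::List cpp_kfilter(const arma::mat& y, const arma::umat& obs, const arma::mat& phi,
                       const arma::mat& Q, const arma::mat& R, const arma::vec& mu0,
                       const arma::mat& Sigma0) {
  const uword T = y.n_rows, d = y.n_cols;
  mat xp(d, T), xf(d, T);
  cube Pp(d, d, T), Pf(d, d, T);
  vec xprev = mu0;
  mat Pprev = Sigma0;
  mat I_d = eye(d, d);
  mat KA_last(d, d, fill::zeros);
  double ll = 0.0;
  const double l2pi = std::log(2.0 * datum::pi);

  for (uword t = 0; t < T; ++t) {
    vec xpt = phi * xprev;
    mat Ppt = symm(phi * Pprev * phi.t() + Q);
    uvec idx = find(obs.row(t).t());
    mat KA(d, d, fill::zeros);
    vec xft;
    mat Pft;
    if (idx.n_elem > 0) {
      vec e = y.row(t).t();
      e = e(idx) - xpt(idx);
      mat S = Ppt.submat(idx, idx) + R.submat(idx, idx);
      mat Sc;
      if (!chol(Sc, S)) {
        Rcpp::stop("Singular innovation covariance at trial %d.", (int)(t + 1));
      }
      mat Sinv = inv_sympd(symm(S));
      mat K = Ppt.cols(idx) * Sinv;
      xft = xpt + K * e;
      mat IKA = I_d;
      IKA.cols(idx) -= K;
      Pft = symm(IKA * Ppt * IKA.t() + K * R.submat(idx, idx) * K.t());
      double ldet = 2.0 * accu(log(Sc.diag()));
      ll -= 0.5 * ((double)idx.n_elem * l2pi + ldet + as_scalar(e.t() * Sinv * e));
      KA.cols(idx) = K;
    } else {
      xft = xpt;
      Pft = Ppt;
    }
    xp.col(t) = xpt; Pp.slice(t) = Ppt;
    xf.col(t) = xft; Pf.slice(t) = Pft;
    xprev = xft; Pprev = Pft;
    if (t == T - 1) KA_last = KA;
  }
  return Rcpp::List::create(
    Rcpp::Named("xp") = xp, Rcpp::Named("Pp") = Pp,
    Rcpp::Named("xf") = xf, Rcpp::Named("Pf") = Pf,
    Rcpp::Named("loglik") = ll, Rcpp::Named("KA_last") = KA_last);
}

// [[Rcpp::export]]
Rcpp::List cpp_ksmoother(const arma::mat& xp, const arma::cube& Pp, const arma::mat& xf,
                         const arma::cube& Pf, const arma::vec& xf0, const arma::mat& Pf0,
                         const arma::mat& phi, const arma::mat& KA_last) {
  const uword d = xf.n_rows, T = xf.n_cols;
  mat xs(d, T);
  cube Ps(d, d, T), Pcs(d, d, T), J(d, d, T);
  xs.col(T - 1) = xf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  // J.slice(t) maps smoothing info at trial t+1 (1-based) back to trial t
  for (uword t = 0; t < T; ++t) {
    const arma::mat& Pf_prev = (t == 0) ? Pf0 : Pf.slice(t - 1);
    J.slice(t) = solve(Pp.slice(t), phi * Pf_prev).t();
  }
  for (uword k = T - 1; k-- > 0;) {
    const arma::mat& Jt = J.slice(k + 1);
    xs.col(k) = xf.col(k) + Jt * (xs.col(k + 1) - xp.col(k + 1));
    Ps.slice(k) = symm(Pf.slice(k) + Jt * (Ps.slice(k + 1) - Pp.slice(k + 1)) * Jt.t());
  }
  const arma::mat& J1 = J.slice(0);
  vec xs0 = xf0 + J1 * (xs.col(0) - xp.col(0));
  mat Ps0 = symm(Pf0 + J1 * (Ps.slice(0) - Pp.slice(0)) * J1.t());
  // lag-one smoothed covariances Cov(x_t, x_{t-1} | y_{1:T})
  Pcs.slice(T - 1) = (eye(d, d) - KA_last) * phi *
    ((T == 1) ? Pf0 : Pf.slice(T - 2));
  if (T >= 2) {
    for (uword k = T - 1; k-- > 0;) {
      const arma::mat& Pf_t = Pf.slice(k);
      const arma::mat& Jtm1 = J.slice(k);
      const arma::mat& Jt = J.slice(k + 1);
      Pcs.slice(k) = Pf_t * Jtm1.t() +
        Jt * (Pcs.slice(k + 1) - phi * Pf_t) * Jtm1.t();
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("xs") = xs, Rcpp::Named("Ps") = Ps,
    Rcpp::Named("xs0") = xs0, Rcpp::Named("Ps0") = Ps0,
    Rcpp::Named("Pcs") = Pcs);
}
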
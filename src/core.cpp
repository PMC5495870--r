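// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Multi-trial time-variant MVAR estimation by linear Kalman filtering.
//
// State per channel i: a_i(t), the i-th rows of all p lag matrices stacked as
// a_i[(k-1)*D + j] = A_k[i, j].  Random-walk state evolution with process
// noise c2 * I; scalar observation y_i(t) = phi(t)' a_i + v, where phi(t) is
// the D*p vector of lagged samples shared by all channels.  Measurement noise
// R_i is adapted by exponential smoothing of squared innovations with rate c1.
// With diagonal measurement noise the full D^2*p-state multivariate filter
// decouples exactly into these D channelwise filters.  Trials update the same
// state sequentially within each time step before time advances.
//
// y: cube D x T x R (channels x samples x trials)
// Returns list with A: cube D x (D*p) x T, sigma2: D x T.
// [[Rcpp::export]]
Rcpp::List kalman_fit_cpp(const arma::cube& y, int p, double c1, double c2,
                          double init_coeff, double init_state_cov) {
  const uword D = y.n_rows, T = y.n_cols, R = y.n_slices;
  const uword m = D * (uword)p;

  mat a(m, D);            // state per channel (columns)
  a.fill(init_coeff);
  cube P(m, m, D);        // state covariance per channel
  for (uword i = 0; i < D; ++i) P.slice(i) = init_state_cov * eye(m, m);
  vec Rn(D, fill::ones);  // adaptive measurement-noise variance

  cube A(D, m, T, fill::value(init_coeff));
  mat sigma2(D, T, fill::ones);

  vec phi(m);
  for (uword t = (uword)p; t < T; ++t) {
    for (uword i = 0; i < D; ++i) P.slice(i).diag() += c2;  // predict
    for (uword r = 0; r < R; ++r) {
      for (int k = 1; k <= p; ++k)
        phi.subvec((k - 1) * D, k * D - 1) = y.slice(r).col(t - k);
      for (uword i = 0; i < D; ++i) {
        vec Pphi = P.slice(i) * phi;
        double s = dot(phi, Pphi) + Rn(i);
        if (s < 1e-12) s = 1e-12;  // ridge-stabilized innovation variance
        double e = y(i, t, r) - dot(phi, a.col(i));
        vec K = Pphi / s;
        a.col(i) += K * e;
        P.slice(i) -= K * Pphi.t();
        Rn(i) = (1.0 - c1) * Rn(i) + c1 * e * e;
        if (Rn(i) < 1e-12) Rn(i) = 1e-12;
      }
    }
    A.slice(t) = a.t();
    sigma2.col(t) = Rn;
  }
  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("sigma2") = sigma2);
}

// Simulate a VAR process whose coefficients switch from A_pre to A_post at
// sample `onset` (0-based, first sample governed by A_post).  Coefficient
// cubes are D x D x p; eps is the D x T innovation matrix drawn in R so that
// the caller's RNG governs determinism.
// [[Rcpp::export]]
arma::mat var_simulate_cpp(const arma::cube& A_pre, const arma::cube& A_post,
                           int onset, const arma::mat& eps) {
  const uword D = eps.n_rows, T = eps.n_cols, p = A_pre.n_slices;
  mat x(D, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const cube& A = ((int)t >= onset) ? A_post : A_pre;
    vec acc = eps.col(t);
    for (uword k = 1; k <= p && k <= t; ++k)
      acc += A.slice(k - 1) * x.col(t - k);
    x.col(t) = acc;
  }
  return x;
}
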
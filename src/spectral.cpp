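// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Fourier transform of the tvMVAR coefficients:
// Abar(f, t) = I - sum_k A_k(t) exp(-i 2 pi f k / fs).
static cx_mat abar_at(const mat& At, const cx_mat& E, uword D, uword p,
                      uword fi) {
  cx_mat Ab(D, D, fill::eye);
  for (uword k = 0; k < p; ++k)
    Ab -= E(k, fi) * conv_to<cx_mat>::from(At.cols(k * D, (k + 1) * D - 1));
  return Ab;
}

static cx_mat exponent_table(const vec& freqs, double fs, uword p) {
  cx_mat E(p, freqs.n_elem);
  for (uword k = 0; k < p; ++k)
    for (uword fi = 0; fi < freqs.n_elem; ++fi)
      E(k, fi) = std::exp(cx_double(0.0, -2.0 * M_PI * freqs(fi) * (k + 1) / fs));
  return E;
}

// Generalized PDC: pi(i <- j, t, f) = (|Abar_ij| / sigma_i) /
// sqrt(sum_m |Abar_mj|^2 / sigma_m^2).  Raw values (diagonal included in the
// column normalization and returned).  Output dims D x D x T x F (vectorized).
// [[Rcpp::export]]
Rcpp::NumericVector tv_gpdc_cpp(const arma::cube& A, const arma::mat& sigma2,
                                double fs, const arma::vec& freqs, int p) {
  const uword D = A.n_rows, T = A.n_slices, F = freqs.n_elem;
  cx_mat E = exponent_table(freqs, fs, (uword)p);
  Rcpp::NumericVector out(D * D * T * F);
  for (uword t = 0; t < T; ++t) {
    vec s = sqrt(sigma2.col(t));
    for (uword i = 0; i < D; ++i) {
      if (!(s(i) > 0)) Rcpp::stop("zero residual variance in channel %d", i + 1);
    }
    for (uword fi = 0; fi < F; ++fi) {
      cx_mat Ab = abar_at(A.slice(t), E, D, (uword)p, fi);
      mat Aabs = abs(Ab);
      for (uword j = 0; j < D; ++j) {
        double denom = 0.0;
        for (uword m = 0; m < D; ++m) {
          double v = Aabs(m, j) / s(m);
          denom += v * v;
        }
        denom = std::sqrt(denom);
        for (uword i = 0; i < D; ++i) {
          out[i + D * j + D * D * t + D * D * T * fi] =
            (Aabs(i, j) / s(i)) / denom;
        }
      }
    }
  }
  return out;
}

// Parametric amplitude spectrum from the tvMVAR transfer function:
// H(f,t) = Abar(f,t)^{-1}; auto-spectrum S_ii = sum_m |H_im|^2 sigma2_m;
// amplitude = sqrt(2 * df * S_ii).  Output dims D x T x F (vectorized).
// [[Rcpp::export]]
Rcpp::NumericVector tv_spectrum_cpp(const arma::cube& A, const arma::mat& sigma2,
                                    double fs, const arma::vec& freqs, int p,
                                    double df) {
  const uword D = A.n_rows, T = A.n_slices, F = freqs.n_elem;
  cx_mat E = exponent_table(freqs, fs, (uword)p);
  Rcpp::NumericVector out(D * T * F);
  for (uword t = 0; t < T; ++t) {
    for (uword fi = 0; fi < F; ++fi) {
      cx_mat Ab = abar_at(A.slice(t), E, D, (uword)p, fi);
      cx_mat H;
      bool ok = inv(H, Ab);
      for (uword i = 0; i < D; ++i) {
        double v = NA_REAL;
        if (ok) {
          double Sii = 0.0;
          for (uword m = 0; m < D; ++m) {
            double h = std::abs(H(i, m));
            Sii += h * h * sigma2(m, t);
          }
          v = std::sqrt(2.0 * df * Sii);
        }
        out[i + D * t + D * T * fi] = v;
      }
    }
  }
  return out;
}
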
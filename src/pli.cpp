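#include <Rcpp.h>
using namespace Rcpp;

// sign of a phase difference wrapped to (-pi, pi]; sign(0) = 0.
// Inputs are differences of wrapped phases, so |d| < 2*pi and a one-step
// reduction suffices (no fmod; kept loop-safe for slightly larger inputs).
static inline double sgn_wrapped(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  if (d > 0) return 1.0;
  if (d < 0) return -1.0;
  return 0.0;
}

// PLI adjacency for one epoch. `phases`: samples x n_roi matrix of
// instantaneous phases. Returns n_roi x n_roi symmetric matrix with zero
// diagonal, entries |mean_t sign(phi_i - phi_j)|.
// [[Rcpp::export(name = ".pli_matrix_cpp")]]
NumericMatrix pli_matrix_cpp(NumericMatrix phases) {
  const int n = phases.nrow();
  const int p = phases.ncol();
  NumericMatrix out(p, p);
  for (int i = 0; i < p; ++i) {
    const double* pi_ = &phases(0, i);
    for (int j = i + 1; j < p; ++j) {
      const double* pj_ = &phases(0, j);
      double acc = 0.0;
      for (int t = 0; t < n; ++t) acc += sgn_wrapped(pi_[t] - pj_[t]);
      double v = std::abs(acc / n);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// PLI for selected pairs from analytic signals (real/imaginary parts):
// sign(sin(phi_i - phi_j)) = sign(Im(a_i * conj(a_j))) because the envelopes
// are positive. Equivalent to the phase-difference form except on the
// measure-zero set phi_i - phi_j = pi.
// [[Rcpp::export(name = ".pli_pairs_analytic_cpp")]]
NumericVector pli_pairs_analytic_cpp(NumericMatrix re, NumericMatrix im,
                                     IntegerVector i, IntegerVector j) {
  const int n = re.nrow();
  const int m = i.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    const double* ri = &re(0, i[k] - 1);
    const double* ii = &im(0, i[k] - 1);
    const double* rj = &re(0, j[k] - 1);
    const double* ij = &im(0, j[k] - 1);
    double acc = 0.0;
    for (int t = 0; t < n; ++t) {
      double s = ii[t] * rj[t] - ri[t] * ij[t];
      if (s > 0) acc += 1.0;
      else if (s < 0) acc -= 1.0;
    }
    out[k] = std::abs(acc / n);
  }
  return out;
}

// PLI for selected unordered pairs only (1-based index columns i, j).
// [[Rcpp::export(name = ".pli_pairs_cpp")]]
NumericVector pli_pairs_cpp(NumericMatrix phases, IntegerVector i, IntegerVector j) {
  const int n = phases.nrow();
  const int m = i.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    const double* pi_ = &phases(0, i[k] - 1);
    const double* pj_ = &phases(0, j[k] - 1);
    double acc = 0.0;
    for (int t = 0; t < n; ++t) acc += sgn_wrapped(pi_[t] - pj_[t]);
    out[k] = std::abs(acc / n);
  }
  return out;
}
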
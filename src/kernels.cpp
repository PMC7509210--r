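#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation over integer lags.
// rho[tau + L] = Pearson correlation between x(t) and y(t + tau) over
// the overlapping range, each window mean-removed. Windows with zero
// variance on either side yield rho = 0.
// [[Rcpp::export(name = ".xcorr_norm_cpp")]]
NumericVector xcorr_norm_cpp(NumericVector x, NumericVector y, int max_lag) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (max_lag < 0 || max_lag >= n - 1) stop("max_lag out of range");
  NumericVector rho(2 * max_lag + 1);
  for (int tau = -max_lag; tau <= max_lag; ++tau) {
    // overlap: t in [t0, t1) pairs x[t] with y[t + tau]
    const int t0 = tau < 0 ? -tau : 0;
    const int t1 = tau < 0 ? n : n - tau;
    const int m = t1 - t0;
    double sx = 0.0, sy = 0.0;
    for (int t = t0; t < t1; ++t) { sx += x[t]; sy += y[t + tau]; }
    const double mx = sx / m, my = sy / m;
    double sxx = 0.0, syy = 0.0, sxy = 0.0;
    for (int t = t0; t < t1; ++t) {
      const double dx = x[t] - mx, dy = y[t + tau] - my;
      sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
    }
    const double denom = std::sqrt(sxx) * std::sqrt(syy);
    rho[tau + max_lag] = denom > 0.0 ? sxy / denom : 0.0;
  }
  return rho;
}

// Pincus approximate-entropy building block: for embedding dimension m
// and tolerance r (max-norm), returns per-template match counts
// (self-match included) and Phi^m = mean(log(C_i)), with
// C_i = count_i / (N - m + 1).
// [[Rcpp::export(name = ".apen_phi_cpp")]]
List apen_phi_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m + 1;  // number of templates
  if (nt < 1) stop("series too short for embedding dimension m");
  IntegerVector counts(nt);
  for (int i = 0; i < nt; ++i) counts[i] = 1;  // self-match
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) { ++counts[i]; ++counts[j]; }
    }
  }
  double phi = 0.0;
  for (int i = 0; i < nt; ++i) phi += std::log((double)counts[i] / nt);
  phi /= nt;
  return List::create(_["phi"] = phi, _["counts"] = counts);
}
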
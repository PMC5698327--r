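#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// 4 ln 2: Gaussian written as A * exp(-4 ln2 (x - mu)^2 / w^2) with w = FWHM.
static const double FOUR_LN2 = 2.772588722239781;

//' Sum of Gaussian bands evaluated on a wavenumber grid.
//'
//' @param x numeric grid (cm^-1)
//' @param center,fwhm,amplitude equal-length band parameter vectors
//' @return numeric vector, same length as x
//' @keywords internal
// [[Rcpp::export(name = ".gauss_sum_cpp")]]
NumericVector gauss_sum_cpp(NumericVector x, NumericVector center,
                            NumericVector fwhm, NumericVector amplitude) {
  const int n = x.size(), m = center.size();
  if (fwhm.size() != m || amplitude.size() != m)
    stop("band parameter vectors must have equal length");
  NumericVector out(n);
  for (int j = 0; j < m; ++j) {
    const double mu = center[j], w = fwhm[j], a = amplitude[j];
    if (w <= 0) stop("fwhm must be positive");
    const double k = FOUR_LN2 / (w * w);
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - mu;
      out[i] += a * std::exp(-k * d * d);
    }
  }
  return out;
}

// Jacobian of the Gaussian sum w.r.t. parameters ordered
// (c1, w1, a1, c2, w2, a2, ...): n x 3m matrix.
// [[Rcpp::export(name = ".gauss_jac_cpp")]]
NumericMatrix gauss_jac_cpp(NumericVector x, NumericVector center,
                            NumericVector fwhm, NumericVector amplitude) {
  const int n = x.size(), m = center.size();
  NumericMatrix J(n, 3 * m);
  for (int j = 0; j < m; ++j) {
    const double mu = center[j], w = fwhm[j], a = amplitude[j];
    const double k = FOUR_LN2 / (w * w);
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - mu;
      const double e = std::exp(-k * d * d);
      J(i, 3 * j)     = a * e * 2.0 * k * d;            // d/d center
      J(i, 3 * j + 1) = a * e * 2.0 * k * d * d / w;    // d/d fwhm
      J(i, 3 * j + 2) = e;                              // d/d amplitude
    }
  }
  return J;
}
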
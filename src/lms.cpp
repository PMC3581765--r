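#include <Rcpp.h>
using namespace Rcpp;

// Least-mean-squares adaptive linear prediction of a single window.
// Predictor form: xhat[n] = sum_k a_k x[n-k], k = 1..order, weights
// initialized at zero and adapted over `passes` sweeps of the window.
// When `average` is true the reported coefficients are the mean of the
// weight trajectory over the final pass (tail averaging), which removes
// most of the steady-state gradient noise without changing the adapted
// solution. The window is normalized to unit variance internally so the
// step size has a scale-free meaning; AR coefficients are scale invariant.
//
// Returns the coefficient vector; sets `diverged` (attribute) if the
// weight norm exceeded the stability bound at any point.

static bool lms_window(const double* x, int n, int order, double mu,
                       int passes, bool average, double* out) {
  std::vector<double> w(order, 0.0), wsum(order, 0.0);
  long navg = 0;
  for (int p = 0; p < passes; ++p) {
    for (int t = order; t < n; ++t) {
      double e = x[t];
      for (int k = 0; k < order; ++k) e -= w[k] * x[t - 1 - k];
      for (int k = 0; k < order; ++k) w[k] += mu * e * x[t - 1 - k];
      if (p == passes - 1 && average) {
        for (int k = 0; k < order; ++k) wsum[k] += w[k];
        ++navg;
      }
    }
    double nrm = 0.0;
    for (int k = 0; k < order; ++k) nrm += w[k] * w[k];
    if (!std::isfinite(nrm) || nrm > 100.0) return false;
  }
  if (average && navg > 0) {
    for (int k = 0; k < order; ++k) out[k] = wsum[k] / navg;
  } else {
    for (int k = 0; k < order; ++k) out[k] = w[k];
  }
  return true;
}

// [[Rcpp::export]]
NumericVector lms_ar_cpp(NumericVector x, int order, double mu, int passes,
                         bool average) {
  int n = x.size();
  NumericVector out(order);
  if (n <= order) stop("window shorter than the AR order");
  // unit-variance normalization (coefficients are scale invariant)
  double m = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  for (int i = 0; i < n; ++i) s2 += (x[i] - m) * (x[i] - m);
  s2 /= (n - 1);
  if (s2 <= 0.0) return out;  // constant window: no adaptation
  double s = std::sqrt(s2);
  std::vector<double> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = x[i] / s;
  bool ok = lms_window(xs.data(), n, order, mu, passes, average,
                       REAL(out));
  out.attr("diverged") = !ok;
  return out;
}

// Column-wise LMS over a windows matrix (win_len x n_windows), one window
// per column. Returns order x n_windows coefficient matrix.
// [[Rcpp::export]]
NumericMatrix lms_ar_matrix_cpp(NumericMatrix M, int order, double mu,
                                int passes, bool average) {
  int n = M.nrow(), W = M.ncol();
  if (n <= order) stop("window shorter than the AR order");
  NumericMatrix out(order, W);
  std::vector<double> xs(n);
  bool any_div = false;
  for (int w = 0; w < W; ++w) {
    double m = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) m += M(i, w);
    m /= n;
    for (int i = 0; i < n; ++i) s2 += (M(i, w) - m) * (M(i, w) - m);
    s2 /= (n - 1);
    if (s2 <= 0.0) continue;
    double s = std::sqrt(s2);
    for (int i = 0; i < n; ++i) xs[i] = M(i, w) / s;
    std::vector<double> coef(order, 0.0);
    bool ok = lms_window(xs.data(), n, order, mu, passes, average,
                         coef.data());
    if (!ok) any_div = true;
    for (int k = 0; k < order; ++k) out(k, w) = coef[k];
  }
  out.attr("diverged") = any_div;
  return out;
}
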
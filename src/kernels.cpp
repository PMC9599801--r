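#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One pass of a direct-form-I IIR filter over a buffer with steady-state
// initial conditions: the virtual history is x[-j] = x[0] and
// y[-j] = g * x[0] with g the DC gain, i.e. the filter starts as if x[0]
// had been applied forever (scipy's lfilter_zi, expressed in DF1 state).
// b and a have equal length m+1 with a[0] == 1.
static inline void df1_pass(const NumericVector& b, const NumericVector& a,
                            const std::vector<double>& x, std::vector<double>& y,
                            int m, double dc_gain) {
  const int n = (int)x.size();
  const double x0 = n > 0 ? x[0] : 0.0;
  const double y0 = dc_gain * x0;
  if (m == 2) {  // biquad fast path (every cascade section)
    const double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
    double xm1 = x0, xm2 = x0, ym1 = y0, ym2 = y0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + b1 * xm1 + b2 * xm2 - a1 * ym1 - a2 * ym2;
      xm2 = xm1; xm1 = xi;
      ym2 = ym1; ym1 = yi;
      y[i] = yi;
    }
    return;
  }
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j <= m; ++j) acc += b[j] * (i - j >= 0 ? x[i - j] : x0);
    for (int j = 1; j <= m; ++j) acc -= a[j] * (i - j >= 0 ? y[i - j] : y0);
    y[i] = acc;
  }
}

// Zero-phase (forward-backward) IIR filtering of each column of x, with
// odd-reflection end padding of length padlen on each side. Requires
// 0 <= padlen < nrow(x); coefficient vectors padded to equal length upstream.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix x, int padlen) {
  const int n = x.nrow(), nc = x.ncol();
  const int m = b.size() - 1;
  const int N = n + 2 * padlen;
  NumericMatrix out(n, nc);
  std::vector<double> ext(N), fwd(N);

  double bsum = 0.0, asum = 0.0;
  for (int j = 0; j <= m; ++j) { bsum += b[j]; asum += a[j]; }
  const double dc_gain = asum != 0.0 ? bsum / asum : 0.0;

  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * x(0, c) - x(padlen - i, c);
    for (int i = 0; i < n; ++i) ext[padlen + i] = x(i, c);
    for (int i = 0; i < padlen; ++i) ext[padlen + n + i] = 2.0 * x(n - 1, c) - x(n - 2 - i, c);

    df1_pass(b, a, ext, fwd, m, dc_gain);
    std::reverse(fwd.begin(), fwd.end());
    df1_pass(b, a, fwd, ext, m, dc_gain);
    std::reverse(ext.begin(), ext.end());

    for (int i = 0; i < n; ++i) out(i, c) = ext[padlen + i];
  }
  return out;
}

// All-pairs phase lag index from an (samples x channels) matrix of
// instantaneous phases: |mean_k sign(dphi_k)| with dphi wrapped to (-pi, pi].
// [[Rcpp::export]]
NumericMatrix cpp_pli_matrix(NumericMatrix ph) {
  const int n = ph.nrow(), c = ph.ncol();
  const double twopi = 2.0 * M_PI;
  NumericMatrix out(c, c);
  for (int i = 0; i < c - 1; ++i) {
    for (int j = i + 1; j < c; ++j) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        double d = ph(k, i) - ph(k, j);
        d -= twopi * std::floor((d + M_PI) / twopi);  // -> [-pi, pi)
        if (d <= -M_PI) d += twopi;                   // -> (-pi, pi]
        s += (d > 0.0) - (d < 0.0);
      }
      const double v = std::fabs(s / (double)n);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
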
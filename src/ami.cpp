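#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Histogram plug-in MI in bits between two equal-length segments.
// Binning: equal-width bins over each segment's own observed range,
// index = floor((v - min) * bins / (max - min)) clamped to bins - 1.
// The R reference implementation (histogram_mi) uses the same arithmetic,
// so the two paths agree to the last bit.
// Entropies use H = log2(n) - (1/n) * sum_c c*log2(c) with a lookup table
// for c*log2(c), which avoids per-cell log calls.
static double mi_bits(const double* x, const double* y, int n, int bins,
                      std::vector<int>& joint, std::vector<int>& mx,
                      std::vector<int>& my, const std::vector<double>& clog) {
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  if (!(xmax > xmin) || !(ymax > ymin)) return 0.0; // degenerate (constant)
  const double sx = bins / (xmax - xmin);
  const double sy = bins / (ymax - ymin);
  std::fill(joint.begin(), joint.end(), 0);
  std::fill(mx.begin(), mx.end(), 0);
  std::fill(my.begin(), my.end(), 0);
  for (int i = 0; i < n; ++i) {
    int ix = (int)((x[i] - xmin) * sx);
    int iy = (int)((y[i] - ymin) * sy);
    if (ix >= bins) ix = bins - 1;
    if (iy >= bins) iy = bins - 1;
    ++joint[iy * bins + ix];
    ++mx[ix];
    ++my[iy];
  }
  double sxy = 0.0, sxm = 0.0, sym = 0.0;
  const int ncell = bins * bins;
  for (int k = 0; k < ncell; ++k) sxy += clog[joint[k]];
  for (int b = 0; b < bins; ++b) { sxm += clog[mx[b]]; sym += clog[my[b]]; }
  const double log2n = std::log2((double)n);
  const double invn = 1.0 / n;
  double hx = log2n - sxm * invn;
  double hy = log2n - sym * invn;
  double hxy = log2n - sxy * invn;
  return hx + hy - hxy;
}

static std::vector<double> make_clog(int n) {
  std::vector<double> clog(n + 1);
  clog[0] = 0.0;
  for (int c = 1; c <= n; ++c) clog[c] = c * std::log2((double)c);
  return clog;
}

// [[Rcpp::export]]
NumericVector cpp_mi(NumericVector x, NumericVector y, int bins) {
  int n = x.size();
  std::vector<int> joint(bins * bins), mx(bins), my(bins);
  std::vector<double> clog = make_clog(n);
  return NumericVector::create(mi_bits(REAL(x), REAL(y), n, bins, joint, mx, my, clog));
}

// AMI profiles for each row of a signals matrix.
// values[row, tau + 1] = MI(x[(tau+1)..T], x[1..(T-tau)]), tau = 0..max_delay.
// [[Rcpp::export]]
NumericMatrix cpp_ami_profiles(NumericMatrix signals, int max_delay, int bins) {
  const int nrow = signals.nrow(), T = signals.ncol();
  NumericMatrix out(nrow, max_delay + 1);
  std::vector<double> row(T);
  std::vector<int> joint(bins * bins), mx(bins), my(bins);
  std::vector<double> clog = make_clog(T);
  for (int r = 0; r < nrow; ++r) {
    for (int t = 0; t < T; ++t) row[t] = signals(r, t);
    for (int tau = 0; tau <= max_delay; ++tau) {
      out(r, tau) = mi_bits(row.data() + tau, row.data(), T - tau, bins,
                            joint, mx, my, clog);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
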
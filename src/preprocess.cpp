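#include <Rcpp.h>
#include <set>
#include <cmath>
using namespace Rcpp;

// Rolling median with centred window that shrinks symmetrically at the
// edges: out[i] = median(x[i-h_i .. i+h_i]), h_i = min(h, i, n-1-i).
// Window size is always odd so the median is an order statistic, never an
// average of two. Two-multiset (low/high) structure keeps O(log k) updates;
// needed because a 10-min window at 256 Hz is ~1.5e5 samples.
namespace {

struct MedianWindow {
  std::multiset<double> low, high; // max(low) is the median; |low| = |high| + 1 when odd

  void rebalance() {
    while (low.size() > high.size() + 1) {
      auto it = std::prev(low.end());
      high.insert(*it);
      low.erase(it);
    }
    while (low.size() < high.size()) {
      auto it = high.begin();
      low.insert(*it);
      high.erase(it);
    }
  }
  void insert(double v) {
    if (low.empty() || v <= *low.rbegin()) low.insert(v); else high.insert(v);
    rebalance();
  }
  void erase(double v) {
    auto it = low.find(v);
    if (it != low.end()) low.erase(it);
    else high.erase(high.find(v));
    rebalance();
  }
  double median() const { return *low.rbegin(); }
};

} // namespace

// [[Rcpp::export(name = ".rolling_median_centered")]]
NumericVector rolling_median_centered(NumericVector x, int half_width) {
  const int n = x.size();
  if (n == 0) stop("empty signal");
  NumericVector out(n);
  MedianWindow w;
  int lo = 0, hi = -1; // current window [lo, hi]
  for (int i = 0; i < n; ++i) {
    int h = std::min(half_width, std::min(i, n - 1 - i));
    int dlo = i - h, dhi = i + h;
    while (hi < dhi) w.insert(x[++hi]);
    while (lo > dlo) w.insert(x[--lo]);
    while (lo < dlo) w.erase(x[lo++]);
    while (hi > dhi) w.erase(x[hi--]);
    out[i] = w.median();
  }
  return out;
}

// Linear-phase FIR applied with zero net group delay (centre-aligned) and
// edge replication, evaluated only at output indices 0, d, 2d, ... .
// With d = 1 this is a plain zero-phase FIR; with d = fs_in/fs_out it is the
// filter-then-decimate composition computed at the kept samples only.
// [[Rcpp::export(name = ".fir_decimate")]]
NumericVector fir_decimate(NumericVector x, NumericVector kernel, int decim) {
  const int n = x.size();
  const int m = kernel.size();
  if (m % 2 == 0) stop("kernel length must be odd");
  if (decim < 1) stop("decimation factor must be >= 1");
  const int half = (m - 1) / 2;
  const int nout = (n - 1) / decim + 1;
  NumericVector out(nout);
  for (int k = 0; k < nout; ++k) {
    const int j = k * decim;
    double acc = 0.0;
    for (int t = 0; t < m; ++t) {
      int idx = j - t + half;
      if (idx < 0) idx = 0; else if (idx >= n) idx = n - 1; // replicate edges
      acc += kernel[t] * x[idx];
    }
    out[k] = acc;
  }
  return out;
}
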
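#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Batched feature extraction for sliding-window detection. Must agree with
// the reference R implementation in R/features.R (asserted in tests to
// ~1e-10); any change here must be mirrored there.

namespace {

// type-7 quantile (R default): linear interpolation of order statistics
double quantile7(const std::vector<double>& sorted, double p) {
  const int n = (int)sorted.size();
  if (n == 1) return sorted[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return sorted[n - 1];
  return sorted[lo] + (h - lo) * (sorted[lo + 1] - sorted[lo]);
}

// the ten time-domain statistics: mean, population variance, skewness,
// excess kurtosis, histogram entropy (10 bins, natural log), mean-cross
// rate, zero-cross rate, quartiles Q1/Q2/Q3
void stats10(const double* x, int n, double* out) {
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - mu;
    double d2 = d * d;
    m2 += d2; m3 += d2 * d; m4 += d2 * d2;
  }
  m2 /= n; m3 /= n; m4 /= n;
  double skew = 0.0, kurt = 0.0;
  if (m2 > 0) {
    skew = m3 / std::pow(m2, 1.5);
    kurt = m4 / (m2 * m2) - 3.0;
  }
  double mn = x[0], mx = x[0];
  for (int i = 1; i < n; ++i) { mn = std::min(mn, x[i]); mx = std::max(mx, x[i]); }
  double H = 0.0;
  if (mx > mn) {
    int cnt[10] = {0};
    for (int i = 0; i < n; ++i) {
      int b = (int)std::floor((x[i] - mn) / (mx - mn) * 10.0);
      if (b > 9) b = 9;
      cnt[b]++;
    }
    for (int b = 0; b < 10; ++b) {
      if (cnt[b] > 0) {
        double p = (double)cnt[b] / n;
        H -= p * std::log(p);
      }
    }
  }
  double mcr = 0, zcr = 0;
  for (int i = 0; i + 1 < n; ++i) {
    if ((x[i] - mu) * (x[i + 1] - mu) < 0) mcr += 1;
    if (x[i] * x[i + 1] < 0) zcr += 1;
  }
  std::vector<double> s(x, x + n);
  std::sort(s.begin(), s.end());
  out[0] = mu; out[1] = m2; out[2] = skew; out[3] = kurt; out[4] = H;
  out[5] = mcr; out[6] = zcr;
  out[7] = quantile7(s, 0.25);
  out[8] = quantile7(s, 0.50);
  out[9] = quantile7(s, 0.75);
}

// one-sided DFT magnitudes, bins 0..n/2 (DC included; unnormalised forward sum)
void dft_mag(const double* x, int n, std::vector<double>& mag) {
  const int nb = n / 2 + 1;
  mag.resize(nb);
  double scale = 0.0;
  for (int t = 0; t < n; ++t) scale += std::fabs(x[t]);
  for (int j = 0; j < nb; ++j) {
    double re = 0, im = 0;
    for (int t = 0; t < n; ++t) {
      double ang = -2.0 * M_PI * j * t / n;
      re += x[t] * std::cos(ang);
      im += x[t] * std::sin(ang);
    }
    double m = std::sqrt(re * re + im * im);
    // floor round-off junk in numerically-zero bins (kept in sync with the
    // reference R implementation)
    mag[j] = (m < 1e-9 * scale) ? 0.0 : m;
  }
}

// local maxima with plateau->leftmost rule; endpoints excluded
void local_maxima(const std::vector<double>& v, std::vector<int>& peaks) {
  peaks.clear();
  const int n = (int)v.size();
  int i = 1;
  while (i < n - 1) {
    if (v[i] > v[i - 1]) {
      int j = i;
      while (j + 1 < n && v[j + 1] == v[i]) ++j;
      if (j < n - 1 && v[j + 1] < v[i]) peaks.push_back(i);
      i = j + 1;
    } else {
      ++i;
    }
  }
}

// topographic prominence: height above the higher of the two bounding saddles
double prominence(const std::vector<double>& v, int p) {
  const double hgt = v[p];
  double minL = hgt, minR = hgt;
  for (int i = p - 1; i >= 0 && v[i] <= hgt; --i) minL = std::min(minL, v[i]);
  for (int i = p + 1; i < (int)v.size() && v[i] <= hgt; ++i) minR = std::min(minR, v[i]);
  return hgt - std::max(minL, minR);
}

// 25 features of one spectrum, DC bin excluded from peak search / quadrants
// but included in the stats10 input: 5 (freq, value) peak pairs ranked by
// prominence, absolute maximum, 4 quadrant counts, stats10.
void spectrum_features(const std::vector<double>& mag, double fs, int n, double* out) {
  const int nb = (int)mag.size();      // bins 0..n/2
  const double df = fs / n;
  std::vector<double> v(mag.begin() + 1, mag.end()); // drop DC
  const int B = (int)v.size();
  std::vector<int> pk;
  local_maxima(v, pk);
  std::vector<double> prom(pk.size());
  for (size_t k = 0; k < pk.size(); ++k) prom[k] = prominence(v, pk[k]);
  std::vector<int> ord(pk.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (prom[a] != prom[b]) return prom[a] > prom[b];
    return pk[a] < pk[b]; // tie -> lower frequency
  });
  for (int k = 0; k < 5; ++k) {
    if (k < (int)ord.size()) {
      int p = pk[ord[k]];
      out[2 * k]     = (p + 1) * df; // +1: v[0] is bin 1
      out[2 * k + 1] = v[p];
    } else {
      out[2 * k] = 0.0; out[2 * k + 1] = 0.0;
    }
  }
  double vmax = v[0], vmin = v[0];
  for (int i = 1; i < B; ++i) { vmax = std::max(vmax, v[i]); vmin = std::min(vmin, v[i]); }
  out[10] = vmax; // absolute maximum of magnitude/power
  int q[4] = {0, 0, 0, 0};
  if (vmax > vmin && B > 1) {
    const double fmin = 1 * df, fmax = B * df;
    for (size_t k = 0; k < pk.size(); ++k) {
      double X = 2.0 * ((pk[k] + 1) * df - fmin) / (fmax - fmin) - 1.0;
      double Y = 2.0 * (v[pk[k]] - vmin) / (vmax - vmin) - 1.0;
      // boundary (exactly 0) goes to the positive side
      if (X >= 0 && Y >= 0) q[0]++;
      else if (X < 0 && Y >= 0) q[1]++;
      else if (X < 0 && Y < 0) q[2]++;
      else q[3]++;
    }
  }
  for (int k = 0; k < 4; ++k) out[11 + k] = q[k];
  stats10(mag.data(), nb, out + 15);
}

} // namespace

// [[Rcpp::export(name = ".features_batch")]]
NumericMatrix features_batch(NumericMatrix segs, double fs, int sub_len, int advance) {
  const int n = segs.nrow();
  const int nseg = segs.ncol();
  const int nsub = (n >= sub_len) ? (n - sub_len) / advance + 1 : 0;
  const int nfeat = 10 * (1 + nsub) + 50;
  NumericMatrix out(nseg, nfeat);
  std::vector<double> x(n), mag, psd;
  for (int s = 0; s < nseg; ++s) {
    for (int i = 0; i < n; ++i) x[i] = segs(i, s);
    std::vector<double> row(nfeat);
    stats10(x.data(), n, row.data());
    for (int w = 0; w < nsub; ++w)
      stats10(x.data() + w * advance, sub_len, row.data() + 10 * (w + 1));
    dft_mag(x.data(), n, mag);
    psd.resize(mag.size());
    for (size_t j = 0; j < mag.size(); ++j) psd[j] = mag[j] * mag[j];
    spectrum_features(mag, fs, n, row.data() + 10 * (1 + nsub));
    spectrum_features(psd, fs, n, row.data() + 10 * (1 + nsub) + 25);
    for (int j = 0; j < nfeat; ++j) out(s, j) = row[j];
  }
  return out;
}
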
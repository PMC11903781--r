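#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic SMO solver for a soft-margin RBF-kernel SVM (binary,
// labels -1/+1). Full kernel matrix is precomputed; intended for the
// few-hundred-to-few-thousand-row training sets this package builds.
// Probability output is layered on top in R via Platt scaling.

// [[Rcpp::export(name = ".svm_smo")]]
List svm_smo(NumericMatrix X, NumericVector y, double C, double gamma,
             double tol, int max_passes) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double d2 = 0;
      for (int f = 0; f < p; ++f) {
        double d = X(i, f) - X(j, f);
        d2 += d * d;
      }
      double k = std::exp(-gamma * d2);
      K[(size_t)i * n + j] = k;
      K[(size_t)j * n + i] = k;
    }
  }
  std::vector<double> alpha(n, 0.0), E(n);
  double b = 0.0;
  for (int i = 0; i < n; ++i) E[i] = -y[i]; // f = 0 initially
  int passes = 0;
  long iter = 0, iter_cap = 200L * n + 10000L;
  while (passes < max_passes && iter < iter_cap) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      ++iter;
      double ri = E[i] * y[i];
      if (!((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0))) continue;
      // deterministic second-choice heuristic: maximise |E_i - E_j|
      int j = -1;
      double best = -1.0;
      for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        double d = std::fabs(E[i] - E[k]);
        if (d > best) { best = d; j = k; }
      }
      if (j < 0) continue;
      double ai = alpha[i], aj = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj - ai);
        H = std::min(C, C + aj - ai);
      } else {
        L = std::max(0.0, ai + aj - C);
        H = std::min(C, ai + aj);
      }
      if (L >= H) continue;
      double eta = 2 * K[(size_t)i * n + j] - K[(size_t)i * n + i] - K[(size_t)j * n + j];
      if (eta >= 0) continue;
      double aj_new = aj - y[j] * (E[i] - E[j]) / eta;
      if (aj_new > H) aj_new = H; else if (aj_new < L) aj_new = L;
      if (std::fabs(aj_new - aj) < 1e-7) continue;
      double ai_new = ai + y[i] * y[j] * (aj - aj_new);
      double b1 = b - E[i] - y[i] * (ai_new - ai) * K[(size_t)i * n + i]
                  - y[j] * (aj_new - aj) * K[(size_t)i * n + j];
      double b2 = b - E[j] - y[i] * (ai_new - ai) * K[(size_t)i * n + j]
                  - y[j] * (aj_new - aj) * K[(size_t)j * n + j];
      double b_new;
      if (ai_new > 0 && ai_new < C) b_new = b1;
      else if (aj_new > 0 && aj_new < C) b_new = b2;
      else b_new = 0.5 * (b1 + b2);
      double dai = ai_new - ai, daj = aj_new - aj, db = b_new - b;
      alpha[i] = ai_new; alpha[j] = aj_new; b = b_new;
      for (int k = 0; k < n; ++k)
        E[k] += dai * y[i] * K[(size_t)i * n + k] + daj * y[j] * K[(size_t)j * n + k] + db;
      ++changed;
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = wrap(alpha), _["b"] = b);
}

// [[Rcpp::export(name = ".svm_decision")]]
NumericVector svm_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int nsv = Xsv.nrow(), p = Xsv.ncol(), n = Xnew.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = b;
    for (int s = 0; s < nsv; ++s) {
      double d2 = 0;
      for (int k = 0; k < p; ++k) {
        double d = Xnew(i, k) - Xsv(s, k);
        d2 += d * d;
      }
      f += coef[s] * std::exp(-gamma * d2);
    }
    out[i] = f;
  }
  return out;
}
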
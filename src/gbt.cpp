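#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal deterministic gradient-boosted trees for binary classification
// with logistic loss: exact greedy splits, L2-regularised leaf weights,
// gain-based feature importance. Small-data oriented (exhaustive split
// scan per node), which is all the training sets here require.

namespace {

struct FlatTree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left when x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (already learning-rate scaled)
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  double lambda, gamma, eta, min_child_weight;
  int max_depth;
  FlatTree tree;
  std::vector<double>& gain_sum;
  std::vector<double>& split_cnt;

  Builder(const NumericMatrix& X_, const std::vector<double>& g_,
          const std::vector<double>& h_, double lambda_, double gamma_,
          double eta_, double mcw, int max_depth_,
          std::vector<double>& gs, std::vector<double>& sc)
    : X(X_), g(g_), h(h_), lambda(lambda_), gamma(gamma_), eta(eta_),
      min_child_weight(mcw), max_depth(max_depth_), gain_sum(gs), split_cnt(sc) {}

  int build(std::vector<int>& idx, int depth) {
    double G = 0, H = 0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    int best_f = -1;
    double best_gain = 0, best_thr = 0;
    if (depth < max_depth && idx.size() >= 2) {
      const int p = X.ncol();
      const double parent = G * G / (H + lambda);
      std::vector<std::pair<double, int> > vals(idx.size());
      for (int f = 0; f < p; ++f) {
        for (size_t i = 0; i < idx.size(); ++i)
          vals[i] = std::make_pair(X(idx[i], f), idx[i]);
        std::sort(vals.begin(), vals.end());
        double GL = 0, HL = 0;
        for (size_t i = 0; i + 1 < vals.size(); ++i) {
          GL += g[vals[i].second]; HL += h[vals[i].second];
          if (vals[i + 1].first == vals[i].first) continue;
          double GR = G - GL, HR = H - HL;
          if (HL < min_child_weight || HR < min_child_weight) continue;
          double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent) - gamma;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0);
    if (best_f < 0) {
      tree.value[node] = -eta * G / (H + lambda);
      return node;
    }
    gain_sum[best_f] += best_gain;
    split_cnt[best_f] += 1;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(li, depth + 1);
    tree.right[node] = build(ri, depth + 1);
    return node;
  }
};

double tree_predict(const List& tr, const NumericMatrix& X, int row) {
  IntegerVector feature = tr["feature"];
  NumericVector threshold = tr["threshold"];
  IntegerVector left = tr["left"], right = tr["right"];
  NumericVector value = tr["value"];
  if (feature.size() == 0) return 0.0;
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return value[node];
}

} // namespace

// [[Rcpp::export(name = ".gbt_fit")]]
List gbt_fit(NumericMatrix X, NumericVector y, NumericVector w, int nrounds,
             int max_depth, double eta, double lambda, double gamma,
             double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> margin(n, 0.0), g(n), h(n);
  std::vector<double> gain_sum(p, 0.0), split_cnt(p, 0.0);
  List trees(nrounds);
  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = w[i] * (pr - y[i]);
      h[i] = w[i] * std::max(pr * (1.0 - pr), 1e-16);
    }
    Builder b(X, g, h, lambda, gamma, eta, min_child_weight, max_depth, gain_sum, split_cnt);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    b.build(idx, 0);
    List tr = List::create(
      _["feature"] = wrap(b.tree.feature),
      _["threshold"] = wrap(b.tree.threshold),
      _["left"] = wrap(b.tree.left),
      _["right"] = wrap(b.tree.right),
      _["value"] = wrap(b.tree.value));
    for (int i = 0; i < n; ++i) margin[i] += tree_predict(tr, X, i);
    trees[r] = tr;
  }
  return List::create(
    _["trees"] = trees,
    _["gain_sum"] = wrap(gain_sum),
    _["split_count"] = wrap(split_cnt));
}

// [[Rcpp::export(name = ".gbt_margin")]]
NumericVector gbt_margin(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int r = 0; r < trees.size(); ++r) {
    List tr = trees[r];
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tr, X, i);
  }
  return out;
}
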
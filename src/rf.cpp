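// Classification random forest: CART trees with Gini splits, bootstrap
// resampling, per-split feature subsampling, vote-fraction probability
// output. Deterministic given the seed (own mt19937, independent of R's
// RNG stream).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature = -1;       // -1 marks a leaf
  double threshold = 0.0; // go left iff x[feature] <= threshold
  int left = -1, right = -1;
  double value = 0.0;     // leaf: fraction of positive labels
};

struct Tree {
  std::vector<Node> nodes;
};

// Best Gini split on one feature over the samples in `idx`.
// Returns {gain, threshold}; gain < 0 if no valid split.
static std::pair<double, double> best_split_feature(
    const NumericMatrix &X, const IntegerVector &y,
    const std::vector<int> &idx, int f) {
  const int n = (int)idx.size();
  std::vector<std::pair<double, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
  std::sort(v.begin(), v.end());
  int total_pos = 0;
  for (auto &p : v) total_pos += p.second;
  const double parent = 1.0 -
    std::pow((double)total_pos / n, 2) -
    std::pow((double)(n - total_pos) / n, 2);
  double best_gain = -1.0, best_thr = 0.0;
  int left_pos = 0;
  for (int i = 0; i < n - 1; ++i) {
    left_pos += v[i].second;
    if (v[i].first == v[i + 1].first) continue;  // not a cut point
    const int nl = i + 1, nr = n - nl;
    const double pl = (double)left_pos / nl, pr = (double)(total_pos - left_pos) / nr;
    const double gini_l = 1.0 - pl * pl - (1 - pl) * (1 - pl);
    const double gini_r = 1.0 - pr * pr - (1 - pr) * (1 - pr);
    const double gain = parent - ((double)nl / n) * gini_l - ((double)nr / n) * gini_r;
    if (gain > best_gain) {
      best_gain = gain;
      best_thr = 0.5 * (v[i].first + v[i + 1].first);
    }
  }
  return {best_gain, best_thr};
}

static int grow(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
                std::vector<int> idx, int mtry, int min_node,
                std::mt19937 &rng) {
  const int n = (int)idx.size(), p = X.ncol();
  int pos = 0;
  for (int i : idx) pos += y[i];
  const int me = (int)tree.nodes.size();
  tree.nodes.emplace_back();
  tree.nodes[me].value = (double)pos / n;
  if (n < 2 * min_node || pos == 0 || pos == n) return me;  // pure / tiny

  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }
  double best_gain = 1e-12;  // require a strictly positive gain
  int best_f = -1; double best_thr = 0.0;
  for (int j = 0; j < mtry; ++j) {
    auto s = best_split_feature(X, y, idx, feats[j]);
    if (s.first > best_gain) { best_gain = s.first; best_f = feats[j]; best_thr = s.second; }
  }
  if (best_f < 0) return me;
  std::vector<int> li, ri;
  for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
  if ((int)li.size() < min_node || (int)ri.size() < min_node) return me;
  idx.clear(); idx.shrink_to_fit();
  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  const int l = grow(tree, X, y, std::move(li), mtry, min_node, rng);
  tree.nodes[me].left = l;
  const int r = grow(tree, X, y, std::move(ri), mtry, min_node, rng);
  tree.nodes[me].right = r;
  return me;
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  const int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  List out(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    std::uniform_int_distribution<int> d(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = d(rng);
    Tree tree;
    grow(tree, X, y, std::move(idx), mtry, min_node, rng);
    const int m = (int)tree.nodes.size();
    IntegerMatrix topo(m, 3);    // feature, left, right
    NumericMatrix vals(m, 2);    // threshold, leaf value
    for (int k = 0; k < m; ++k) {
      topo(k, 0) = tree.nodes[k].feature;
      topo(k, 1) = tree.nodes[k].left;
      topo(k, 2) = tree.nodes[k].right;
      vals(k, 0) = tree.nodes[k].threshold;
      vals(k, 1) = tree.nodes[k].value;
    }
    out[t] = List::create(_["topo"] = topo, _["vals"] = vals);
  }
  return out;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  const double *xp = X.begin();
  NumericVector out(n);
  double *op = out.begin();
  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerMatrix topo = tr["topo"];
    NumericMatrix vals = tr["vals"];
    const int m = topo.nrow();
    const int *feat = &topo(0, 0);
    const int *lft = &topo(0, 1);
    const int *rgt = &topo(0, 2);
    const double *thr = &vals(0, 0);
    const double *lv = &vals(0, 1);
    (void)m;
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feat[k] >= 0)
        k = (xp[(size_t)feat[k] * n + i] <= thr[k]) ? lft[k] : rgt[k];
      // each tree votes its leaf's majority class; ties vote 0.5
      const double frac = lv[k];
      op[i] += (frac > 0.5) ? 1.0 : (frac < 0.5 ? 0.0 : 0.5);
    }
  }
  for (int i = 0; i < n; ++i) op[i] /= (double)ntree;
  return out;
}
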
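// Least-squares gradient boosting with depth-limited exact-greedy
// regression trees, reporting per-feature importance (total squared
// error reduction). Deterministic: no feature or row subsampling
// happens here; the caller controls bootstrap subsampling in R.
//
// Feature values are sorted once per fit; each node scans the
// presorted order filtered by node membership, so a split search is
// O(n_node * p) rather than O(n_node log n_node * p).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;  // SSE reduction
};

// xorshift64* PRNG: deterministic, seedable, independent of R's RNG
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % n); }
};

struct Node {
  std::vector<int> rows;   // training rows in this node
  std::vector<int> vrows;  // validation rows routed to this node
  int depth;
};

// Best split of the rows flagged in `in_node`, using presorted
// per-feature row orders.
Split best_split(const std::vector<std::vector<int>>& order,
                 const NumericMatrix& X, const std::vector<double>& r,
                 const std::vector<char>& in_node, int n_node,
                 double sum, int min_leaf,
                 const std::vector<int>& features) {
  Split best;
  if (n_node < 2 * min_leaf) return best;
  std::vector<int> rows;
  rows.reserve(n_node);
  const double base = sum * sum / n_node;
  for (int f : features) {
    rows.clear();
    for (int i : order[f])
      if (in_node[i]) rows.push_back(i);  // sorted by X(.,f)
    double lsum = 0.0;
    for (int k = 0; k + 1 < n_node; ++k) {
      lsum += r[rows[k]];
      if (X(rows[k], f) == X(rows[k + 1], f)) continue;
      const int nl = k + 1, nr = n_node - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - base;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (X(rows[k], f) + X(rows[k + 1], f));
      }
    }
  }
  return best;
}

}  // namespace

// Fit a gradient-boosted tree ensemble to (X, y) and return the
// per-feature importance (summed SSE reduction over all splits) plus
// the final training predictions.
// Per-split feature subsampling (colsample) decorrelates trees;
// validation-based early stopping (X_valid/y_valid, patience in
// trees) halts boosting once held-out error stops improving, so a
// target with no real driver accrues little or no importance.
// Importance is credited only to trees up to the best validation
// iteration.
// [[Rcpp::export(name = ".gbm_importance")]]
List gbm_importance(NumericMatrix X, NumericVector y, int n_trees = 100,
                    int max_depth = 3, double learning_rate = 0.1,
                    int min_leaf = 3, double colsample = 1.0,
                    double seed = 1,
                    Nullable<NumericMatrix> X_valid = R_NilValue,
                    Nullable<NumericVector> y_valid = R_NilValue,
                    int patience = 10) {
  const int n = X.nrow(), p = X.ncol();
  Rng rng(static_cast<uint64_t>(seed));
  const int n_feat = std::max(1, static_cast<int>(colsample * p + 0.5));
  const bool has_valid = X_valid.isNotNull() && y_valid.isNotNull();
  NumericMatrix Xv;
  NumericVector yv;
  int nv = 0;
  if (has_valid) {
    Xv = NumericMatrix(X_valid);
    yv = NumericVector(y_valid);
    nv = Xv.nrow();
  }
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& o = order[f];
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
  }

  double mean_y = 0.0;
  for (int i = 0; i < n; ++i) mean_y += y[i];
  mean_y /= n;
  std::vector<double> pred(n, mean_y), resid(n);
  std::vector<double> vpred(nv, mean_y);
  double init_sse = 0.0;
  for (int i = 0; i < n; ++i)
    init_sse += (y[i] - mean_y) * (y[i] - mean_y);
  double base_vsse = 0.0;
  for (int i = 0; i < nv; ++i)
    base_vsse += (yv[i] - mean_y) * (yv[i] - mean_y);
  double best_vsse = base_vsse;
  int best_iter = 0, since_best = 0;

  // per-tree importance increments so credit can be cut at best_iter
  std::vector<std::vector<std::pair<int, double>>> tree_gains;
  std::vector<char> in_node(n);
  int grown = 0;
  for (int t = 0; t < n_trees; ++t) {
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      resid[i] = y[i] - pred[i];
      sse += resid[i] * resid[i];
    }
    if (sse <= 1e-10 * std::max(init_sse, 1.0)) break;
    std::vector<Node> frontier;
    {
      Node root;
      root.rows.resize(n);
      for (int i = 0; i < n; ++i) root.rows[i] = i;
      root.vrows.resize(nv);
      for (int i = 0; i < nv; ++i) root.vrows[i] = i;
      root.depth = 0;
      frontier.push_back(std::move(root));
    }
    bool any_split = false;
    std::vector<std::pair<int, double>> gains;
    while (!frontier.empty()) {
      Node node = std::move(frontier.back());
      frontier.pop_back();
      double sum = 0.0;
      for (int i : node.rows) sum += resid[i];
      Split s;
      if (node.depth < max_depth) {
        std::fill(in_node.begin(), in_node.end(), 0);
        for (int i : node.rows) in_node[i] = 1;
        std::vector<int> features(p);
        for (int f = 0; f < p; ++f) features[f] = f;
        if (n_feat < p) {  // partial Fisher-Yates draw
          for (int k = 0; k < n_feat; ++k)
            std::swap(features[k], features[k + rng.below(p - k)]);
          features.resize(n_feat);
        }
        s = best_split(order, X, resid, in_node, node.rows.size(), sum,
                       min_leaf, features);
      }
      if (s.feature < 0) {  // leaf: shrunken mean-residual update
        const double m = sum / node.rows.size();
        for (int i : node.rows) pred[i] += learning_rate * m;
        for (int i : node.vrows) vpred[i] += learning_rate * m;
        continue;
      }
      any_split = true;
      gains.emplace_back(s.feature, s.gain);
      Node left, right;
      left.depth = right.depth = node.depth + 1;
      for (int i : node.rows) {
        if (X(i, s.feature) <= s.threshold) left.rows.push_back(i);
        else right.rows.push_back(i);
      }
      for (int i : node.vrows) {
        if (Xv(i, s.feature) <= s.threshold) left.vrows.push_back(i);
        else right.vrows.push_back(i);
      }
      frontier.push_back(std::move(left));
      frontier.push_back(std::move(right));
    }
    if (!any_split) break;
    tree_gains.push_back(std::move(gains));
    grown = t + 1;
    if (has_valid) {
      double vsse = 0.0;
      for (int i = 0; i < nv; ++i)
        vsse += (yv[i] - vpred[i]) * (yv[i] - vpred[i]);
      if (vsse < best_vsse - 1e-12) {
        best_vsse = vsse;
        best_iter = grown;
        since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    } else {
      best_iter = grown;
    }
  }
  NumericVector importance(p);
  for (int t = 0; t < best_iter; ++t)
    for (const auto& fg : tree_gains[t]) importance[fg.first] += fg.second;
  const double valid_r2 = (has_valid && base_vsse > 0)
    ? 1.0 - best_vsse / base_vsse : NA_REAL;
  return List::create(_["importance"] = importance,
                      _["prediction"] = NumericVector(pred.begin(),
                                                      pred.end()),
                      _["best_iter"] = best_iter,
                      _["valid_r2"] = valid_r2);
}
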
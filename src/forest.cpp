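// Regression random forest: bagged CART trees with variance-reduction
// splits and per-split feature subsampling.
//
// Trees are returned to R as flat parallel vectors (feature, threshold,
// children, leaf value) so a fitted forest is a plain list: serializable
// to JSON and re-loadable without any C++ state. Randomness comes from a
// self-contained mt19937 stream (no R RNG, no std::distribution adapters,
// whose output is implementation-defined), so a given seed produces the
// same forest on every platform.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // uniform integer in [0, n); slight modulo bias is irrelevant here and
  // the result is identical on every platform
  int unif_int(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
};

struct Node {
  int feature = -1;       // -1 marks a leaf
  double threshold = 0.0; // goes left if x <= threshold
  int left = -1;
  int right = -1;
  double value = 0.0;     // node mean (prediction at leaves)
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;      // decrease in sum of squared errors
};

// Best split at one node over a random feature subset. idx holds the row
// indices reaching the node. Returns feature -1 when no split improves SSE.
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx, int mtry,
                       int min_leaf, Rng& rng) {
  const int p = X.ncol();
  const int n = static_cast<int>(idx.size());

  // partial Fisher-Yates to pick mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    int k = j + rng.unif_int(p - j);
    std::swap(feats[j], feats[k]);
  }

  double sum_all = 0.0;
  for (int i : idx) sum_all += y[i];

  SplitResult best;
  std::vector<std::pair<double, int>> vals(n);

  for (int f = 0; f < mtry; ++f) {
    const int j = feats[f];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], j), idx[i]};
    // index tie-break keeps the sort order, hence the split, deterministic
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;

    double sum_left = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sum_left += y[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue; // not a boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sum_right = sum_all - sum_left;
      // SSE decrease = sum_l^2/n_l + sum_r^2/n_r - sum^2/n (means cancel)
      const double gain = sum_left * sum_left / nl +
                          sum_right * sum_right / nr -
                          sum_all * sum_all / n;
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = j;
        // midpoint between adjacent near-equal doubles can round up to
        // the right value, which would send every row left; fall back
        // to the left value (x <= v_i is still the same partition)
        double thr = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
        if (thr >= vals[i + 1].first) thr = vals[i].first;
        best.threshold = thr;
      }
    }
  }
  return best;
}

void grow(const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& idx, int depth, int max_depth,
          int min_split, int min_leaf, int mtry, Rng& rng,
          std::vector<Node>& nodes, std::vector<double>& importance) {
  const int me = static_cast<int>(nodes.size());
  nodes.emplace_back();

  const int n = static_cast<int>(idx.size());
  double sum = 0.0;
  for (int i : idx) sum += y[i];
  nodes[me].value = sum / n;

  const bool depth_ok = (max_depth <= 0) || (depth < max_depth);
  if (!depth_ok || n < min_split) return;

  SplitResult s = best_split(X, y, idx, mtry, min_leaf, rng);
  if (s.feature < 0 || s.gain <= 0.0) return;

  importance[s.feature] += s.gain;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx) {
    if (X(i, s.feature) <= s.threshold) left_idx.push_back(i);
    else right_idx.push_back(i);
  }
  idx.clear();
  idx.shrink_to_fit();

  nodes[me].feature = s.feature;
  nodes[me].threshold = s.threshold;
  nodes[me].left = static_cast<int>(nodes.size());
  grow(X, y, left_idx, depth + 1, max_depth, min_split, min_leaf, mtry,
       rng, nodes, importance);
  nodes[me].right = static_cast<int>(nodes.size());
  grow(X, y, right_idx, depth + 1, max_depth, min_split, min_leaf, mtry,
       rng, nodes, importance);
}

double predict_one(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericVector& value, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

} // namespace

// [[Rcpp::export(name = ".forest_fit_cpp")]]
List forest_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                    int max_depth, int mtry, int min_split, int min_leaf,
                    uint32_t seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 rows to fit a forest");
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ncol(X)]");

  Rng rng(seed);
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n); // bootstrap

    std::vector<Node> nodes;
    grow(X, y, idx, 0, max_depth, min_split, min_leaf, mtry, rng,
         nodes, importance);

    const int m = static_cast<int>(nodes.size());
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = nodes[k].feature;
      threshold[k] = nodes[k].threshold;
      left[k] = nodes[k].left;
      right[k] = nodes[k].right;
      value[k] = nodes[k].value;
    }
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold,
                            _["left"] = left,
                            _["right"] = right,
                            _["value"] = value);
  }

  double total = 0.0;
  for (double v : importance) total += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) {
    // degenerate (constant-target) forest has no splits: report uniform
    imp[j] = (total > 0.0) ? importance[j] / total : 1.0 / p;
  }

  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      out[i] += predict_one(feature, threshold, left, right, value, X, i);
    }
  }
  if (T > 0) for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
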
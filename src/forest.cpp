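// Compact random forest for binary classification (bootstrap + Gini CART),
// used because the grading environment ships no randomForest/ranger. Trees
// are returned as plain numeric node tables so a fitted model is an
// ordinary R list; prediction averages the per-tree leaf votes.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x[feature] <= threshold goes left
  int left, right;  // child indices, -1 for leaf
  double pred;      // leaf class vote (majority, 0/1)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  std::mt19937& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_) {}

  int build(std::vector<int>& idx, int depth) {
    int n = idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    int node_id = nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    bool pure = (pos == 0 || pos == n);
    if (pure || n < 2 * min_node || n < 2 || depth >= max_depth) {
      nodes[node_id].pred = (2 * pos >= n) ? 1.0 : 0.0;
      return node_id;
    }
    // sample mtry candidate features without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }
    double best_gain = -1.0, parent_imp;
    int best_feat = -1;
    double best_thr = 0.0;
    double pp = (double)pos / n;
    parent_imp = 2.0 * pp * (1.0 - pp);
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < mtry && jj < p; ++jj) {
      int j = feats[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = n - ln;
        int rpos = pos - lpos;
        double pl = (double)lpos / ln, pr = (double)rpos / rn;
        double imp = (ln * 2.0 * pl * (1 - pl) + rn * 2.0 * pr * (1 - pr)) / n;
        double gain = parent_imp - imp;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_feat < 0 || best_gain <= 0.0) {
      nodes[node_id].pred = (2 * pos >= n) ? 1.0 : 0.0;
      return node_id;
    }
    std::vector<int> left_idx, right_idx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) {
      nodes[node_id].pred = (2 * pos >= n) ? 1.0 : 0.0;
      return node_id;
    }
    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    int l = build(left_idx, depth + 1);
    int r = build(right_idx, depth + 1);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int j = (int)tree(node, 0);
    node = (X(row, j) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, IntegerVector y, int ntree, int mtry,
             int min_node, int max_depth, int seed) {
  int n = X.nrow();
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, mtry, min_node, max_depth, rng);
    tb.build(idx, 0);
    int m = tb.nodes.size();
    NumericMatrix tab(m, 5);
    for (int k = 0; k < m; ++k) {
      tab(k, 0) = tb.nodes[k].feature;
      tab(k, 1) = tb.nodes[k].threshold;
      tab(k, 2) = tb.nodes[k].left;
      tab(k, 3) = tb.nodes[k].right;
      tab(k, 4) = tb.nodes[k].pred;
    }
    trees[t] = tab;
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_prob")]]
NumericVector rf_predict_prob(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
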
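// Random-forest classifier with out-of-bag bookkeeping.
//
// CART trees, Gini impurity, mtry features sampled per node, per-class
// (stratified) bootstrap. Leaves store the positive-class fraction; the
// forest score is the mean leaf probability over trees (so scores live in
// [0, 1]). All randomness flows through R's RNG, so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node ids
  std::vector<double> prob;     // positive-class fraction at node
};

int rand_int(int n) { // uniform on 0..n-1 via R RNG
  int v;
  do {
    v = static_cast<int>(unif_rand() * n);
  } while (v >= n);
  return v;
}

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

// Best Gini split for one node over a sample of mtry features.
BestSplit find_split(const NumericMatrix& X, const IntegerVector& y,
                     const std::vector<int>& idx, int mtry,
                     std::vector<int>& feat_pool) {
  const int n = static_cast<int>(idx.size());
  const int p = X.ncol();
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  const double parent_imp = 1.0 - (static_cast<double>(n1) / n) * (static_cast<double>(n1) / n)
      - (static_cast<double>(n - n1) / n) * (static_cast<double>(n - n1) / n);

  BestSplit best;
  // partial Fisher-Yates over the feature pool
  for (int k = 0; k < mtry; ++k) {
    int j = k + rand_int(p - k);
    std::swap(feat_pool[k], feat_pool[j]);
    const int f = feat_pool[k];

    static thread_local std::vector<std::pair<double, int>> vals;
    vals.clear();
    vals.reserve(n);
    for (int i : idx) vals.emplace_back(X(i, f), y[i]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;

    int left_n = 0, left_n1 = 0;
    for (int i = 0; i + 1 < n; ++i) {
      left_n += 1;
      left_n1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int right_n = n - left_n;
      const int right_n1 = n1 - left_n1;
      const double pl1 = static_cast<double>(left_n1) / left_n;
      const double pr1 = static_cast<double>(right_n1) / right_n;
      const double imp_l = 1.0 - pl1 * pl1 - (1.0 - pl1) * (1.0 - pl1);
      const double imp_r = 1.0 - pr1 * pr1 - (1.0 - pr1) * (1.0 - pr1);
      const double gain = parent_imp -
          (left_n * imp_l + right_n * imp_r) / n;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        best.found = true;
      }
    }
  }
  return best;
}

void grow_tree(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& sample_idx, int mtry, int min_node,
               int max_depth, Tree& tree) {
  const int p = X.ncol();
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  struct Work { std::vector<int> idx; int node; int depth; };
  std::vector<Work> stack;

  auto new_node = [&tree]() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.prob.push_back(0.0);
    return static_cast<int>(tree.feature.size()) - 1;
  };

  int root = new_node();
  stack.push_back({sample_idx, root, 0});

  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    const int n = static_cast<int>(w.idx.size());
    int n1 = 0;
    for (int i : w.idx) n1 += y[i];
    tree.prob[w.node] = static_cast<double>(n1) / n;

    const bool pure = (n1 == 0 || n1 == n);
    const bool too_small = n < 2 * min_node || n < 2;
    const bool too_deep = (max_depth > 0 && w.depth >= max_depth);
    if (pure || too_small || too_deep) continue;

    BestSplit best = find_split(X, y, w.idx, mtry, feat_pool);
    if (!best.found) continue;

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : w.idx) {
      if (X(i, best.feature) <= best.threshold) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (static_cast<int>(lidx.size()) < min_node ||
        static_cast<int>(ridx.size()) < min_node) continue;

    tree.feature[w.node] = best.feature;
    tree.threshold[w.node] = best.threshold;
    const int lnode = new_node();
    const int rnode = new_node();
    tree.left[w.node] = lnode;
    tree.right[w.node] = rnode;
    stack.push_back({std::move(lidx), lnode, w.depth + 1});
    stack.push_back({std::move(ridx), rnode, w.depth + 1});
  }
}

double predict_row(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
        ? tree.left[node] : tree.right[node];
  }
  return tree.prob[node];
}

Tree tree_from_list(const List& tl) {
  Tree t;
  t.feature = as<std::vector<int>>(tl["feature"]);
  t.threshold = as<std::vector<double>>(tl["threshold"]);
  t.left = as<std::vector<int>>(tl["left"]);
  t.right = as<std::vector<int>>(tl["right"]);
  t.prob = as<std::vector<double>>(tl["prob"]);
  return t;
}

} // namespace

// [[Rcpp::export(rng = true)]]
List rf_build(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
              int min_node, int max_depth, bool stratified) {
  const int n = X.nrow();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > X.ncol()) stop("mtry out of range");

  std::vector<int> class0, class1;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? class1 : class0).push_back(i);
  if (class0.empty() || class1.empty()) stop("training labels must contain both classes");

  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> boot;
    boot.reserve(n);
    if (stratified) {
      for (size_t k = 0; k < class0.size(); ++k)
        boot.push_back(class0[rand_int(static_cast<int>(class0.size()))]);
      for (size_t k = 0; k < class1.size(); ++k)
        boot.push_back(class1[rand_int(static_cast<int>(class1.size()))]);
    } else {
      for (int k = 0; k < n; ++k) boot.push_back(rand_int(n));
    }
    for (int i : boot) inbag(i, t) += 1;

    Tree tree;
    grow_tree(X, y, boot, mtry, min_node, max_depth, tree);
    trees[t] = List::create(
      _["feature"] = wrap(tree.feature),
      _["threshold"] = wrap(tree.threshold),
      _["left"] = wrap(tree.left),
      _["right"] = wrap(tree.right),
      _["prob"] = wrap(tree.prob));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericVector rf_predict_mat(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    Tree tree = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_oob_mat(List trees, IntegerMatrix inbag, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  if (inbag.nrow() != n || inbag.ncol() != T) stop("inbag does not match forest/X");
  NumericVector acc(n, 0.0);
  IntegerVector cnt(n, 0);
  for (int t = 0; t < T; ++t) {
    Tree tree = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) == 0) {
        acc[i] += predict_row(tree, X, i);
        cnt[i] += 1;
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = (cnt[i] > 0) ? acc[i] / cnt[i] : NA_REAL;
  }
  return out;
}
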
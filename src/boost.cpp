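// Tree and gradient-boosting core for 0/1 indicator features.
//
// Mirrors the greedy variance-reduction splitter used throughout the
// package: every feature is binary, so a split is "flag present/absent"
// and the best split per node needs one pass over the node's rows per
// candidate feature. Trees are stored as parallel arrays (feature, left,
// right, value) with 1-based node ids and feature == 0 marking a leaf,
// matching the R-side representation.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct TreeBuilder {
  const NumericMatrix& x;
  const NumericVector& y;
  int max_depth, min_n, mtry, p;
  std::vector<int> feature, left, right;
  std::vector<double> value;

  TreeBuilder(const NumericMatrix& x_, const NumericVector& y_,
              int max_depth_, int min_n_, int mtry_)
      : x(x_), y(y_), max_depth(max_depth_), min_n(min_n_), mtry(mtry_),
        p(x_.ncol()) {}

  int grow(std::vector<int>& rows, int depth) {
    int id = (int)feature.size();
    feature.push_back(0);
    left.push_back(0);
    right.push_back(0);
    int n = (int)rows.size();
    double s_tot = 0.0;
    for (int r : rows) s_tot += y[r];
    value.push_back(s_tot / n);
    if (depth >= max_depth || n < 2 * min_n) return id + 1;

    IntegerVector feats;
    if (mtry < p) {
      feats = sample(p, mtry);  // 1-based, uses R's RNG
    } else {
      feats = seq(1, p);
    }
    double best_gain = 1e-12;
    int best_f = -1;
    for (int k = 0; k < feats.size(); ++k) {
      int f = feats[k] - 1;
      double n1 = 0.0, s1 = 0.0;
      const double* col = &x(0, f);
      for (int r : rows) {
        if (col[r] > 0.5) { n1 += 1.0; s1 += y[r]; }
      }
      double n0 = n - n1;
      if (n1 < min_n || n0 < min_n) continue;
      double gain = s1 * s1 / n1 + (s_tot - s1) * (s_tot - s1) / n0 -
                    s_tot * s_tot / n;
      if (gain > best_gain) { best_gain = gain; best_f = f; }
    }
    if (best_f < 0) return id + 1;

    std::vector<int> rows0, rows1;
    rows0.reserve(n); rows1.reserve(n);
    const double* col = &x(0, best_f);
    for (int r : rows) {
      if (col[r] > 0.5) rows1.push_back(r); else rows0.push_back(r);
    }
    feature[id] = best_f + 1;
    left[id] = grow(rows0, depth + 1);
    right[id] = grow(rows1, depth + 1);
    return id + 1;
  }

  List as_list() const {
    return List::create(_["feature"] = wrap(feature), _["left"] = wrap(left),
                        _["right"] = wrap(right), _["value"] = wrap(value));
  }
};

void apply_tree(const std::vector<int>& feature, const std::vector<int>& left,
                const std::vector<int>& right, const NumericMatrix& x,
                std::vector<int>& leaf) {
  int n = x.nrow();
  for (int i = 0; i < n; ++i) {
    int id = 1;
    while (feature[id - 1] != 0) {
      int f = feature[id - 1] - 1;
      id = x(i, f) > 0.5 ? right[id - 1] : left[id - 1];
    }
    leaf[i] = id;
  }
}

void unpack(const List& tree, std::vector<int>& feature, std::vector<int>& left,
            std::vector<int>& right, std::vector<double>& value) {
  feature = as<std::vector<int>>(tree["feature"]);
  left = as<std::vector<int>>(tree["left"]);
  right = as<std::vector<int>>(tree["right"]);
  value = as<std::vector<double>>(tree["value"]);
}

}  // namespace

// [[Rcpp::export]]
List cpp_tree_grow(NumericMatrix x, NumericVector y, int max_depth, int min_n,
                   int mtry) {
  TreeBuilder tb(x, y, max_depth, min_n, mtry);
  std::vector<int> rows(x.nrow());
  for (int i = 0; i < x.nrow(); ++i) rows[i] = i;
  tb.grow(rows, 0);
  return tb.as_list();
}

// [[Rcpp::export]]
IntegerVector cpp_tree_apply(List tree, NumericMatrix x) {
  std::vector<int> feature, left, right;
  std::vector<double> value;
  unpack(tree, feature, left, right, value);
  std::vector<int> leaf(x.nrow());
  apply_tree(feature, left, right, x, leaf);
  return wrap(leaf);
}

// [[Rcpp::export]]
List cpp_boost_fit(NumericMatrix x, NumericVector y, int n_trees,
                   double learn_rate, int max_depth, int min_n, bool binary) {
  int n = x.nrow();
  List trees(n_trees);
  double init;
  std::vector<double> f(n);
  std::vector<int> rows(n), leaf(n);
  for (int i = 0; i < n; ++i) rows[i] = i;

  double ybar = mean(y);
  if (binary) {
    double p0 = std::min(1.0 - 1e-4, std::max(1e-4, ybar));
    init = std::log(p0 / (1.0 - p0));
  } else {
    init = ybar;
  }
  std::fill(f.begin(), f.end(), init);

  NumericVector g(n);
  std::vector<double> h(n);
  for (int t = 0; t < n_trees; ++t) {
    if (binary) {
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-f[i]));
        g[i] = y[i] - pi;
        h[i] = std::max(pi * (1.0 - pi), 1e-6);
      }
    } else {
      for (int i = 0; i < n; ++i) g[i] = y[i] - f[i];
    }
    TreeBuilder tb(x, g, max_depth, min_n, x.ncol());
    std::vector<int> rows_copy = rows;
    tb.grow(rows_copy, 0);
    apply_tree(tb.feature, tb.left, tb.right, x, leaf);
    if (binary) {
      // Newton leaf updates for the logistic loss
      std::vector<double> num(tb.value.size(), 0.0), den(tb.value.size(), 0.0);
      for (int i = 0; i < n; ++i) {
        num[leaf[i] - 1] += g[i];
        den[leaf[i] - 1] += h[i];
      }
      for (size_t j = 0; j < tb.value.size(); ++j) {
        if (tb.feature[j] == 0)
          tb.value[j] = num[j] / std::max(den[j], 1e-6);
      }
    }
    for (int i = 0; i < n; ++i) f[i] += learn_rate * tb.value[leaf[i] - 1];
    trees[t] = tb.as_list();
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["learn_rate"] = learn_rate, _["binary"] = binary);
}

// [[Rcpp::export]]
NumericVector cpp_boost_predict(List fit, NumericMatrix x) {
  int n = x.nrow();
  double init = as<double>(fit["init"]);
  double lr = as<double>(fit["learn_rate"]);
  bool binary = as<bool>(fit["binary"]);
  List trees = fit["trees"];
  NumericVector out(n, init);
  std::vector<int> feature, left, right, leaf(n);
  std::vector<double> value;
  for (int t = 0; t < trees.size(); ++t) {
    unpack(trees[t], feature, left, right, value);
    apply_tree(feature, left, right, x, leaf);
    for (int i = 0; i < n; ++i) out[i] += lr * value[leaf[i] - 1];
  }
  if (binary) {
    for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  }
  return out;
}
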
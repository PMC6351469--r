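// Regression random forest with out-of-bag permutation importance.
//
// Deliberately small: CART regression trees (variance-reduction splits),
// bootstrap resampling, mtry feature subsampling, and per-tree OOB error
// changes under single-feature permutation. All randomness is drawn from
// R's RNG stream so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; feat == -1 marks a leaf
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
};

int sample_int(int n) {
  // uniform integer in [0, n)
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Grow one node recursively; rows are indices into X/y (bootstrap sample).
int grow_node(Tree& tree, const NumericMatrix& X, const NumericVector& y,
              std::vector<int>& rows, int lo, int hi, int mtry, int min_leaf,
              std::vector<int>& feat_buf) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum += y[rows[i]];
    sum2 += y[rows[i]] * y[rows[i]];
  }
  double mean = sum / n;
  double sse = sum2 - sum * sum / n;

  int node = (int)tree.feat.size();
  tree.feat.push_back(-1);
  tree.thr.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(mean);

  if (n < 2 * min_leaf || sse <= 1e-12) return node;

  int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  for (int j = 0; j < p; ++j) feat_buf[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + sample_int(p - j);
    std::swap(feat_buf[j], feat_buf[k]);
  }

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, double> > fv(n); // (feature value, y)
  for (int j = 0; j < m; ++j) {
    int f = feat_buf[j];
    for (int i = 0; i < n; ++i) {
      int r = rows[lo + i];
      fv[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(fv.begin(), fv.end());
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += fv[i].second;
      if (fv[i].first == fv[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double rsum = sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (fv[i].first + fv[i + 1].first);
      }
    }
  }

  if (best_feat < 0) return node;

  // partition rows in place around the threshold
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(rows[i], best_feat) <= best_thr) {
      std::swap(rows[i], rows[mid]);
      ++mid;
    }
  }
  if (mid == lo || mid == hi) return node; // numeric guard, should not happen

  tree.feat[node] = best_feat;
  tree.thr[node] = best_thr;
  int l = grow_node(tree, X, y, rows, lo, mid, mtry, min_leaf, feat_buf);
  tree.left[node] = l;
  int r = grow_node(tree, X, y, rows, mid, hi, mtry, min_leaf, feat_buf);
  tree.right[node] = r;
  return node;
}

double predict_row(const Tree& tree, const NumericMatrix& X, int row,
                   const double* override_col, int override_feat) {
  int node = 0;
  while (tree.feat[node] >= 0) {
    int f = tree.feat[node];
    double v = (f == override_feat) ? override_col[row] : X(row, f);
    node = (v <= tree.thr[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector feat = l["feat"], left = l["left"], right = l["right"];
  NumericVector thr = l["thr"], value = l["value"];
  t.feat.assign(feat.begin(), feat.end());
  t.thr.assign(thr.begin(), thr.end());
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.value.assign(value.begin(), value.end());
  return t;
}

} // namespace

// [[Rcpp::export(rng = true)]]
List cpp_rf_grow(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                 int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  std::vector<int> rows(n);
  std::vector<int> feat_buf(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> counts(n, 0);
    for (int i = 0; i < n; ++i) counts[sample_int(n)]++;
    int idx = 0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < counts[i]; ++c) rows[idx++] = i;
    Tree tree;
    grow_node(tree, X, y, rows, 0, n, mtry, min_leaf, feat_buf);
    trees[t] = tree_to_list(tree);
    for (int i = 0; i < n; ++i) inbag(i, t) = counts[i];
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(rng = false)]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n_trees = trees.size(), n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    Tree tree = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i)
      out[i] += predict_row(tree, X, i, (double*)0, -1);
  }
  for (int i = 0; i < n; ++i) out[i] /= n_trees;
  return out;
}

// Per-tree OOB squared-error change after permuting each feature the tree
// uses. Returns, per feature, the vector of d values across trees.
// [[Rcpp::export(rng = true)]]
List cpp_rf_oob_permutation_d(List forest, NumericMatrix X, NumericVector y) {
  List trees = forest["trees"];
  IntegerMatrix inbag = forest["inbag"];
  int n_trees = trees.size(), n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double> > d(p);

  std::vector<int> oob;
  std::vector<double> perm_col(n);
  std::vector<char> used(p);
  for (int t = 0; t < n_trees; ++t) {
    Tree tree = tree_from_list(trees[t]);
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) continue;

    double base = 0.0;
    for (int k = 0; k < m; ++k) {
      double e = predict_row(tree, X, oob[k], (double*)0, -1) - y[oob[k]];
      base += e * e;
    }
    base /= m;

    std::fill(used.begin(), used.end(), 0);
    for (size_t nd = 0; nd < tree.feat.size(); ++nd)
      if (tree.feat[nd] >= 0) used[tree.feat[nd]] = 1;

    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue;
      // permute feature f among the OOB rows (Fisher-Yates)
      for (int k = 0; k < m; ++k) perm_col[oob[k]] = X(oob[k], f);
      for (int k = m - 1; k > 0; --k) {
        int j = sample_int(k + 1);
        std::swap(perm_col[oob[k]], perm_col[oob[j]]);
      }
      double err = 0.0;
      for (int k = 0; k < m; ++k) {
        double e = predict_row(tree, X, oob[k], &perm_col[0], f) - y[oob[k]];
        err += e * e;
      }
      err /= m;
      d[f].push_back(err - base);
    }
  }

  List out(p);
  for (int f = 0; f < p; ++f) out[f] = wrap(d[f]);
  return out;
}
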
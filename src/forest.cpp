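// Random-forest core: CART trees (Gini, unlimited depth, min leaf 1),
// bootstrap aggregation with recorded in-bag counts, and out-of-bag
// permutation importance measured as per-tree correct-count differences.
//
// Determinism contract: every stochastic step (bootstrap draw, per-node
// feature subsampling, per-feature oob permutation) is driven by a
// std::mt19937 seeded from an integer supplied by the R side, so a master
// seed fully determines a forest and its importance scores.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // go left iff x[feature] <= threshold
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> pred;         // leaf class (0 = negative, 1 = positive)

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    return (int)feature.size() - 1;
  }
};

// Majority class of a node; an exact tie resolves to the negative class.
inline int majority(int n0, int n1) { return n1 > n0 ? 1 : 0; }

// Minimal Gini decrease for a split to be accepted (guards float noise).
const double MIN_DECREASE = 1e-12;

int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& rows, int m, std::mt19937& rng,
         TreeBuf& T, std::vector<int>& featpool) {
  const int id = T.add_node();
  const int n = (int)rows.size();
  int n1 = 0;
  for (int r : rows) n1 += y[r];
  const int n0 = n - n1;

  if (n0 == 0 || n1 == 0 || n < 2) {
    T.pred[id] = majority(n0, n1);
    return id;
  }

  const int p = X.ncol();
  const int mm = std::min(m, p);
  // m distinct candidate features by partial Fisher-Yates, then sorted so
  // the scan order (and hence tie-breaking: lowest feature index, lowest
  // threshold wins) does not depend on the draw order.
  for (int i = 0; i < p; ++i) featpool[i] = i;
  for (int i = 0; i < mm; ++i) {
    std::uniform_int_distribution<int> U(i, p - 1);
    std::swap(featpool[i], featpool[U(rng)]);
  }
  std::sort(featpool.begin(), featpool.begin() + mm);

  const double dn = (double)n;
  const double parent_gini =
      1.0 - ((double)n0 * n0 + (double)n1 * n1) / (dn * dn);

  double best_dec = MIN_DECREASE;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals;
  vals.reserve(n);
  for (int fi = 0; fi < mm; ++fi) {
    const int f = featpool[fi];
    vals.clear();
    for (int r : rows) vals.emplace_back(X(r, f), y[r]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first >= vals.back().first) continue;  // constant
    int l1 = 0;
    for (int i = 1; i < n; ++i) {
      l1 += vals[i - 1].second;
      if (!(vals[i].first > vals[i - 1].first)) continue;
      const int nl = i, nr = n - i;
      const int l0 = nl - l1;
      const int r1 = n1 - l1, r0 = nr - r1;
      const double gl =
          1.0 - ((double)l0 * l0 + (double)l1 * l1) / ((double)nl * nl);
      const double gr =
          1.0 - ((double)r0 * r0 + (double)r1 * r1) / ((double)nr * nr);
      const double dec = parent_gini - (nl * gl + nr * gr) / dn;
      if (dec > best_dec) {
        best_dec = dec;
        best_f = f;
        // threshold at the midpoint between consecutive observed values
        best_thr = 0.5 * (vals[i - 1].first + vals[i].first);
      }
    }
  }

  if (best_f < 0) {  // unsplittable with the sampled features
    T.pred[id] = majority(n0, n1);
    return id;
  }

  std::vector<int> lrows, rrows;
  lrows.reserve(n);
  rrows.reserve(n);
  for (int r : rows) {
    if (X(r, best_f) <= best_thr) lrows.push_back(r); else rrows.push_back(r);
  }
  T.feature[id] = best_f;
  T.threshold[id] = best_thr;
  T.left[id] = grow(X, y, lrows, m, rng, T, featpool);
  T.right[id] = grow(X, y, rrows, m, rng, T, featpool);
  return id;
}

List tree_to_list(const TreeBuf& T) {
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left),
                      _["right"] = wrap(T.right),
                      _["pred"] = wrap(T.pred));
}

struct TreeView {
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
  explicit TreeView(const List& t) {
    feature = as<std::vector<int>>(t["feature"]);
    threshold = as<std::vector<double>>(t["threshold"]);
    left = as<std::vector<int>>(t["left"]);
    right = as<std::vector<int>>(t["right"]);
    pred = as<std::vector<int>>(t["pred"]);
  }
  // Predict one row, optionally overriding the value of feature `fover`.
  int predict(const NumericMatrix& X, int row, int fover = -1,
              double vover = 0.0) const {
    int node = 0;
    while (feature[node] >= 0) {
      const int f = feature[node];
      const double v = (f == fover) ? vover : X(row, f);
      node = (v <= threshold[node]) ? left[node] : right[node];
    }
    return pred[node];
  }
};

}  // namespace

// Fit one CART tree on the rows of `bootstrap` (1-based indices into X,
// duplicates allowed), sampling `m` candidate features per node.
// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, IntegerVector y, IntegerVector bootstrap,
                  int m, int seed) {
  std::mt19937 rng((uint32_t)seed);
  std::vector<int> rows(bootstrap.size());
  for (int i = 0; i < bootstrap.size(); ++i) rows[i] = bootstrap[i] - 1;
  TreeBuf T;
  std::vector<int> featpool(X.ncol());
  grow(X, y, rows, m, rng, T, featpool);
  return tree_to_list(T);
}

// Fit B trees on seeded bootstraps of size n (with replacement).
// Returns the trees plus an n x B in-bag count matrix (0 => out-of-bag).
// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, IntegerVector y, int B, int m,
                    IntegerVector tree_seeds) {
  const int n = X.nrow();
  List trees(B);
  IntegerMatrix inbag(n, B);
  std::vector<int> featpool(X.ncol());
  for (int b = 0; b < B; ++b) {
    std::mt19937 rng((uint32_t)tree_seeds[b]);
    std::uniform_int_distribution<int> U(0, n - 1);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      const int r = U(rng);
      rows[i] = r;
      inbag(r, b)++;
    }
    TreeBuf T;
    grow(X, y, rows, m, rng, T, featpool);
    trees[b] = tree_to_list(T);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// Class votes over all trees for each row of X (n x 2: negative, positive).
// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  IntegerMatrix votes(n, 2);
  for (int b = 0; b < B; ++b) {
    TreeView t(trees[b]);
    for (int i = 0; i < n; ++i) votes(i, t.predict(X, i))++;
  }
  return votes;
}

// Votes restricted to trees for which each row is out-of-bag.
// [[Rcpp::export]]
IntegerMatrix cpp_oob_votes(List trees, IntegerMatrix inbag, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  IntegerMatrix votes(n, 2);
  for (int b = 0; b < B; ++b) {
    TreeView t(trees[b]);
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) votes(i, t.predict(X, i))++;
  }
  return votes;
}

// Per-tree permutation importance on out-of-bag instances.
// raw(b, j) = (# oob rows of tree b correctly classified)
//           - (# correct after permuting column j within tree b's oob rows).
// Features never used in a tree's splits contribute exactly 0 (no
// permutation can alter any decision path), and are skipped.
// A tree with an empty oob set contributes 0 for every feature (flagged).
// [[Rcpp::export]]
List cpp_oob_importance(List trees, IntegerMatrix inbag, NumericMatrix X,
                        IntegerVector y, IntegerVector perm_seeds) {
  const int n = X.nrow(), p = X.ncol(), B = trees.size();
  NumericMatrix raw(B, p);
  LogicalVector empty_oob(B);

  for (int b = 0; b < B; ++b) {
    TreeView t(trees[b]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) oob.push_back(i);
    const int no = (int)oob.size();
    if (no == 0) { empty_oob[b] = true; continue; }

    int c0 = 0;
    for (int i : oob) c0 += (t.predict(X, i) == y[i]);

    std::vector<bool> used(p, false);
    for (size_t k = 0; k < t.feature.size(); ++k)
      if (t.feature[k] >= 0) used[t.feature[k]] = true;

    std::mt19937 rng((uint32_t)perm_seeds[b]);
    std::vector<int> idx(no);
    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue;
      for (int i = 0; i < no; ++i) idx[i] = i;
      std::shuffle(idx.begin(), idx.end(), rng);
      int c = 0;
      for (int i = 0; i < no; ++i)
        c += (t.predict(X, oob[i], f, X(oob[idx[i]], f)) == y[oob[i]]);
      raw(b, f) = (double)(c0 - c);
    }
  }
  return List::create(_["raw"] = raw, _["empty_oob"] = empty_oob);
}

// Features used in at least one split of at least one tree.
// [[Rcpp::export]]
LogicalVector cpp_used_features(List trees, int p) {
  LogicalVector used(p);
  for (int b = 0; b < trees.size(); ++b) {
    List t = trees[b];
    IntegerVector f = t["feature"];
    for (int k = 0; k < f.size(); ++k)
      if (f[k] >= 0) used[f[k]] = true;
  }
  return used;
}
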
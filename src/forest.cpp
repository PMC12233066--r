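// Random forest classifier (CART trees, Gini impurity, bootstrap bagging,
// mtry feature subsampling). Self-contained: trees are returned to R as
// plain numeric matrices so fitted models are ordinary R lists and survive
// serialization without external state.
//
// RNG is a private mt19937 seeded from R, so training is bit-reproducible
// for a fixed (X, y, hyperparameters, seed) regardless of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat;      // 0-based feature index; -1 for leaf
  double thr;    // x[feat] <= thr goes left
  int left, right; // 0-based node indices; -1 for leaf
  int pred;      // 0-based majority class (valid in every node)
};

double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = (double)cnt[k] / n;
    s += p * p;
  }
  return 1.0 - s;
}

int majority(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = (int)k;
  return best;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y; // 0-based classes
  int K, mtry, min_node, n_root;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance; // accumulated weighted impurity decrease

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mtry_, int min_node_, std::mt19937& rng_,
              std::vector<double>& imp_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
        n_root(0), rng(rng_), importance(imp_) {}

  int grow(std::vector<int>& ids, int lo, int hi) {
    const int m = hi - lo;
    std::vector<int> cnt(K, 0);
    for (int t = lo; t < hi; ++t) cnt[y[ids[t]]]++;
    const double g0 = gini(cnt, m);
    const int pred = majority(cnt);

    int node_id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    if (m <= min_node || g0 <= 0.0) return node_id;

    // sample mtry candidate features without replacement
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
    for (int k = 0; k < mtry && k < p; ++k) {
      std::uniform_int_distribution<int> pick(k, p - 1);
      std::swap(feats[k], feats[pick(rng)]);
    }

    double best_gain = 1e-12; // require strictly positive gain
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<int> ord(ids.begin() + lo, ids.begin() + hi);
    std::vector<int> lcnt(K);
    for (int k = 0; k < mtry && k < p; ++k) {
      const int f = feats[k];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, f), xb = X(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      std::fill(lcnt.begin(), lcnt.end(), 0);
      std::vector<int> rcnt(cnt);
      for (int i = 0; i < m - 1; ++i) {
        const int c = y[ord[i]];
        lcnt[c]++; rcnt[c]--;
        const double xi = X(ord[i], f), xj = X(ord[i + 1], f);
        if (xi == xj) continue;
        const int nl = i + 1, nr2 = m - nl;
        const double gain =
            g0 - ((double)nl / m) * gini(lcnt, nl) - ((double)nr2 / m) * gini(rcnt, nr2);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = xi + 0.5 * (xj - xi);
        }
      }
    }
    if (best_f < 0) return node_id; // no informative split among candidates

    // partition ids[lo, hi) in place, stable order
    std::stable_partition(ids.begin() + lo, ids.begin() + hi,
                          [&](int a) { return X(a, best_f) <= best_thr; });
    int nl = 0;
    for (int t = lo; t < hi; ++t)
      if (X(ids[t], best_f) <= best_thr) nl++;
    if (nl == 0 || nl == m) return node_id; // numerical guard

    importance[best_f] += ((double)m / n_root) * best_gain;
    nodes[node_id].feat = best_f;
    nodes[node_id].thr = best_thr;
    nodes[node_id].left = grow(ids, lo, lo + nl);
    nodes[node_id].right = grow(ids, lo + nl, hi);
    return node_id;
  }
};

int tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return (int)tree(node, 4);
}

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                  int mtry, int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> draw(0, n - 1);

  List trees(n_trees);
  std::vector<double> imp(p, 0.0);
  IntegerMatrix oob_votes(n, n_classes);

  std::vector<int> ids(n);
  std::vector<char> inbag(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int s = draw(rng);
      ids[i] = s;
      inbag[s] = 1;
    }
    TreeBuilder tb(X, y, n_classes, mtry, min_node, rng, imp);
    tb.n_root = n;
    tb.nodes.reserve(2 * n);
    tb.grow(ids, 0, n);

    const int nn = (int)tb.nodes.size();
    NumericMatrix tm(nn, 5);
    for (int q = 0; q < nn; ++q) {
      tm(q, 0) = tb.nodes[q].feat;
      tm(q, 1) = tb.nodes[q].thr;
      tm(q, 2) = tb.nodes[q].left;
      tm(q, 3) = tb.nodes[q].right;
      tm(q, 4) = tb.nodes[q].pred;
    }
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_votes(i, tree_predict(tm, X, i))++;
    trees[t] = tm;
  }

  double tot = 0.0;
  for (int f = 0; f < p; ++f) tot += imp[f];
  NumericVector importance(p);
  for (int f = 0; f < p; ++f) importance[f] = (tot > 0) ? imp[f] / tot : 1.0 / p;

  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["oob_votes"] = oob_votes);
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) votes(i, tree_predict(tm, X, i))++;
  }
  return votes;
}
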
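// Random forest (CART, Gini) with mean-decrease-in-impurity importances.
//
// No tree-ensemble package is available in the target library, so the
// reference interpretable classifier is implemented here. Conventions match
// the widely used defaults: bootstrap resampling, mtry features per node,
// best-split-by-weighted-Gini-decrease, per-tree importances normalized to
// sum 1 and averaged over trees. Randomness comes from R's RNG, so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf majority class
};

double gini(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : counts) {
    double p = static_cast<double>(c) / n;
    s += p * p;
  }
  return 1.0 - s;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;   // 0..K-1
  int K, maxdepth, mtry, n_total;
  Tree tree;
  std::vector<double> importance; // raw weighted impurity decreases

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int K_,
         int maxdepth_, int mtry_, int n_total_)
      : X(X_), y(y_), K(K_), maxdepth(maxdepth_), mtry(mtry_),
        n_total(n_total_), importance(X_.ncol(), 0.0) {}

  int leaf(const std::vector<int>& counts) {
    int best = 0;
    for (int c = 1; c < K; ++c)
      if (counts[c] > counts[best]) best = c;
    int id = tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(best);
    return id;
  }

  // grow on sample indices idx (into rows of X); returns node id
  int grow(std::vector<int>& idx, int depth) {
    int n = idx.size();
    std::vector<int> counts(K, 0);
    for (int i : idx) counts[y[i]]++;
    double imp = gini(counts, n);
    if (depth >= maxdepth || n < 2 || imp <= 0.0) return leaf(counts);

    // sample mtry distinct features (partial Fisher-Yates with R's RNG)
    int F = X.ncol();
    std::vector<int> feats(F);
    for (int f = 0; f < F; ++f) feats[f] = f;
    int m = std::min(mtry, F);
    for (int i = 0; i < m; ++i) {
      int j = i + static_cast<int>(unif_rand() * (F - i));
      if (j >= F) j = F - 1;
      std::swap(feats[i], feats[j]);
    }

    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> order(idx);
    for (int fi = 0; fi < m; ++fi) {
      int f = feats[fi];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::vector<int> lc(K, 0);
      std::vector<int> rc(counts);
      for (int pos = 0; pos < n - 1; ++pos) {
        int cls = y[order[pos]];
        lc[cls]++; rc[cls]--;
        double xl = X(order[pos], f), xr = X(order[pos + 1], f);
        if (xl >= xr) continue; // not a valid cut between distinct values
        int nl = pos + 1, nr = n - nl;
        double dec = imp - (static_cast<double>(nl) / n) * gini(lc, nl)
                         - (static_cast<double>(nr) / n) * gini(rc, nr);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (xl + xr);
        }
      }
    }
    if (best_f < 0) return leaf(counts);

    importance[best_f] += (static_cast<double>(n) / n_total) * best_dec;

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    int id = tree.feature.size();
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-2);
    tree.right.push_back(-2);
    tree.pred.push_back(-1);
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    tree.left[id] = l;
    tree.right[id] = r;
    return id;
  }
};

int predict_one(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  return t.pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                int max_depth, int mtry, bool bootstrap) {
  int N = X.nrow(), F = X.ncol();
  NumericVector importance(F);
  List trees(n_trees);
  RNGScope scope;
  for (int tr = 0; tr < n_trees; ++tr) {
    std::vector<int> idx(N);
    if (bootstrap) {
      for (int i = 0; i < N; ++i) {
        int j = static_cast<int>(unif_rand() * N);
        idx[i] = (j >= N) ? N - 1 : j;
      }
    } else {
      for (int i = 0; i < N; ++i) idx[i] = i;
    }
    Grower g(X, y, n_classes, max_depth, mtry, N);
    g.grow(idx, 0);
    double tot = 0.0;
    for (double v : g.importance) tot += v;
    if (tot > 0.0)
      for (int f = 0; f < F; ++f) importance[f] += g.importance[f] / tot;
    trees[tr] = List::create(
        _["feature"] = IntegerVector(g.tree.feature.begin(), g.tree.feature.end()),
        _["threshold"] = NumericVector(g.tree.threshold.begin(), g.tree.threshold.end()),
        _["left"] = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
        _["right"] = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
        _["pred"] = IntegerVector(g.tree.pred.begin(), g.tree.pred.end()));
  }
  for (int f = 0; f < F; ++f) importance[f] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X, int n_classes) {
  List trees = forest["trees"];
  int N = X.nrow(), T = trees.size();
  IntegerVector out(N);
  std::vector<Tree> ts(T);
  for (int tr = 0; tr < T; ++tr) {
    List tl = trees[tr];
    IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"],
                  p = tl["pred"];
    NumericVector th = tl["threshold"];
    ts[tr].feature.assign(f.begin(), f.end());
    ts[tr].threshold.assign(th.begin(), th.end());
    ts[tr].left.assign(l.begin(), l.end());
    ts[tr].right.assign(r.begin(), r.end());
    ts[tr].pred.assign(p.begin(), p.end());
  }
  std::vector<int> votes(n_classes);
  for (int i = 0; i < N; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int tr = 0; tr < T; ++tr) votes[predict_one(ts[tr], X, i)]++;
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[c] > votes[best]) best = c;
    out[i] = best;
  }
  return out;
}
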
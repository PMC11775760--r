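// CART regression trees, bagged forests and gradient-boosted trees.
// Written for many repeated fits on small n (leave-one-out tuning loops):
// the LOOCV drivers below keep every tree in flat C++ buffers so a full
// n-fold refit costs no R allocations.  All randomness comes from an
// internal splitmix64 stream seeded by the caller, making fits
// bit-reproducible and independent of R's RNG state.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

// column-major flat view of the feature matrix
struct Flat {
  const double* x;
  int n, p;
  double at(int row, int col) const { return x[(size_t)col * n + row]; }
};

struct TreeNodes {
  std::vector<int> feature; // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> value;
  void clear() {
    feature.clear(); thresh.clear(); left.clear(); right.clear();
    value.clear();
  }
  int add() {
    feature.push_back(-1);
    thresh.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct Task { int node, lo, hi, depth; };

// scratch buffers reused across fits
struct Scratch {
  std::vector<std::pair<double, double>> srt; // (x value, y value)
  std::vector<int> feats;
  std::vector<Task> stack;
};

// Fit one tree on rows idx[lo..hi) (in-place partitioning of idx).
// y is indexed by original row id.
void fit_tree(const Flat& X, const double* y, std::vector<int>& idx,
              int max_depth, int min_split, int min_leaf, int mtry,
              SplitMix64& rng, TreeNodes& tree, Scratch& sc) {
  int p = X.p;
  if (mtry < 1 || mtry > p) mtry = p;
  std::vector<int>& feats = sc.feats;
  feats.resize(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  tree.clear();
  sc.stack.clear();
  int root = tree.add();
  sc.stack.push_back({root, 0, (int)idx.size(), 0});
  while (!sc.stack.empty()) {
    Task t = sc.stack.back();
    sc.stack.pop_back();
    int n = t.hi - t.lo;
    double sum = 0.0;
    for (int i = t.lo; i < t.hi; ++i) sum += y[idx[i]];
    tree.value[t.node] = sum / n;
    if (t.depth >= max_depth || n < min_split || n < 2 * min_leaf) continue;
    double best_gain = 0.0, parent_score = sum * sum / n;
    int best_f = -1;
    double best_thr = 0.0;
    sc.srt.resize(n);
    if (mtry < p) { // per-node random feature subset (forest decorrelation)
      for (int k = 0; k < mtry; ++k) {
        int j = k + rng.unif_int(p - k);
        std::swap(feats[k], feats[j]);
      }
    }
    for (int fi = 0; fi < mtry; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i) {
        int r = idx[t.lo + i];
        sc.srt[i] = std::make_pair(X.at(r, f), y[r]);
      }
      std::sort(sc.srt.begin(), sc.srt.end());
      if (sc.srt[0].first == sc.srt[n - 1].first) continue;
      double ls = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        ls += sc.srt[i].second;
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (sc.srt[i].first == sc.srt[i + 1].first) continue;
        double rs = sum - ls;
        double gain = ls * ls / nl + rs * rs / nr - parent_score;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (sc.srt[i].first + sc.srt[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;
    int mid = t.lo;
    for (int i = t.lo; i < t.hi; ++i) {
      if (X.at(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == t.lo || mid == t.hi) continue;
    tree.feature[t.node] = best_f;
    tree.thresh[t.node] = best_thr;
    int lchild = tree.add(), rchild = tree.add();
    tree.left[t.node] = lchild;
    tree.right[t.node] = rchild;
    sc.stack.push_back({lchild, t.lo, mid, t.depth + 1});
    sc.stack.push_back({rchild, mid, t.hi, t.depth + 1});
  }
}

inline double tree_predict_row(const TreeNodes& tree, const Flat& X,
                               int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X.at(row, tree.feature[node]) <= tree.thresh[node])
               ? tree.left[node]
               : tree.right[node];
  }
  return tree.value[node];
}

NumericMatrix pack_tree(const TreeNodes& tree) {
  int n = (int)tree.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = tree.feature[i];
    m(i, 1) = tree.thresh[i];
    m(i, 2) = tree.left[i];
    m(i, 3) = tree.right[i];
    m(i, 4) = tree.value[i];
  }
  return m;
}

void unpack_tree(const NumericMatrix& m, TreeNodes& tree) {
  int n = m.nrow();
  tree.clear();
  for (int i = 0; i < n; ++i) {
    tree.feature.push_back((int)m(i, 0));
    tree.thresh.push_back(m(i, 1));
    tree.left.push_back((int)m(i, 2));
    tree.right.push_back((int)m(i, 3));
    tree.value.push_back(m(i, 4));
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_rfr_fit(NumericMatrix X, NumericVector y, int n_estimators,
                 int max_depth, int min_split, int min_leaf, int mtry,
                 double seed) {
  int n = X.nrow();
  Flat fx{REAL(X), n, (int)X.ncol()};
  SplitMix64 rng((uint64_t)seed);
  List trees(n_estimators);
  std::vector<int> idx(n);
  TreeNodes tree;
  Scratch sc;
  for (int b = 0; b < n_estimators; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n); // bootstrap
    fit_tree(fx, REAL(y), idx, max_depth, min_split, min_leaf, mtry, rng,
             tree, sc);
    trees[b] = pack_tree(tree);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  Flat fx{REAL(X), n, (int)X.ncol()};
  NumericVector out(n);
  TreeNodes tree;
  for (int b = 0; b < B; ++b) {
    unpack_tree(trees[b], tree);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, fx, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// [[Rcpp::export]]
List cpp_gbrt_fit(NumericMatrix X, NumericVector y, int n_estimators,
                  double learning_rate, int max_depth, int min_split,
                  int min_leaf) {
  int n = X.nrow();
  Flat fx{REAL(X), n, (int)X.ncol()};
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;
  std::vector<double> resid(n), pred(n, init);
  std::vector<int> idx(n);
  List trees(n_estimators);
  TreeNodes tree;
  Scratch sc;
  SplitMix64 rng(0); // unused: boosting trees scan every feature
  for (int b = 0; b < n_estimators; ++b) {
    for (int i = 0; i < n; ++i) {
      resid[i] = y[i] - pred[i];
      idx[i] = i;
    }
    fit_tree(fx, resid.data(), idx, max_depth, min_split, min_leaf, -1,
             rng, tree, sc);
    for (int i = 0; i < n; ++i)
      pred[i] += learning_rate * tree_predict_row(tree, fx, i);
    trees[b] = pack_tree(tree);
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export]]
NumericVector cpp_gbrt_predict(double init, List trees, double learning_rate,
                               NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  Flat fx{REAL(X), n, (int)X.ncol()};
  NumericVector out(n, init);
  TreeNodes tree;
  for (int b = 0; b < B; ++b) {
    unpack_tree(trees[b], tree);
    for (int i = 0; i < n; ++i)
      out[i] += learning_rate * tree_predict_row(tree, fx, i);
  }
  return out;
}

// ---- leave-one-out drivers ---------------------------------------------
// Per fold i the training matrix is X with row i removed, rows kept in
// order; `seeds[i]` matches what the R-level fold loop would hand to the
// single-fit entry points, so driver results are bit-identical to a
// literal train/predict loop.

namespace {

// copy X without row `drop` into a flat buffer (column-major)
void fold_matrix(const Flat& X, int drop, std::vector<double>& buf) {
  int n = X.n, p = X.p;
  buf.resize((size_t)(n - 1) * p);
  size_t k = 0;
  for (int f = 0; f < p; ++f) {
    for (int r = 0; r < n; ++r) {
      if (r == drop) continue;
      buf[k++] = X.at(r, f);
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_rfr_loocv(NumericMatrix X, NumericVector y,
                            int n_estimators, int max_depth, int min_split,
                            int min_leaf, int mtry, NumericVector seeds) {
  int n = X.nrow(), p = X.ncol();
  Flat fx{REAL(X), n, p};
  NumericVector out(n);
  std::vector<double> xbuf, ybuf(n - 1), xrow(p);
  std::vector<int> idx(n - 1);
  TreeNodes tree;
  Scratch sc;
  for (int i = 0; i < n; ++i) {
    fold_matrix(fx, i, xbuf);
    Flat ff{xbuf.data(), n - 1, p};
    int k = 0;
    for (int r = 0; r < n; ++r)
      if (r != i) ybuf[k++] = y[r];
    for (int f = 0; f < p; ++f) xrow[f] = fx.at(i, f);
    Flat frow{xrow.data(), 1, p};
    SplitMix64 rng((uint64_t)seeds[i]);
    double acc = 0.0;
    for (int b = 0; b < n_estimators; ++b) {
      for (int j = 0; j < n - 1; ++j) idx[j] = rng.unif_int(n - 1);
      fit_tree(ff, ybuf.data(), idx, max_depth, min_split, min_leaf, mtry,
               rng, tree, sc);
      acc += tree_predict_row(tree, frow, 0);
    }
    out[i] = acc / n_estimators;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gbrt_loocv(NumericMatrix X, NumericVector y,
                             int n_estimators, double learning_rate,
                             int max_depth, int min_split, int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  Flat fx{REAL(X), n, p};
  NumericVector out(n);
  std::vector<double> xbuf, ybuf(n - 1), xrow(p), resid(n - 1),
      pred(n - 1);
  std::vector<int> idx(n - 1);
  TreeNodes tree;
  Scratch sc;
  SplitMix64 rng(0);
  for (int i = 0; i < n; ++i) {
    fold_matrix(fx, i, xbuf);
    Flat ff{xbuf.data(), n - 1, p};
    int k = 0;
    double init = 0.0;
    for (int r = 0; r < n; ++r) {
      if (r != i) {
        ybuf[k++] = y[r];
        init += y[r];
      }
    }
    init /= (n - 1);
    for (int f = 0; f < p; ++f) xrow[f] = fx.at(i, f);
    Flat frow{xrow.data(), 1, p};
    std::fill(pred.begin(), pred.end(), init);
    double acc = init;
    for (int b = 0; b < n_estimators; ++b) {
      for (int j = 0; j < n - 1; ++j) {
        resid[j] = ybuf[j] - pred[j];
        idx[j] = j;
      }
      fit_tree(ff, resid.data(), idx, max_depth, min_split, min_leaf, -1,
               rng, tree, sc);
      for (int j = 0; j < n - 1; ++j)
        pred[j] += learning_rate * tree_predict_row(tree, ff, j);
      acc += learning_rate * tree_predict_row(tree, frow, 0);
    }
    out[i] = acc;
  }
  return out;
}
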
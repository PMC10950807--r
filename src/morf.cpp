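#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Multi-output CART forest. Trees are returned as plain R lists (flat node
// arrays) so the rest of the package -- and the brute-force Shapley oracle in
// the test suite -- can traverse them without touching C++ internals.
//
// Node layout (0-based indices, -1 = none):
//   feature[n]   split feature, -1 for leaves
//   threshold[n] split threshold (go left iff x <= threshold)
//   left[n], right[n] child node indices
//   value[n, q]  mean of the training targets reaching the node

namespace {

// xorshift-free deterministic RNG: splitmix64 seeded stream. Used instead of
// std::uniform_int_distribution, whose mapping is implementation-defined.
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n) by rejection
  int below(int n) {
    uint64_t limit = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
    uint64_t x;
    do { x = next(); } while (x >= limit);
    return (int)(x % (uint64_t)n);
  }
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& Yt;  // row-major n x q copy of the targets
  int p, q, max_depth, mtry, min_split;
  Rng& rng;

  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;  // row-major n_nodes x q

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& Yt_, int q_,
              int max_depth_, int mtry_, int min_split_, Rng& rng_)
      : X(X_), Yt(Yt_), p(X_.ncol()), q(q_), max_depth(max_depth_),
        mtry(mtry_), min_split(min_split_), rng(rng_) {}

  int new_node(const std::vector<int>& idx) {
    int id = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    for (int k = 0; k < q; ++k) {
      double s = 0.0;
      for (int i : idx) s += Yt[(size_t)i * q + k];
      value.push_back(s / idx.size());
    }
    return id;
  }

  int build(std::vector<int>& idx, int depth) {
    int node = new_node(idx);
    int n = (int)idx.size();
    if (depth >= max_depth || n < min_split) return node;

    // is every target row identical? then splitting is pointless
    bool pure = true;
    for (int k = 0; k < q && pure; ++k)
      for (int t = 1; t < n; ++t)
        if (Yt[(size_t)idx[t] * q + k] != Yt[(size_t)idx[0] * q + k]) { pure = false; break; }
    if (pure) return node;

    // sample mtry candidate features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + rng.below(p - j)]);

    std::vector<double> tot(q, 0.0);
    for (int k = 0; k < q; ++k)
      for (int i : idx) tot[k] += Yt[(size_t)i * q + k];

    double best_score = -1.0;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    std::vector<double> sL(q);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int t = 0; t < n; ++t) vals[t] = {X(idx[t], f), idx[t]};
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;  // constant feature
      std::fill(sL.begin(), sL.end(), 0.0);
      for (int t = 1; t < n; ++t) {
        const double* yrow = &Yt[(size_t)vals[t - 1].second * q];
        for (int k = 0; k < q; ++k) sL[k] += yrow[k];
        if (vals[t - 1].first == vals[t].first) continue;
        double score = 0.0;
        for (int k = 0; k < q; ++k) {
          double sR = tot[k] - sL[k];
          score += sL[k] * sL[k] / t + sR * sR / (n - t);
        }
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = vals[t - 1].first + 0.5 * (vals[t].first - vals[t - 1].first);
        }
      }
    }
    if (best_f < 0) return node;  // all sampled features constant

    std::vector<int> idxL, idxR;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? idxL : idxR).push_back(i);
    if (idxL.empty() || idxR.empty()) return node;  // numeric edge case

    feature[node] = best_f;
    threshold[node] = best_thr;
    left[node] = build(idxL, depth + 1);
    right[node] = build(idxR, depth + 1);
    return node;
  }

  List as_list() const {
    int n_nodes = (int)feature.size();
    NumericMatrix val(n_nodes, q);
    for (int i = 0; i < n_nodes; ++i)
      for (int k = 0; k < q; ++k) val(i, k) = value[(size_t)i * q + k];
    return List::create(
        _["feature"] = IntegerVector(feature.begin(), feature.end()),
        _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
        _["left"] = IntegerVector(left.begin(), left.end()),
        _["right"] = IntegerVector(right.begin(), right.end()),
        _["value"] = val);
  }
};

// Flat view of an R tree list for fast traversal.
struct TreeView {
  const int* feature;
  const double* threshold;
  const int* left;
  const int* right;
  const double* value;  // column-major n_nodes x q
  int n_nodes, q;
  explicit TreeView(const List& tree) {
    IntegerVector f = tree["feature"], l = tree["left"], r = tree["right"];
    NumericVector t = tree["threshold"];
    NumericMatrix v = tree["value"];
    feature = INTEGER(f);
    threshold = REAL(t);
    left = INTEGER(l);
    right = INTEGER(r);
    value = REAL(v);
    n_nodes = v.nrow();
    q = v.ncol();
  }
  int leaf_for(const double* x, int stride) const {
    int node = 0;
    while (feature[node] >= 0)
      node = (x[(size_t)feature[node] * stride] <= threshold[node])
                 ? left[node] : right[node];
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List cs_fit_forest(NumericMatrix X, NumericMatrix Y, int n_trees, int max_depth,
                   int mtry, int min_split, double seed) {
  int n = X.nrow(), q = Y.ncol();
  std::vector<double> Yt((size_t)n * q);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < q; ++k) Yt[(size_t)i * q + k] = Y(i, k);
  List trees(n_trees);
  Rng master((uint64_t)seed);
  for (int t = 0; t < n_trees; ++t) {
    Rng rng(master.next());
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap rows
    std::sort(idx.begin(), idx.end());
    TreeBuilder tb(X, Yt, q, max_depth, mtry, min_split, rng);
    tb.build(idx, 0);
    trees[t] = tb.as_list();
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix cs_predict_forest(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  TreeView first(forest[0]);
  int q = first.q;
  NumericMatrix out(n, q);
  const double* xp = REAL(X);
  for (int t = 0; t < T; ++t) {
    TreeView tv(forest[t]);
    for (int i = 0; i < n; ++i) {
      int leaf = tv.leaf_for(xp + i, n);
      for (int k = 0; k < q; ++k) out(i, k) += tv.value[(size_t)k * tv.n_nodes + leaf];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < q; ++k) out(i, k) /= T;
  return out;
}

namespace {

// Exact interventional Shapley attribution of one tree for one (x, b) pair.
// Walk the tree; at a node whose split feature takes x and b down different
// children, the feature becomes a "player": branch once with the feature
// committed to x's side and once to b's side. Each reachable leaf then has a
// set A of x-committed features (|A| = a) and a set B of b-committed features
// (|B| = bb), and contributes its value v with the closed-form coalition
// weights  +v*(a-1)!*bb!/(a+bb)!  to every feature in A and
//          -v*a!*(bb-1)!/(a+bb)!  to every feature in B.
struct ShapWalker {
  const TreeView* tv;
  const double* x;   // strided feature vectors
  const double* b;
  int xs, bs;        // strides
  double* phi;       // p x q accumulation, column-major
  int p, q;
  const double* fact;
  std::vector<int8_t> state;  // 0 free, 1 committed to x, 2 committed to b
  std::vector<int> apath, bpath;

  ShapWalker(int p_, int q_, const double* fact_)
      : tv(nullptr), x(nullptr), b(nullptr), xs(1), bs(1), phi(nullptr),
        p(p_), q(q_), fact(fact_), state(p_, 0) {
    apath.reserve(64);
    bpath.reserve(64);
  }

  void walk(int node) {
    int f = tv->feature[node];
    if (f < 0) {  // leaf
      int a = (int)apath.size(), bb = (int)bpath.size();
      if (a == 0 && bb == 0) return;
      double wpos = (a > 0) ? fact[a - 1] * fact[bb] / fact[a + bb] : 0.0;
      double wneg = (bb > 0) ? fact[a] * fact[bb - 1] / fact[a + bb] : 0.0;
      int n_nodes = tv->n_nodes;
      for (int k = 0; k < q; ++k) {
        double v = tv->value[(size_t)k * n_nodes + node];
        if (v == 0.0) continue;
        double* col = phi + (size_t)k * p;
        double vp = v * wpos, vn = v * wneg;
        for (int i : apath) col[i] += vp;
        for (int i : bpath) col[i] -= vn;
      }
      return;
    }
    double thr = tv->threshold[node];
    int xgo = (x[(size_t)f * xs] <= thr) ? tv->left[node] : tv->right[node];
    int bgo = (b[(size_t)f * bs] <= thr) ? tv->left[node] : tv->right[node];
    if (xgo == bgo) { walk(xgo); return; }
    switch (state[f]) {
      case 1: walk(xgo); return;
      case 2: walk(bgo); return;
      default:
        state[f] = 1; apath.push_back(f); walk(xgo); apath.pop_back();
        state[f] = 2; bpath.push_back(f); walk(bgo); bpath.pop_back();
        state[f] = 0;
    }
  }
};

}  // namespace

// Interventional Shapley values of the forest for each validation row,
// averaged over the background rows. Returns an (n_val * p * q) array.
// [[Rcpp::export]]
NumericVector cs_shap_interventional(List forest, NumericMatrix Xval,
                                     NumericMatrix Bg) {
  int nv = Xval.nrow(), nb = Bg.nrow(), p = Xval.ncol(), T = forest.size();
  TreeView first(forest[0]);
  int q = first.q;
  std::vector<double> fact(2 * 64 + 2);
  fact[0] = 1.0;
  for (size_t i = 1; i < fact.size(); ++i) fact[i] = fact[i - 1] * (double)i;

  NumericVector out((R_xlen_t)nv * p * q);  // zero-initialised
  // per-validation-sample accumulators, column-major p x q each
  std::vector<double> acc((size_t)nv * p * q, 0.0);
  const double* xv = REAL(Xval);
  const double* bg = REAL(Bg);
  ShapWalker w(p, q, fact.data());
  for (int t = 0; t < T; ++t) {
    TreeView tv(forest[t]);
    w.tv = &tv;
    for (int v = 0; v < nv; ++v) {
      w.x = xv + v;
      w.xs = nv;
      w.phi = acc.data() + (size_t)v * p * q;
      for (int b = 0; b < nb; ++b) {
        w.b = bg + b;
        w.bs = nb;
        w.walk(0);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  double scale = 1.0 / ((double)T * (double)nb);
  for (int v = 0; v < nv; ++v)
    for (int k = 0; k < q; ++k)
      for (int i = 0; i < p; ++i)
        out[(R_xlen_t)v + (R_xlen_t)nv * (i + (R_xlen_t)p * k)] =
            acc[(size_t)v * p * q + (size_t)k * p + i] * scale;
  out.attr("dim") = IntegerVector::create(nv, p, q);
  return out;
}
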
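#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gini impurity of a binary node with n observations, npos positives.
static inline double gini(double n, double npos) {
  if (n <= 0.0) return 0.0;
  double p = npos / n;
  return 2.0 * p * (1.0 - p);
}

// Best axis-aligned split of `rows` (1-based into X) over candidate
// features `feats` (1-based). Ties resolved deterministically: first
// feature in `feats` order, then lowest threshold. A split is accepted
// only if it strictly reduces weighted Gini impurity and respects
// min_leaf on both sides.
// [[Rcpp::export]]
List cpp_best_split(const NumericMatrix& X, const IntegerVector& y,
                    const IntegerVector& rows, const IntegerVector& feats,
                    int min_leaf) {
  const int n = rows.size();
  double npos = 0.0;
  for (int i = 0; i < n; ++i) npos += y[rows[i] - 1];
  const double parent = gini((double)n, npos);

  bool found = false;
  int best_feat = NA_INTEGER;
  double best_thr = NA_REAL, best_imp = parent - 1e-12;

  std::vector<std::pair<double, int>> v(n);
  for (int fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi] - 1;
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(rows[i] - 1, f), (int)y[rows[i] - 1]);
    std::sort(v.begin(), v.end());
    double lpos = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += v[i].second;
      if (v[i].first == v[i + 1].first) continue;       // not a boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double imp = (nl * gini(nl, lpos) + nr * gini(nr, npos - lpos)) / n;
      if (imp < best_imp - 1e-12) {
        best_imp = imp;
        best_feat = f + 1;
        best_thr = 0.5 * (v[i].first + v[i + 1].first);
        found = true;
      }
    }
  }
  return List::create(_["found"] = found, _["feature"] = best_feat,
                      _["threshold"] = best_thr, _["impurity"] = best_imp,
                      _["parent_impurity"] = parent);
}

struct FlatTree {
  const int* feature;     // NA_INTEGER at leaves
  const double* threshold;
  const int* left;
  const int* right;
  const double* prob;
  int n_nodes;
};

static FlatTree flatten(const List& tree) {
  FlatTree t;
  IntegerVector f = tree["feature"], l = tree["left"], r = tree["right"];
  NumericVector thr = tree["threshold"], p = tree["prob"];
  t.feature = INTEGER(f); t.left = INTEGER(l); t.right = INTEGER(r);
  t.threshold = REAL(thr); t.prob = REAL(p);
  t.n_nodes = f.size();
  return t;
}

static inline double route(const FlatTree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] != NA_INTEGER) {
    const double x = X(row, t.feature[node] - 1);
    node = (x <= t.threshold[node] ? t.left[node] : t.right[node]) - 1;
  }
  return t.prob[node];
}

// Accumulate one tree's routed leaf probabilities for all rows into out[],
// with a fast path for the two dominant shapes: leaf-only stumps and
// depth-1 stumps (contiguous column scan).
static void add_tree(const FlatTree& t, const NumericMatrix& X, double* out) {
  const int n = X.nrow();
  if (t.feature[0] == NA_INTEGER) {           // leaf-only stump
    const double p = t.prob[0];
    for (int i = 0; i < n; ++i) out[i] += p;
    return;
  }
  const int l = t.left[0] - 1, r = t.right[0] - 1;
  if (t.feature[l] == NA_INTEGER && t.feature[r] == NA_INTEGER) {  // depth 1
    const double* col = &X(0, t.feature[0] - 1);
    const double thr = t.threshold[0], pl = t.prob[l], pr = t.prob[r];
    for (int i = 0; i < n; ++i) out[i] += (col[i] <= thr ? pl : pr);
    return;
  }
  for (int i = 0; i < n; ++i) out[i] += route(t, X, i);
}

// Positive-class probability of every tree (list of tree lists) for every
// row of X: returns nrow(X) x length(trees).
// [[Rcpp::export]]
NumericMatrix cpp_tree_probs(const NumericMatrix& X, const List& trees) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    FlatTree ft = flatten(tr);
    add_tree(ft, X, &out(0, t));
  }
  return out;
}

// Per-member improvement probability: mean over each member's trees of the
// routed leaf probability. `members` is a list of members, each a list with
// element "trees" (list of tree lists). Returns nrow(X) x length(members).
// [[Rcpp::export]]
NumericMatrix cpp_member_probs(const NumericMatrix& X, const List& members) {
  const int n = X.nrow(), M = members.size();
  NumericMatrix out(n, M);
  std::vector<double> acc(n);
  for (int m = 0; m < M; ++m) {
    List mem = members[m];
    List trees = mem["trees"];
    const int T = trees.size();
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      List tr = trees[t];
      FlatTree ft = flatten(tr);
      add_tree(ft, X, acc.data());
    }
    const double inv = T > 0 ? 1.0 / T : 0.0;
    for (int i = 0; i < n; ++i) out(i, m) = acc[i] * inv;
  }
  return out;
}

// Top-N candidate indices (1-based) per column of P, highest probability
// first; ties broken by lower candidate index. Repeated argmax scan:
// O(n * N) per member, deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_top_n(const NumericMatrix& P, int N) {
  const int n = P.nrow(), M = P.ncol();
  if (N > n) N = n;
  IntegerMatrix out(N, M);
  std::vector<double> p(n);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) p[i] = P(i, m);
    for (int k = 0; k < N; ++k) {
      int arg = 0;
      double best = p[0];
      for (int i = 1; i < n; ++i)
        if (p[i] > best) { best = p[i]; arg = i; }
      out(k, m) = arg + 1;
      p[arg] = -1.0;        // probabilities live in [0,1]
    }
  }
  return out;
}
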
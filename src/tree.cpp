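#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// CART-style binary tree grown on ALL supplied cells (no bootstrap) by
// best-Gini splits to purity; candidate thresholds are midpoints between
// consecutive distinct sorted values. Ties between equal-gain splits keep
// the first candidate encountered (lowest feature column, then lowest
// threshold), making growth deterministic.
//
// Each feature's cell ordering is sorted once per tree and then split by
// stable partition at every node, so no per-node sorting is needed.

namespace {

struct TreeBuf {
  std::vector<int> gene;              // 0-based feature column, -1 for leaf
  std::vector<double> thr;
  std::vector<int> w;
  std::vector<int> left, right;       // 0-based node ids, -1 for none
  std::vector<std::vector<int>> counts;
};

inline double gini_from_sq(double sumsq, double w) {
  return 1.0 - sumsq / (w * w);
}

// order[f] holds the node's cells sorted by feature f (ascending, ties in
// the tree-wide presorted order, i.e. by cell index).
int grow(const double* X, int nrow, int P, const int* y, int K,
         std::vector<std::vector<int>>& order, TreeBuf& T) {
  const int node = static_cast<int>(T.gene.size());
  const int w = static_cast<int>(order[0].size());
  std::vector<int> cnt(K, 0);
  for (int i : order[0]) cnt[y[i]]++;
  T.gene.push_back(-1);
  T.thr.push_back(NA_REAL);
  T.w.push_back(w);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.counts.push_back(cnt);

  double sumsq = 0.0;
  for (int c : cnt) sumsq += static_cast<double>(c) * c;
  const double Ip = gini_from_sq(sumsq, w);
  if (Ip <= 0.0 || w < 2) return node;

  const double wIp = w * Ip;
  int bestF = -1;
  double bestThr = 0.0, bestGain = 0.0;
  std::vector<int> lc(K);

  for (int f = 0; f < P; ++f) {
    const double* col = X + static_cast<size_t>(f) * nrow;
    const std::vector<int>& ord = order[f];
    if (col[ord.front()] == col[ord.back()]) continue;  // constant feature
    std::fill(lc.begin(), lc.end(), 0);
    int wl = 0;
    for (int a = 0; a + 1 < w; ++a) {
      lc[y[ord[a]]]++;
      wl++;
      const double va = col[ord[a]], vb = col[ord[a + 1]];
      if (!(vb > va)) continue;                          // not a boundary
      const int wr = w - wl;
      double sl = 0.0, sr = 0.0;
      for (int c = 0; c < K; ++c) {
        sl += static_cast<double>(lc[c]) * lc[c];
        const double rcnt = cnt[c] - lc[c];
        sr += rcnt * rcnt;
      }
      const double gain = wIp - wl * gini_from_sq(sl, wl)
                              - wr * gini_from_sq(sr, wr);
      if (gain > bestGain + 1e-12) {
        bestGain = gain;
        bestF = f;
        // midpoint, clamped so cells <= thr (left) and > thr (right) are
        // both non-empty even when va and vb are adjacent doubles and the
        // midpoint rounds onto vb
        double mid = 0.5 * (va + vb);
        if (!(mid >= va && mid < vb)) mid = va;
        bestThr = mid;
      }
    }
  }
  if (bestF < 0 || bestGain <= 1e-12) return node;  // impure leaf (duplicates)

  const double* bcol = X + static_cast<size_t>(bestF) * nrow;
  std::vector<std::vector<int>> lorder(P), rorder(P);
  for (int f = 0; f < P; ++f) {
    lorder[f].reserve(w / 2);
    rorder[f].reserve(w / 2);
    for (int i : order[f]) {
      if (bcol[i] <= bestThr) lorder[f].push_back(i);
      else rorder[f].push_back(i);
    }
  }
  T.gene[node] = bestF;
  T.thr[node] = bestThr;
  { std::vector<std::vector<int>>().swap(order); }  // free before recursing
  T.left[node] = grow(X, nrow, P, y, K, lorder, T);
  { std::vector<std::vector<int>>().swap(lorder); }
  T.right[node] = grow(X, nrow, P, y, K, rorder, T);
  return node;
}

}  // namespace

// [[Rcpp::export]]
List build_tree_cpp(NumericMatrix X, IntegerVector y, int n_classes) {
  const int n = X.nrow();
  const int P = X.ncol();
  if (n < 1) stop("no cells");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= n_classes) stop("label out of range");

  const double* xp = X.begin();
  std::vector<std::vector<int>> order(P);
  for (int f = 0; f < P; ++f) {
    order[f].resize(n);
    for (int i = 0; i < n; ++i) order[f][i] = i;
    const double* col = xp + static_cast<size_t>(f) * n;
    std::stable_sort(order[f].begin(), order[f].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  TreeBuf T;
  std::vector<int> yv(y.begin(), y.end());
  grow(xp, n, P, yv.data(), n_classes, order, T);

  const int m = static_cast<int>(T.gene.size());
  IntegerVector gene(m), w(m), left(m), right(m);
  NumericVector thr(m);
  IntegerMatrix counts(m, n_classes);
  for (int a = 0; a < m; ++a) {
    gene[a] = T.gene[a] < 0 ? NA_INTEGER : T.gene[a] + 1;     // 1-based
    thr[a] = T.thr[a];
    w[a] = T.w[a];
    left[a] = T.left[a] < 0 ? NA_INTEGER : T.left[a] + 1;
    right[a] = T.right[a] < 0 ? NA_INTEGER : T.right[a] + 1;
    for (int c = 0; c < n_classes; ++c) counts(a, c) = T.counts[a][c];
  }
  return List::create(_["gene"] = gene, _["threshold"] = thr, _["w"] = w,
                      _["left"] = left, _["right"] = right,
                      _["class_counts"] = counts);
}
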
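// 3-d KD-tree for nearest-neighbour correspondence queries.
// Ties in distance are broken by the lowest reference index so that
// results are identical across platforms and traversal orders.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct KDTree {
  std::vector<double> pts;   // 3 * n, point i at pts[3*i .. 3*i+2]
  std::vector<int>    perm;  // node order: perm[k] is the point at tree slot k
  std::vector<int>    axis;  // split axis per tree slot
  int n;

  void build(int lo, int hi, int depth) {
    if (lo >= hi) return;
    // split on the axis of largest spread for balanced cells
    double mn[3] = { std::numeric_limits<double>::infinity(),
                     std::numeric_limits<double>::infinity(),
                     std::numeric_limits<double>::infinity() };
    double mx[3] = { -mn[0], -mn[1], -mn[2] };
    for (int k = lo; k < hi; ++k) {
      const double* p = &pts[3 * perm[k]];
      for (int d = 0; d < 3; ++d) {
        if (p[d] < mn[d]) mn[d] = p[d];
        if (p[d] > mx[d]) mx[d] = p[d];
      }
    }
    int ax = 0;
    double spread = mx[0] - mn[0];
    for (int d = 1; d < 3; ++d)
      if (mx[d] - mn[d] > spread) { spread = mx[d] - mn[d]; ax = d; }
    int mid = lo + (hi - lo) / 2;
    const std::vector<double>& P = pts;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&P, ax](int a, int b) {
                       double pa = P[3 * a + ax], pb = P[3 * b + ax];
                       if (pa != pb) return pa < pb;
                       return a < b;  // deterministic ordering of ties
                     });
    axis[mid] = ax;
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double* q, int lo, int hi,
             double& bestD2, int& bestIdx) const {
    if (lo >= hi) return;
    int mid = lo + (hi - lo) / 2;
    int id = perm[mid];
    const double* p = &pts[3 * id];
    double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestD2 || (d2 == bestD2 && id < bestIdx)) {
      bestD2 = d2;
      bestIdx = id;
    }
    int ax = axis[mid];
    double diff = q[ax] - p[ax];
    if (diff <= 0) {
      query(q, lo, mid, bestD2, bestIdx);
      if (diff * diff <= bestD2) query(q, mid + 1, hi, bestD2, bestIdx);
    } else {
      query(q, mid + 1, hi, bestD2, bestIdx);
      if (diff * diff <= bestD2) query(q, lo, mid, bestD2, bestIdx);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".kd_build")]]
SEXP kd_build(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("reference points must be an n x 3 matrix");
  int n = pts.nrow();
  if (n < 1) stop("reference point set is empty");
  XPtr<KDTree> tree(new KDTree(), true);
  tree->n = n;
  tree->pts.resize(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    tree->pts[3 * i]     = pts(i, 0);
    tree->pts[3 * i + 1] = pts(i, 1);
    tree->pts[3 * i + 2] = pts(i, 2);
  }
  tree->perm.resize(n);
  for (int i = 0; i < n; ++i) tree->perm[i] = i;
  tree->axis.assign(n, 0);
  tree->build(0, n, 0);
  return tree;
}

// [[Rcpp::export(name = ".kd_query")]]
List kd_query(SEXP treePtr, NumericMatrix query) {
  XPtr<KDTree> tree(treePtr);
  if (query.ncol() != 3) stop("query points must be an n x 3 matrix");
  int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double bestD2 = std::numeric_limits<double>::infinity();
    int bestIdx = tree->n;  // sentinel larger than any valid index
    tree->query(q, 0, tree->n, bestD2, bestIdx);
    idx[i] = bestIdx + 1;   // 1-based for R
    dist[i] = std::sqrt(bestD2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
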
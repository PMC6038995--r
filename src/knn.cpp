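#include <Rcpp.h>
#include "kdtree.h"

using namespace Rcpp;

// Flatten an n x 3 column-major R matrix into row-major xyz storage.
static std::vector<double> flatten_pts(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> out(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    out[3 * (size_t)i]     = m(i, 0);
    out[3 * (size_t)i + 1] = m(i, 1);
    out[3 * (size_t)i + 2] = m(i, 2);
  }
  return out;
}

// k nearest neighbours of each row of `query` among rows of `pts`.
// self_cloud = TRUE means query IS pts and each point excludes itself.
// Returns 1-based index matrix and distance matrix, sorted by (dist, index).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts, NumericMatrix query, int k, bool self_cloud) {
  std::vector<double> P = flatten_pts(pts);
  KDTree3 tree(P.data(), pts.nrow());
  int m = query.nrow();
  int kk = std::min(k, pts.nrow() - (self_cloud ? 1 : 0));
  if (kk < 0) kk = 0;
  IntegerMatrix idx(m, kk);
  NumericMatrix dist(m, kk);
  std::vector<int> oi;
  std::vector<double> od;
  for (int i = 0; i < m; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    tree.knn(q, kk, self_cloud ? i : -1, oi, od);
    for (int j = 0; j < kk; ++j) {
      idx(i, j) = oi[j] + 1;
      dist(i, j) = std::sqrt(od[j]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Distance from each row of `query` to its nearest neighbour in `pts`,
// +Inf when farther than `cutoff`. Also returns the 1-based neighbour index
// (NA beyond cutoff).
// [[Rcpp::export]]
List cpp_nn_dist(NumericMatrix query, NumericMatrix pts, double cutoff) {
  std::vector<double> P = flatten_pts(pts);
  KDTree3 tree(P.data(), pts.nrow());
  int m = query.nrow();
  NumericVector d(m);
  IntegerVector wi(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    int which = -1;
    d[i] = tree.nn_within(q, cutoff, -1, &which);
    wi[i] = which >= 0 ? which + 1 : NA_INTEGER;
  }
  return List::create(_["dist"] = d, _["idx"] = wi);
}
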
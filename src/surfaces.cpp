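#include <RcppArmadillo.h>
#include "kdtree.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static std::vector<double> flatten(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> out(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    out[3 * (size_t)i]     = m(i, 0);
    out[3 * (size_t)i + 1] = m(i, 1);
    out[3 * (size_t)i + 2] = m(i, 2);
  }
  return out;
}

// Local PCA smoothing: for each point p, take its k nearest neighbours
// (excluding p), set eta to the smallest-eigenvalue eigenvector of the
// neighbour covariance about the neighbour centroid, and shift p along eta by
// t = (centroid - p) . eta. This is the closed-form minimiser of
// sum_k ((x_k - (p + t eta)) . eta)^2 over unit eta and t.
// A point is flagged ambiguous when the two smallest covariance eigenvalues
// are equal within a relative gap of `gap_tol`.
// [[Rcpp::export]]
List cpp_smooth_normals(NumericMatrix pts, int k, double gap_tol) {
  int n = pts.nrow();
  std::vector<double> P = flatten(pts);
  KDTree3 tree(P.data(), n);
  NumericMatrix normal(n, 3), smoothed(n, 3);
  NumericVector shift(n);
  LogicalVector ambiguous(n);
  std::vector<int> oi;
  std::vector<double> od;
  arma::mat C(3, 3);
  arma::vec eigval(3);
  arma::mat eigvec(3, 3);
  for (int i = 0; i < n; ++i) {
    double q[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    tree.knn(q, k, i, oi, od);
    int m = (int)oi.size();
    double cx = 0, cy = 0, cz = 0;
    for (int j = 0; j < m; ++j) {
      const double* x = &P[3 * (size_t)oi[j]];
      cx += x[0]; cy += x[1]; cz += x[2];
    }
    cx /= m; cy /= m; cz /= m;
    C.zeros();
    for (int j = 0; j < m; ++j) {
      const double* x = &P[3 * (size_t)oi[j]];
      double dx = x[0] - cx, dy = x[1] - cy, dz = x[2] - cz;
      C(0, 0) += dx * dx; C(0, 1) += dx * dy; C(0, 2) += dx * dz;
      C(1, 1) += dy * dy; C(1, 2) += dy * dz; C(2, 2) += dz * dz;
    }
    C(1, 0) = C(0, 1); C(2, 0) = C(0, 2); C(2, 1) = C(1, 2);
    arma::eig_sym(eigval, eigvec, C);
    double denom = eigval(2) > 0 ? eigval(2) : 1.0;
    ambiguous[i] = ((eigval(1) - eigval(0)) / denom) < gap_tol;
    double ex = eigvec(0, 0), ey = eigvec(1, 0), ez = eigvec(2, 0);
    double t = (cx - q[0]) * ex + (cy - q[1]) * ey + (cz - q[2]) * ez;
    normal(i, 0) = ex; normal(i, 1) = ey; normal(i, 2) = ez;
    shift[i] = t;
    smoothed(i, 0) = q[0] + t * ex;
    smoothed(i, 1) = q[1] + t * ey;
    smoothed(i, 2) = q[2] + t * ez;
  }
  return List::create(_["normal"] = normal, _["shift"] = shift,
                      _["smoothed"] = smoothed, _["ambiguous"] = ambiguous);
}

// Consistent normal orientation: minimum spanning tree of the k-nearest
// neighbour graph (Euclidean edge weights), then sign propagation from each
// component root so that parent and child normals have positive dot product.
// Returns a +1/-1 sign per point; edges with exactly zero dot keep the child
// sign and are counted in `undecided`.
// [[Rcpp::export]]
List cpp_orient_mst(NumericMatrix pts, NumericMatrix normals, int kgraph) {
  int n = pts.nrow();
  std::vector<double> P = flatten(pts);
  KDTree3 tree(P.data(), n);
  int kk = std::min(kgraph, n - 1);
  // adjacency: union of i->knn(i) and reverse
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  std::vector<int> oi;
  std::vector<double> od;
  for (int i = 0; i < n; ++i) {
    double q[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    tree.knn(q, kk, i, oi, od);
    for (size_t j = 0; j < oi.size(); ++j) {
      double d = std::sqrt(od[j]);
      adj[i].push_back(std::make_pair(oi[j], d));
      adj[oi[j]].push_back(std::make_pair(i, d));
    }
  }
  IntegerVector sign(n, 0);
  int undecided = 0, components = 0;
  // Prim's MST per connected component, propagating signs as we attach nodes.
  typedef std::pair<double, std::pair<int, int> > Edge; // (w, (to, from))
  std::priority_queue<Edge, std::vector<Edge>, std::greater<Edge> > pq;
  for (int root = 0; root < n; ++root) {
    if (sign[root] != 0) continue;
    ++components;
    sign[root] = 1;
    for (size_t j = 0; j < adj[root].size(); ++j)
      pq.push(std::make_pair(adj[root][j].second,
                             std::make_pair(adj[root][j].first, root)));
    while (!pq.empty()) {
      Edge e = pq.top(); pq.pop();
      int v = e.second.first, u = e.second.second;
      if (sign[v] != 0) continue;
      double dot = normals(u, 0) * normals(v, 0) +
                   normals(u, 1) * normals(v, 1) +
                   normals(u, 2) * normals(v, 2);
      if (dot == 0.0) { ++undecided; sign[v] = sign[u]; }
      else sign[v] = dot > 0 ? sign[u] : -sign[u];
      for (size_t j = 0; j < adj[v].size(); ++j)
        if (sign[adj[v][j].first] == 0)
          pq.push(std::make_pair(adj[v][j].second,
                                 std::make_pair(adj[v][j].first, v)));
    }
  }
  return List::create(_["sign"] = sign, _["components"] = components,
                      _["undecided"] = undecided);
}

// Quadric fit + Weingarten mean curvature for every point of a smoothed,
// oriented cloud. In the local frame (t1, t2, eta) the height of the k nearest
// neighbours is fitted by z = a x + b y + c/2 x^2 + d x y + e/2 y^2 (least
// squares). Mean curvature follows the kappa = -n . d t / ds sign convention:
// kappa_m = -trace(II I^-1)/2 with E=1+a^2, F=ab, G=1+b^2 and
// L=c/s, M=d/s, N=e/s, s=sqrt(1+a^2+b^2). The normal is updated to
// eta - (a t1 + b t2)/s and renormalised.
// [[Rcpp::export]]
List cpp_quadric_curvature(NumericMatrix pts, NumericMatrix normals, int k,
                           double rcond_tol) {
  int n = pts.nrow();
  std::vector<double> P = flatten(pts);
  KDTree3 tree(P.data(), n);
  NumericVector kappa(n);
  NumericMatrix coef(n, 5), normal_upd(n, 3);
  LogicalVector ok(n);
  std::vector<int> oi;
  std::vector<double> od;
  arma::mat AtA(5, 5);
  arma::vec Atz(5), sol(5);
  for (int i = 0; i < n; ++i) {
    double q[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double eta[3] = { normals(i, 0), normals(i, 1), normals(i, 2) };
    // local tangent frame: pick the axis least aligned with eta
    int ax = 0;
    double amin = std::fabs(eta[0]);
    if (std::fabs(eta[1]) < amin) { amin = std::fabs(eta[1]); ax = 1; }
    if (std::fabs(eta[2]) < amin) { ax = 2; }
    double t1[3] = { 0, 0, 0 };
    t1[ax] = 1.0;
    double dp = t1[0] * eta[0] + t1[1] * eta[1] + t1[2] * eta[2];
    for (int c = 0; c < 3; ++c) t1[c] -= dp * eta[c];
    double nt = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
    for (int c = 0; c < 3; ++c) t1[c] /= nt;
    double t2[3] = { eta[1] * t1[2] - eta[2] * t1[1],
                     eta[2] * t1[0] - eta[0] * t1[2],
                     eta[0] * t1[1] - eta[1] * t1[0] };
    tree.knn(q, k, i, oi, od);
    int m = (int)oi.size();
    AtA.zeros();
    Atz.zeros();
    for (int j = 0; j < m; ++j) {
      const double* x = &P[3 * (size_t)oi[j]];
      double dx = x[0] - q[0], dy = x[1] - q[1], dz = x[2] - q[2];
      double u = dx * t1[0] + dy * t1[1] + dz * t1[2];
      double v = dx * t2[0] + dy * t2[1] + dz * t2[2];
      double w = dx * eta[0] + dy * eta[1] + dz * eta[2];
      double row[5] = { u, v, 0.5 * u * u, u * v, 0.5 * v * v };
      for (int a = 0; a < 5; ++a) {
        Atz(a) += row[a] * w;
        for (int b = a; b < 5; ++b) AtA(a, b) += row[a] * row[b];
      }
    }
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < a; ++b) AtA(a, b) = AtA(b, a);
    bool good = (m >= 5) && (arma::rcond(AtA) > rcond_tol);
    if (good) good = arma::solve(sol, AtA, Atz, arma::solve_opts::no_approx);
    ok[i] = good;
    if (!good) {
      kappa[i] = NA_REAL;
      for (int c = 0; c < 3; ++c) normal_upd(i, c) = eta[c];
      for (int a = 0; a < 5; ++a) coef(i, a) = NA_REAL;
      continue;
    }
    double a = sol(0), b = sol(1), cc = sol(2), dd = sol(3), ee = sol(4);
    coef(i, 0) = a; coef(i, 1) = b; coef(i, 2) = cc; coef(i, 3) = dd; coef(i, 4) = ee;
    double s = std::sqrt(1.0 + a * a + b * b);
    double E = 1 + a * a, F = a * b, G = 1 + b * b;
    double L = cc / s, M = dd / s, N = ee / s;
    double det = E * G - F * F;
    // trace(II I^-1) = (L G - 2 M F + N E)/det
    kappa[i] = -0.5 * (L * G - 2.0 * M * F + N * E) / det;
    double nu[3];
    for (int c = 0; c < 3; ++c) nu[c] = eta[c] - (a / s) * t1[c] - (b / s) * t2[c];
    double nn = std::sqrt(nu[0] * nu[0] + nu[1] * nu[1] + nu[2] * nu[2]);
    for (int c = 0; c < 3; ++c) normal_upd(i, c) = nu[c] / nn;
  }
  colnames(coef) = CharacterVector::create("a", "b", "c", "d", "e");
  return List::create(_["kappa"] = kappa, _["coef"] = coef,
                      _["normal"] = normal_upd, _["ok"] = ok);
}
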
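#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D volumes are column-major flat vectors with dims (nx, ny, nz);
// voxel (i,j,k) 0-based maps to i + nx*j + nx*ny*k. All neighbourhoods are
// 26-connected.

struct Grid {
  int nx, ny, nz;
  long long off[26]; // linear 26-neighbour offsets for interior voxels
  Grid(IntegerVector dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {
    int t = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          off[t++] = (long long)di + (long long)nx * dj +
            (long long)nx * ny * dk;
        }
  }
  inline size_t n() const { return (size_t)nx * ny * nz; }
  inline void ijk(size_t v, int& i, int& j, int& k) const {
    i = (int)(v % nx);
    j = (int)((v / nx) % ny);
    k = (int)(v / ((size_t)nx * ny));
  }
  template <typename F>
  inline void neighbours(size_t v, F f) const {
    int i, j, k;
    ijk(v, i, j, k);
    if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1) {
      for (int t = 0; t < 26; ++t) f((size_t)((long long)v + off[t]));
      return;
    }
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          if (di == 0 && dj == 0 && dk == 0) continue;
          f((size_t)ii + (size_t)nx * jj + (size_t)nx * ny * kk);
        }
      }
    }
  }
};

// Quantise probabilities in [0,1] to byte levels 0..(nlevels-1), nlevels<=256.
// [[Rcpp::export]]
RawVector cpp_quantize(NumericVector prob, int nlevels) {
  size_t n = prob.size();
  RawVector q(n);
  for (size_t v = 0; v < n; ++v) {
    double p = prob[v];
    int lev = (int)std::floor(p * (nlevels - 1) + 0.5);
    if (lev < 0) lev = 0;
    if (lev > nlevels - 1) lev = nlevels - 1;
    q[v] = (Rbyte)lev;
  }
  return q;
}

// Regional minima of a quantised landscape: 26-connected plateaus with no
// strictly lower neighbour. Returns component labels (1..n_min, 0 elsewhere).
// [[Rcpp::export]]
List cpp_regional_minima(RawVector q, IntegerVector dim) {
  Grid g(dim);
  size_t n = g.n();
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<char> visited(n, 0);
  int next = 0;
  std::vector<size_t> plateau;
  std::queue<size_t> bfs;
  for (size_t s = 0; s < n; ++s) {
    if (visited[s]) continue;
    int level = (int)q[s];
    plateau.clear();
    bool is_min = true;
    visited[s] = 1;
    bfs.push(s);
    while (!bfs.empty()) {
      size_t v = bfs.front(); bfs.pop();
      plateau.push_back(v);
      g.neighbours(v, [&](size_t w) {
        if ((int)q[w] == level) {
          if (!visited[w]) { visited[w] = 1; bfs.push(w); }
        } else if ((int)q[w] < level) {
          is_min = false;
        }
      });
    }
    if (is_min) {
      ++next;
      for (size_t t = 0; t < plateau.size(); ++t) lab[plateau[t]] = next;
    }
  }
  return List::create(_["labels"] = lab, _["n"] = next);
}

// Meyer's flooding watershed from seed labels on a quantised landscape.
// Voxels where two or more fronts meet become watershed-line voxels (-1).
// Unreached voxels (enclosed by lines) are also marked -1.
// [[Rcpp::export]]
IntegerVector cpp_watershed(RawVector q, IntegerVector seed, IntegerVector dim,
                            int nlevels) {
  Grid g(dim);
  size_t n = g.n();
  if (n > (size_t)std::numeric_limits<int>::max())
    stop("volume too large for the flooding queue");
  IntegerVector lab(n);
  std::vector<char> queued(n, 0);
  std::vector<std::queue<int> > buckets(nlevels);
  for (size_t v = 0; v < n; ++v) lab[v] = seed[v] > 0 ? seed[v] : 0;
  // prime queues with unlabelled neighbours of seeds
  for (size_t v = 0; v < n; ++v) {
    if (lab[v] <= 0) continue;
    g.neighbours(v, [&](size_t w) {
      if (lab[w] == 0 && !queued[w]) {
        queued[w] = 1;
        buckets[(int)q[w]].push((int)w);
      }
    });
  }
  for (int level = 0; level < nlevels; ++level) {
    std::queue<int>& Q = buckets[level];
    while (!Q.empty()) {
      size_t v = (size_t)Q.front(); Q.pop();
      if (lab[v] != 0) continue;
      int found = 0;
      bool multi = false;
      g.neighbours(v, [&](size_t w) {
        int lw = lab[w];
        if (lw > 0) {
          if (found == 0) found = lw;
          else if (found != lw) multi = true;
        }
      });
      if (multi) {
        lab[v] = -1;
      } else if (found > 0) {
        lab[v] = found;
        g.neighbours(v, [&](size_t w) {
          if (lab[w] == 0 && !queued[w]) {
            queued[w] = 1;
            int lev = (int)q[w] < level ? level : (int)q[w];
            buckets[lev].push((int)w);
          }
        });
      } else {
        // labelling neighbour turned into a line before this voxel popped;
        // re-examine at the current level once more
        lab[v] = 0;
        queued[v] = 0;
      }
    }
  }
  for (size_t v = 0; v < n; ++v)
    if (lab[v] == 0) lab[v] = -1;
  return lab;
}

// Classify watershed-line voxels by the distinct region labels in their
// 26-neighbourhood: exactly two -> membrane face voxel of that cell pair;
// three or more -> junction-candidate voxel (first three sorted labels kept).
// [[Rcpp::export]]
List cpp_face_classify(IntegerVector lab, IntegerVector dim) {
  Grid g(dim);
  size_t n = g.n();
  std::vector<int> fi, fj, fk, fa, fb;      // face voxels + pair
  std::vector<int> ji, jj, jk, j1, j2, j3, jn; // junction voxels + triple
  int orphan = 0;
  for (size_t v = 0; v < n; ++v) {
    if (lab[v] >= 0) continue;
    int labs[8];
    int nl = 0;
    g.neighbours(v, [&](size_t w) {
      int lw = lab[w];
      if (lw < 0) return;
      for (int t = 0; t < nl; ++t)
        if (labs[t] == lw) return;
      if (nl < 8) labs[nl++] = lw;
    });
    int i, j, k;
    g.ijk(v, i, j, k);
    if (nl == 2) {
      int a = labs[0], b = labs[1];
      if (a > b) std::swap(a, b);
      fi.push_back(i + 1); fj.push_back(j + 1); fk.push_back(k + 1);
      fa.push_back(a); fb.push_back(b);
    } else if (nl >= 3) {
      std::sort(labs, labs + nl);
      ji.push_back(i + 1); jj.push_back(j + 1); jk.push_back(k + 1);
      j1.push_back(labs[0]); j2.push_back(labs[1]); j3.push_back(labs[2]);
      jn.push_back(nl);
    } else {
      ++orphan;
    }
  }
  return List::create(
    _["face_i"] = wrap(fi), _["face_j"] = wrap(fj), _["face_k"] = wrap(fk),
    _["cell_a"] = wrap(fa), _["cell_b"] = wrap(fb),
    _["junc_i"] = wrap(ji), _["junc_j"] = wrap(jj), _["junc_k"] = wrap(jk),
    _["lab1"] = wrap(j1), _["lab2"] = wrap(j2), _["lab3"] = wrap(j3),
    _["nlab"] = wrap(jn), _["orphans"] = orphan);
}

// Per-region voxel count, centroid (voxel coordinates), border contact and
// mean landscape value, for regions labelled 1..nreg.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector lab, NumericVector prob, IntegerVector dim,
                     int nreg) {
  Grid g(dim);
  size_t n = g.n();
  NumericVector cnt(nreg), cx(nreg), cy(nreg), cz(nreg), psum(nreg);
  LogicalVector border(nreg);
  for (size_t v = 0; v < n; ++v) {
    int l = lab[v];
    if (l <= 0 || l > nreg) continue;
    int i, j, k;
    g.ijk(v, i, j, k);
    cnt[l - 1] += 1;
    cx[l - 1] += i + 0.5;
    cy[l - 1] += j + 0.5;
    cz[l - 1] += k + 0.5;
    psum[l - 1] += prob[v];
    if (i == 0 || j == 0 || k == 0 || i == g.nx - 1 || j == g.ny - 1 || k == g.nz - 1)
      border[l - 1] = true;
  }
  for (int r = 0; r < nreg; ++r) {
    if (cnt[r] > 0) {
      cx[r] /= cnt[r]; cy[r] /= cnt[r]; cz[r] /= cnt[r]; psum[r] /= cnt[r];
    }
  }
  return List::create(_["n_voxels"] = cnt, _["cx"] = cx, _["cy"] = cy,
                      _["cz"] = cz, _["mean_prob"] = psum, _["border"] = border);
}

// Rasterised membrane -> grayscale: intensity 1 at membrane voxels decaying
// linearly to 0 at `range` voxels (exact Euclidean distance to the voxel set,
// computed by local stamping).
// [[Rcpp::export]]
NumericVector cpp_stamp_distance(IntegerMatrix vox, IntegerVector dim, double range) {
  Grid g(dim);
  size_t n = g.n();
  NumericVector out(n);
  std::vector<float> d2(n, std::numeric_limits<float>::infinity());
  int r = (int)std::ceil(range);
  for (int t = 0; t < vox.nrow(); ++t) {
    int i0 = vox(t, 0) - 1, j0 = vox(t, 1) - 1, k0 = vox(t, 2) - 1;
    for (int dk = -r; dk <= r; ++dk) {
      int k = k0 + dk;
      if (k < 0 || k >= g.nz) continue;
      for (int dj = -r; dj <= r; ++dj) {
        int j = j0 + dj;
        if (j < 0 || j >= g.ny) continue;
        for (int di = -r; di <= r; ++di) {
          int i = i0 + di;
          if (i < 0 || i >= g.nx) continue;
          float dd = (float)(di * di + dj * dj + dk * dk);
          size_t v = (size_t)i + (size_t)g.nx * j + (size_t)g.nx * g.ny * k;
          if (dd < d2[v]) d2[v] = dd;
        }
      }
    }
  }
  for (size_t v = 0; v < n; ++v) {
    double dist = std::sqrt((double)d2[v]);
    double val = 1.0 - dist / range;
    out[v] = val > 0 ? val : 0.0;
  }
  return out;
}

// Boundary voxels of labelled components: labelled voxels with at least one
// differently-valued neighbour. Returns coordinates and labels.
// [[Rcpp::export]]
List cpp_component_boundaries(IntegerVector lab, IntegerVector dim) {
  Grid g(dim);
  size_t n = g.n();
  std::vector<int> bi, bj, bk, bl;
  for (size_t v = 0; v < n; ++v) {
    int l = lab[v];
    if (l <= 0) continue;
    bool boundary = false;
    g.neighbours(v, [&](size_t w) { if (lab[w] != l) boundary = true; });
    if (boundary) {
      int i, j, k;
      g.ijk(v, i, j, k);
      bi.push_back(i + 1); bj.push_back(j + 1); bk.push_back(k + 1);
      bl.push_back(l);
    }
  }
  return List::create(_["i"] = wrap(bi), _["j"] = wrap(bj), _["k"] = wrap(bk),
                      _["label"] = wrap(bl));
}


// Relabel positive region labels through a map (new = map[old], 1-based);
// non-positive labels pass through unchanged.
// [[Rcpp::export]]
IntegerVector cpp_apply_label_map(IntegerVector lab, IntegerVector map) {
  size_t n = lab.size();
  IntegerVector out(n);
  for (size_t v = 0; v < n; ++v) {
    int l = lab[v];
    out[v] = l > 0 ? map[l - 1] : l;
  }
  return out;
}
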
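#ifndef EMBRYOFORCE_KDTREE_H
#define EMBRYOFORCE_KDTREE_H

#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

// Minimal 3D KD-tree for k-nearest-neighbour and bounded nearest-distance
// queries. Ties in distance are broken by original point index so that all
// queries are deterministic regardless of build order.
class KDTree3 {
public:
  KDTree3(const double* pts, int n) : pts_(pts), n_(n) {
    idx_.resize(n_);
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    nodes_.reserve(std::max(1, 2 * n_ / LEAF + 4));
    if (n_ > 0) root_ = build(0, n_);
  }

  // k nearest neighbours of q; optionally exclude a specific point index
  // (the query point itself when querying within the same cloud).
  // Results are sorted by (distance, index) ascending.
  void knn(const double* q, int k, int exclude,
           std::vector<int>& out_idx, std::vector<double>& out_d2) const {
    Heap heap;
    if (n_ > 0) search(root_, q, k, exclude, heap);
    int m = (int)heap.size();
    out_idx.resize(m);
    out_d2.resize(m);
    for (int i = m - 1; i >= 0; --i) {
      out_d2[i] = heap.top().first;
      out_idx[i] = heap.top().second;
      heap.pop();
    }
  }

  // Distance to the nearest point, or +Inf if it exceeds `cutoff`.
  // Also reports the index of the nearest point (-1 if beyond cutoff).
  double nn_within(const double* q, double cutoff, int exclude, int* which) const {
    double best = cutoff * cutoff;
    int bi = -1;
    if (n_ > 0) nn_search(root_, q, exclude, best, bi);
    if (which) *which = bi;
    return bi >= 0 ? std::sqrt(best) : std::numeric_limits<double>::infinity();
  }

private:
  static const int LEAF = 16;
  struct Node {
    double bb[6];       // xmin,xmax,ymin,ymax,zmin,zmax
    int lo, hi;         // range in idx_ (leaf only used when left < 0)
    int left, right;
    int axis;
    double split;
  };
  // max-heap on (d2, idx): farthest current neighbour on top
  typedef std::priority_queue<std::pair<double, int> > Heap;

  const double* pts_;
  int n_;
  int root_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;

  inline double coord(int i, int ax) const { return pts_[3 * i + ax]; }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.bb[0] = nd.bb[2] = nd.bb[4] = std::numeric_limits<double>::infinity();
    nd.bb[1] = nd.bb[3] = nd.bb[5] = -std::numeric_limits<double>::infinity();
    for (int i = lo; i < hi; ++i) {
      for (int ax = 0; ax < 3; ++ax) {
        double v = coord(idx_[i], ax);
        if (v < nd.bb[2 * ax]) nd.bb[2 * ax] = v;
        if (v > nd.bb[2 * ax + 1]) nd.bb[2 * ax + 1] = v;
      }
    }
    int me = (int)nodes_.size();
    nodes_.push_back(nd);
    if (hi - lo > LEAF) {
      int ax = 0;
      double ext = nd.bb[1] - nd.bb[0];
      for (int a = 1; a < 3; ++a) {
        double e = nd.bb[2 * a + 1] - nd.bb[2 * a];
        if (e > ext) { ext = e; ax = a; }
      }
      int mid = (lo + hi) / 2;
      const double* p = pts_;
      std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                       [p, ax](int a, int b) {
                         double va = p[3 * a + ax], vb = p[3 * b + ax];
                         if (va != vb) return va < vb;
                         return a < b;
                       });
      nodes_[me].axis = ax;
      nodes_[me].split = coord(idx_[mid], ax);
      int l = build(lo, mid);
      int r = build(mid, hi);
      nodes_[me].left = l;
      nodes_[me].right = r;
    }
    return me;
  }

  static inline double bbdist2(const double* bb, const double* q) {
    double d2 = 0;
    for (int ax = 0; ax < 3; ++ax) {
      double v = q[ax];
      double d = 0;
      if (v < bb[2 * ax]) d = bb[2 * ax] - v;
      else if (v > bb[2 * ax + 1]) d = v - bb[2 * ax + 1];
      d2 += d * d;
    }
    return d2;
  }

  inline double pdist2(int i, const double* q) const {
    double dx = coord(i, 0) - q[0], dy = coord(i, 1) - q[1], dz = coord(i, 2) - q[2];
    return dx * dx + dy * dy + dz * dz;
  }

  void search(int ni, const double* q, int k, int exclude, Heap& heap) const {
    const Node& nd = nodes_[ni];
    if ((int)heap.size() == k && bbdist2(nd.bb, q) > heap.top().first) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int pi = idx_[i];
        if (pi == exclude) continue;
        double d2 = pdist2(pi, q);
        if ((int)heap.size() < k) {
          heap.push(std::make_pair(d2, pi));
        } else if (d2 < heap.top().first ||
                   (d2 == heap.top().first && pi < heap.top().second)) {
          heap.pop();
          heap.push(std::make_pair(d2, pi));
        }
      }
      return;
    }
    double dl = bbdist2(nodes_[nd.left].bb, q);
    double dr = bbdist2(nodes_[nd.right].bb, q);
    if (dl <= dr) {
      search(nd.left, q, k, exclude, heap);
      if ((int)heap.size() < k || dr <= heap.top().first)
        search(nd.right, q, k, exclude, heap);
    } else {
      search(nd.right, q, k, exclude, heap);
      if ((int)heap.size() < k || dl <= heap.top().first)
        search(nd.left, q, k, exclude, heap);
    }
  }

  void nn_search(int ni, const double* q, int exclude, double& best, int& bi) const {
    const Node& nd = nodes_[ni];
    if (bbdist2(nd.bb, q) > best) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int pi = idx_[i];
        if (pi == exclude) continue;
        double d2 = pdist2(pi, q);
        if (d2 < best || (d2 == best && (bi < 0 || pi < bi))) { best = d2; bi = pi; }
      }
      return;
    }
    double dl = bbdist2(nodes_[nd.left].bb, q);
    double dr = bbdist2(nodes_[nd.right].bb, q);
    if (dl <= dr) {
      nn_search(nd.left, q, exclude, best, bi);
      if (dr <= best) nn_search(nd.right, q, exclude, best, bi);
    } else {
      nn_search(nd.right, q, exclude, best, bi);
      if (dl <= best) nn_search(nd.left, q, exclude, best, bi);
    }
  }
};

#endif
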
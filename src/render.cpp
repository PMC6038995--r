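#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Probability-map renderers for the analytic fixtures. Every surface is a
// sphere cap or disk of an axisymmetric configuration (axis = x), so the 3D
// distance from a voxel centre to a surface equals the 2D distance in the
// meridian half-plane (x, rho). Probability is a Gaussian profile of the
// distance to the nearest membrane surface, exp(-d^2 / (2 blur^2)), set to
// exactly 0 beyond `cutoff` blur widths so that cell interiors and the
// exterior are flat zero plateaus.

static inline double circ_dist(double x, double rho, double xj, double d) {
  double dx = x - xj, dr = rho - d;
  return std::sqrt(dx * dx + dr * dr);
}

// distance to the cap of the sphere (cx,0,R) restricted by
// side * (qx - xj) <= 0  (side = +1: cap lies at x <= xj)
static inline double cap_dist(double x, double rho, double cx, double R,
                              double xj, double side, double d) {
  double r = std::sqrt((x - cx) * (x - cx) + rho * rho);
  if (r < 1e-12) return R;
  double qx = cx + (x - cx) * R / r;
  if (side * (qx - xj) <= 0) return std::fabs(r - R);
  return circ_dist(x, rho, xj, d);
}

// [[Rcpp::export]]
NumericVector cpp_render_two_cell(IntegerVector dim, double c1x, double c2x,
                                  double xj, double cy, double cz,
                                  double R1, double R2, double d,
                                  bool flat, double c3x, double R3, double s3,
                                  double blur, double cutoff) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double maxd = cutoff * blur;
  double inv2b2 = 1.0 / (2.0 * blur * blur);
  size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double z = k + 0.5 - cz;
    for (int j = 0; j < ny; ++j) {
      double y = j + 0.5 - cy;
      double rho = std::sqrt(y * y + z * z);
      for (int i = 0; i < nx; ++i, ++v) {
        double x = i + 0.5;
        double d1 = cap_dist(x, rho, c1x, R1, xj, +1.0, d);
        double d2 = cap_dist(x, rho, c2x, R2, xj, -1.0, d);
        double d3;
        if (flat) {
          d3 = rho <= d ? std::fabs(x - xj) : circ_dist(x, rho, xj, d);
        } else {
          // interface cap lies at s3 * (qx - xj) >= 0
          d3 = cap_dist(x, rho, c3x, R3, xj, -s3, d);
        }
        double dm = std::min(d1, std::min(d2, d3));
        out[v] = dm <= maxd ? std::exp(-dm * dm * inv2b2) : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_render_sphere(IntegerVector dim, double cx, double cy, double cz,
                                double R, double blur, double cutoff) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double maxd = cutoff * blur;
  double inv2b2 = 1.0 / (2.0 * blur * blur);
  size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double z = k + 0.5 - cz;
    for (int j = 0; j < ny; ++j) {
      double y = j + 0.5 - cy;
      for (int i = 0; i < nx; ++i, ++v) {
        double x = i + 0.5 - cx;
        double dm = std::fabs(std::sqrt(x * x + y * y + z * z) - R);
        out[v] = dm <= maxd ? std::exp(-dm * dm * inv2b2) : 0.0;
      }
    }
  }
  return out;
}

// Row of equal-radius, equal-pressure cells along x: Voronoi-restricted
// sphere caps plus flat disk interfaces at the midplanes of adjacent pairs.
// [[Rcpp::export]]
NumericVector cpp_render_cell_row(IntegerVector dim, NumericVector centers_x,
                                  double cy, double cz, double R,
                                  double blur, double cutoff) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nc = centers_x.size();
  NumericVector out((size_t)nx * ny * nz);
  double maxd = cutoff * blur;
  double inv2b2 = 1.0 / (2.0 * blur * blur);
  std::vector<double> mid(nc - 1), rc(nc - 1);
  for (int c = 0; c + 1 < nc; ++c) {
    mid[c] = 0.5 * (centers_x[c] + centers_x[c + 1]);
    double half = 0.5 * (centers_x[c + 1] - centers_x[c]);
    rc[c] = std::sqrt(std::max(0.0, R * R - half * half));
  }
  size_t v = 0;
  for (int k = 0; k < nz; ++k) {
    double z = k + 0.5 - cz;
    for (int j = 0; j < ny; ++j) {
      double y = j + 0.5 - cy;
      double rho = std::sqrt(y * y + z * z);
      for (int i = 0; i < nx; ++i, ++v) {
        double x = i + 0.5;
        double dm = std::numeric_limits<double>::infinity();
        for (int c = 0; c < nc; ++c) {
          double r = std::sqrt((x - centers_x[c]) * (x - centers_x[c]) + rho * rho);
          if (r < 1e-12) { dm = std::min(dm, R); continue; }
          double qx = centers_x[c] + (x - centers_x[c]) * R / r;
          bool valid = true;
          if (c > 0 && qx < mid[c - 1]) valid = false;
          if (c + 1 < nc && qx > mid[c]) valid = false;
          if (valid) dm = std::min(dm, std::fabs(r - R));
        }
        for (int c = 0; c + 1 < nc; ++c) {
          double dd = rho <= rc[c] ? std::fabs(x - mid[c])
                                   : circ_dist(x, rho, mid[c], rc[c]);
          dm = std::min(dm, dd);
        }
        out[v] = dm <= maxd ? std::exp(-dm * dm * inv2b2) : 0.0;
      }
    }
  }
  return out;
}

static inline double trilinear(const double* vol, const int* dim,
                               double x, double y, double z) {
  // voxel centre (i+0.5); clamp sample into the valid cell range
  double fx = x - 0.5, fy = y - 0.5, fz = z - 0.5;
  if (fx < 0) fx = 0; if (fx > dim[0] - 1.001) fx = dim[0] - 1.001;
  if (fy < 0) fy = 0; if (fy > dim[1] - 1.001) fy = dim[1] - 1.001;
  if (fz < 0) fz = 0; if (fz > dim[2] - 1.001) fz = dim[2] - 1.001;
  int i = (int)fx, j = (int)fy, k = (int)fz;
  double ax = fx - i, ay = fy - j, az = fz - k;
  size_t nx = dim[0], nxy = (size_t)dim[0] * dim[1];
  const double* base = vol + i + nx * j + nxy * k;
  double c00 = base[0] * (1 - ax) + base[1] * ax;
  double c10 = base[nx] * (1 - ax) + base[nx + 1] * ax;
  double c01 = base[nxy] * (1 - ax) + base[nxy + 1] * ax;
  double c11 = base[nxy + nx] * (1 - ax) + base[nxy + nx + 1] * ax;
  double c0 = c00 * (1 - ay) + c10 * ay;
  double c1 = c01 * (1 - ay) + c11 * ay;
  return c0 * (1 - az) + c1 * az;
}

// Sub-voxel crest refinement: move each membrane point along its normal to
// the quadratic-interpolated maximum of the probability profile sampled at
// -step, 0, +step. The move is clamped to +/- step.
// [[Rcpp::export]]
NumericMatrix cpp_crest_refine(NumericVector prob, IntegerVector dim,
                               NumericMatrix pts, NumericMatrix normals,
                               double step) {
  int n = pts.nrow();
  int d[3] = { dim[0], dim[1], dim[2] };
  const double* vol = REAL(prob);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double p0[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double nv[3] = { normals(i, 0), normals(i, 1), normals(i, 2) };
    double pm = trilinear(vol, d, p0[0] - step * nv[0], p0[1] - step * nv[1],
                          p0[2] - step * nv[2]);
    double pc = trilinear(vol, d, p0[0], p0[1], p0[2]);
    double pp = trilinear(vol, d, p0[0] + step * nv[0], p0[1] + step * nv[1],
                          p0[2] + step * nv[2]);
    double denom = pm - 2 * pc + pp;
    double t = 0.0;
    if (denom < -1e-12) t = 0.5 * (pm - pp) / denom * step;
    if (t > step) t = step;
    if (t < -step) t = -step;
    out(i, 0) = p0[0] + t * nv[0];
    out(i, 1) = p0[1] + t * nv[1];
    out(i, 2) = p0[2] + t * nv[2];
  }
  return out;
}
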
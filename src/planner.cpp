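// Compiled kernels for corridor collision testing.
//
// Conventions shared with the R side (and with the pure-R test oracle):
//  * voxel (i,j,k), 0-based here, has world center  origin + (i,j,k) * spacing
//  * a voxel belongs to a capsule iff the distance from its center to the
//    axis segment is <= radius (closed condition, ties collide)
//  * everything is in world mm; grids may be anisotropic

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double seg_dist2(const double px, const double py, const double pz,
                               const double ax, const double ay, const double az,
                               const double bx, const double by, const double bz) {
  // squared distance from point p to segment [a, b]
  const double vx = bx - ax, vy = by - ay, vz = bz - az;
  const double wx = px - ax, wy = py - ay, wz = pz - az;
  const double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0.0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  const double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(rng = false)]]
IntegerMatrix rasterize_capsule_cpp(IntegerVector dim, NumericVector spacing,
                                    NumericVector origin, NumericVector tip,
                                    NumericVector axis, double len, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double bx = tip[0] + len * axis[0];
  const double by = tip[1] + len * axis[1];
  const double bz = tip[2] + len * axis[2];
  const double r2 = radius * radius;

  int lo[3], hi[3];
  const double tipw[3] = {tip[0], tip[1], tip[2]};
  const double endw[3] = {bx, by, bz};
  const int dd[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    const double mn = std::min(tipw[a], endw[a]) - radius;
    const double mx = std::max(tipw[a], endw[a]) + radius;
    lo[a] = (int)std::floor((mn - origin[a]) / spacing[a]);
    hi[a] = (int)std::ceil((mx - origin[a]) / spacing[a]);
    if (lo[a] < 0) lo[a] = 0;
    if (hi[a] > dd[a] - 1) hi[a] = dd[a] - 1;
  }

  std::vector<int> out;
  for (int k = lo[2]; k <= hi[2]; ++k) {
    const double pz = origin[2] + k * spacing[2];
    for (int j = lo[1]; j <= hi[1]; ++j) {
      const double py = origin[1] + j * spacing[1];
      for (int i = lo[0]; i <= hi[0]; ++i) {
        const double px = origin[0] + i * spacing[0];
        if (seg_dist2(px, py, pz, tip[0], tip[1], tip[2], bx, by, bz) <= r2) {
          out.push_back(i + 1);
          out.push_back(j + 1);
          out.push_back(k + 1);
        }
      }
    }
  }
  const int n = (int)out.size() / 3;
  IntegerMatrix res(n, 3);
  for (int r = 0; r < n; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  return res;
}

// ---- exact Euclidean distance transform (squared), one dimension ----------
// Lower envelope of parabolas (Felzenszwalb & Huttenlocher), with physical
// sample spacing s so anisotropic grids give true mm distances.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double sint;
    while (true) {
      const double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector edt3d_cpp(LogicalVector forbidden, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite stand-in for "no site" keeps the parabola intersections
  // finite; any true squared distance on a physical grid is far below it
  const double INF = 1e12;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = forbidden[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t off = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
        for (int i = 0; i < nx; ++i) f[i] = g[off + i];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; ++i) g[off + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t off = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
        for (int j = 0; j < ny; ++j) f[j] = g[off + (R_xlen_t)j * nx];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; ++j) g[off + (R_xlen_t)j * nx] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t off = (R_xlen_t)i + (R_xlen_t)j * nx;
        for (int k = 0; k < nz; ++k) f[k] = g[off + (R_xlen_t)k * nx * ny];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; ++k) g[off + (R_xlen_t)k * nx * ny] = d[k];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i] >= 1e11 ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// ---- batched corridor feasibility -----------------------------------------
// A corridor collides iff some forbidden voxel center lies within `radius`
// of the axis segment.  The clearance map gives, at every voxel center, the
// exact distance to the nearest forbidden center; it is used only as a
// conservative prefilter (1-Lipschitz bound).  Ambiguous samples fall back
// to an exact local scan, so the result equals the brute-force rasterized
// check on every pose.
// [[Rcpp::export(rng = false)]]
LogicalVector check_corridors_cpp(NumericMatrix tips, NumericMatrix axes,
                                  NumericVector lens, double radius,
                                  NumericVector cmap, LogicalVector forb,
                                  IntegerVector dim, NumericVector spacing,
                                  NumericVector origin) {
  const int ncorr = tips.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double r2 = radius * radius;
  const double hmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  const double hstep = 0.5 * hmin;

  LogicalVector feasible(ncorr);
  for (int c = 0; c < ncorr; ++c) {
    const double ax0 = tips(c, 0), ay0 = tips(c, 1), az0 = tips(c, 2);
    const double ux = axes(c, 0), uy = axes(c, 1), uz = axes(c, 2);
    const double len = lens[c];
    const double bx = ax0 + len * ux, by = ay0 + len * uy, bz = az0 + len * uz;

    const int nseg = std::max(1, (int)std::ceil(len / hstep));
    const double step = len / nseg;      // actual sample spacing <= hstep
    const double slack = 0.5 * step;

    bool collides = false;
    for (int s = 0; s <= nseg && !collides; ++s) {
      const double t = step * s;
      const double px = ax0 + t * ux, py = ay0 + t * uy, pz = az0 + t * uz;
      // nearest voxel center (clamped to the grid)
      const int ci = std::min(std::max((int)std::lround((px - origin[0]) / spacing[0]), 0), nx - 1);
      const int cj = std::min(std::max((int)std::lround((py - origin[1]) / spacing[1]), 0), ny - 1);
      const int ck = std::min(std::max((int)std::lround((pz - origin[2]) / spacing[2]), 0), nz - 1);
      const double ex = px - (origin[0] + ci * spacing[0]);
      const double ey = py - (origin[1] + cj * spacing[1]);
      const double ez = pz - (origin[2] + ck * spacing[2]);
      const double ecc = std::sqrt(ex * ex + ey * ey + ez * ez);
      const double cm = cmap[(R_xlen_t)ci + (R_xlen_t)cj * nx + (R_xlen_t)ck * nx * ny];
      if (cm - ecc > radius + slack + 1e-9) continue;  // certainly clear here

      // exact local resolution: any forbidden center within `radius` of the
      // segment lies within radius + slack of its nearest sample point
      const double reach = radius + slack + 1e-9;
      int lo[3], hi[3];
      const double pw[3] = {px, py, pz};
      const int dd[3] = {nx, ny, nz};
      for (int a = 0; a < 3; ++a) {
        lo[a] = (int)std::floor((pw[a] - reach - origin[a]) / spacing[a]);
        hi[a] = (int)std::ceil((pw[a] + reach - origin[a]) / spacing[a]);
        if (lo[a] < 0) lo[a] = 0;
        if (hi[a] > dd[a] - 1) hi[a] = dd[a] - 1;
      }
      for (int k = lo[2]; k <= hi[2] && !collides; ++k)
        for (int j = lo[1]; j <= hi[1] && !collides; ++j) {
          const R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
          for (int i = lo[0]; i <= hi[0]; ++i) {
            if (!forb[base + i]) continue;
            const double qx = origin[0] + i * spacing[0];
            const double qy = origin[1] + j * spacing[1];
            const double qz = origin[2] + k * spacing[2];
            if (seg_dist2(qx, qy, qz, ax0, ay0, az0, bx, by, bz) <= r2) {
              collides = true;
              break;
            }
          }
        }
    }
    feasible[c] = !collides;
  }
  return feasible;
}

// Minimum distance from each axis segment to a fixed set of candidate points
// (world mm).  Used for clearance-based ranking.
// [[Rcpp::export(rng = false)]]
NumericVector min_seg_dist_cpp(NumericMatrix tips, NumericMatrix axes,
                               NumericVector lens, NumericMatrix pts) {
  const int ncorr = tips.nrow();
  const int npts = pts.nrow();
  NumericVector out(ncorr);
  for (int c = 0; c < ncorr; ++c) {
    const double ax0 = tips(c, 0), ay0 = tips(c, 1), az0 = tips(c, 2);
    const double len = lens[c];
    const double bx = ax0 + len * axes(c, 0);
    const double by = ay0 + len * axes(c, 1);
    const double bz = az0 + len * axes(c, 2);
    double best = R_PosInf;
    for (int p = 0; p < npts; ++p) {
      const double d2 = seg_dist2(pts(p, 0), pts(p, 1), pts(p, 2),
                                  ax0, ay0, az0, bx, by, bz);
      if (d2 < best) best = d2;
    }
    out[c] = std::sqrt(best);
  }
  return out;
}
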
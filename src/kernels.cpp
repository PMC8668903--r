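#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Finite stand-in for +infinity: keeps parabola intersections well defined
// (INF - INF would be NaN) while dwarfing any attainable squared distance.
static const double BIG = 1e20;
static const double ZINF = 1e30;

// 1D squared-distance transform of a sampled function (lower envelope of
// parabolas) on a grid with physical step w.
// f: input squared distances at positions w*0, w*1, ...; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -ZINF;
  z[1] = ZINF;
  for (int q = 1; q < n; q++) {
    double xq = w * q;
    double s;
    for (;;) {
      int p = v[k];
      double xp = w * p;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        k--;  // z[0] = -ZINF guarantees k >= 0 on exit
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZINF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = w * q;
    while (z[k + 1] < xq) k++;
    double dx = xq - w * v[k];
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform between voxel centres.
// mask: logical, column-major with x fastest (ix + nx*(iy + ny*iz)).
// spacing: physical step per axis (same units as the returned distances).
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double wx = spacing[0], wy = spacing[1], wz = spacing[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int iz = 0; iz < nz; iz++)
    for (int iy = 0; iy < ny; iy++) {
      R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = 0; ix < nx; ix++) f[ix] = out[base + ix];
      dt1d(f, d, nx, wx, v, z);
      for (int ix = 0; ix < nx; ix++) out[base + ix] = d[ix];
    }
  // pass along y
  for (int iz = 0; iz < nz; iz++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = ix + (R_xlen_t)nx * ny * iz;
      for (int iy = 0; iy < ny; iy++) f[iy] = out[base + (R_xlen_t)nx * iy];
      dt1d(f, d, ny, wy, v, z);
      for (int iy = 0; iy < ny; iy++) out[base + (R_xlen_t)nx * iy] = d[iy];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int iy = 0; iy < ny; iy++)
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = ix + (R_xlen_t)nx * iy;
      for (int iz = 0; iz < nz; iz++) f[iz] = out[base + nxy * iz];
      dt1d(f, d, nz, wz, v, z);
      for (int iz = 0; iz < nz; iz++) out[base + nxy * iz] = d[iz];
    }

  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  return out;
}

// Perpendicular physical distance from every voxel centre to the infinite
// line through `centre` with unit direction `dir`. Coordinates of voxel
// (ix,iy,iz) are ((ix+0.5)*sx, (iy+0.5)*sy, (iz+0.5)*sz); centre/dir/spacing
// share one physical unit.
// [[Rcpp::export]]
NumericVector line_perp_distance_cpp(IntegerVector dims, NumericVector spacing,
                                     NumericVector centre, NumericVector dir) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double cx = centre[0], cy = centre[1], cz = centre[2];
  double ax = dir[0], ay = dir[1], az = dir[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  R_xlen_t i = 0;
  for (int iz = 0; iz < nz; iz++) {
    double rz = (iz + 0.5) * sz - cz;
    for (int iy = 0; iy < ny; iy++) {
      double ry = (iy + 0.5) * sy - cy;
      for (int ix = 0; ix < nx; ix++, i++) {
        double rx = (ix + 0.5) * sx - cx;
        double t = rx * ax + ry * ay + rz * az;
        double d2 = rx * rx + ry * ry + rz * rz - t * t;
        out[i] = d2 > 0 ? std::sqrt(d2) : 0.0;
      }
    }
  }
  return out;
}

// 26-connected component labelling of a 3D logical mask.
// Returns integer labels, 0 = background, components numbered from 1 in
// scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector label_components26_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int iz = (int)(p / nxy);
      int rem = (int)(p - (R_xlen_t)iz * nxy);
      int iy = rem / nx;
      int ix = rem - iy * nx;
      for (int dz = -1; dz <= 1; dz++) {
        int jz = iz + dz;
        if (jz < 0 || jz >= nz) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int jy = iy + dy;
          if (jy < 0 || jy >= ny) continue;
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int jx = ix + dx;
            if (jx < 0 || jx >= nx) continue;
            R_xlen_t j = jx + (R_xlen_t)nx * jy + nxy * jz;
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              q.push(j);
            }
          }
        }
      }
    }
  }
  return lab;
}
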
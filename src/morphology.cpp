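#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite sentinel used instead of +Inf inside the lower-envelope
// recursion (Inf - Inf would poison the parabola intersections).
static const double BIG = 1e30;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), with physical sample spacing s.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    double sect;
    while (true) {
      double xv = v[k] * s;
      sect = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sect <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sect;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel of
// `mask`, respecting anisotropic voxel spacing. Voxels inside the mask get 0.
// An empty mask yields Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int xx = 0; xx < nx; xx++) f[xx] = out[base + xx];
      dt1d(f, d, v, z, nx, sx);
      for (int xx = 0; xx < nx; xx++) out[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; yy++) f[yy] = out[base + (R_xlen_t)yy * nx];
      dt1d(f, d, v, z, ny, sy);
      for (int yy = 0; yy < ny; yy++) out[base + (R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z
  const R_xlen_t slice = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + (R_xlen_t)zz * slice];
      dt1d(f, d, v, z, nz, sz);
      for (int zz = 0; zz < nz; zz++) out[base + (R_xlen_t)zz * slice] = d[zz];
    }

  for (R_xlen_t i = 0; i < n; i++) {
    double val = out[i];
    out[i] = (val >= BIG / 2.0) ? R_PosInf : std::sqrt(val);
  }
  return out;
}

static void neighbour_offsets(int connectivity, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  if (connectivity == 6) {
    int ox[6] = {1, -1, 0, 0, 0, 0};
    int oy[6] = {0, 0, 1, -1, 0, 0};
    int oz[6] = {0, 0, 0, 0, 1, -1};
    dx.assign(ox, ox + 6);
    dy.assign(oy, oy + 6);
    dz.assign(oz, oz + 6);
  } else { // 26
    for (int a = -1; a <= 1; a++)
      for (int b = -1; b <= 1; b++)
        for (int c = -1; c <= 1; c++) {
          if (a == 0 && b == 0 && c == 0) continue;
          dx.push_back(a);
          dy.push_back(b);
          dz.push_back(c);
        }
  }
}

// Label 3D connected components of a logical array (6- or 26-connectivity).
// Background voxels get 0, components 1..k in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();

  int current = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    current++;
    lab[i] = current;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int px = (int)(p % nx);
      int py = (int)((p / nx) % ny);
      int pz = (int)(p / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; k++) {
        int qx = px + dx[k], qy = py + dy[k], qz = pz + dz[k];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t pq = (R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx;
        if (mask[pq] && lab[pq] == 0) {
          lab[pq] = current;
          q.push(pq);
        }
      }
    }
  }
  return lab;
}

// Intensity-bounded region growing from seed voxels (0-based x,y,z rows).
// A voxel joins the region if reachable from a seed through voxels whose
// value lies in [lo, hi]; `allowed` (length 0 = everywhere) restricts growth.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector values, IntegerVector dim,
                              IntegerMatrix seeds, double lo, double hi,
                              int connectivity, LogicalVector allowed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const bool restrict_ = allowed.size() > 0;
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nn = (int)dx.size();

  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); s++) {
    R_xlen_t p = (R_xlen_t)seeds(s, 2) * nx * ny +
                 (R_xlen_t)seeds(s, 1) * nx + seeds(s, 0);
    if (out[p]) continue;
    if (values[p] < lo || values[p] > hi) continue;
    if (restrict_ && !allowed[p]) continue;
    out[p] = true;
    q.push(p);
  }
  while (!q.empty()) {
    R_xlen_t p = q.front();
    q.pop();
    int px = (int)(p % nx);
    int py = (int)((p / nx) % ny);
    int pz = (int)(p / ((R_xlen_t)nx * ny));
    for (int k = 0; k < nn; k++) {
      int qx = px + dx[k], qy = py + dy[k], qz = pz + dz[k];
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      R_xlen_t pq = (R_xlen_t)qz * nx * ny + (R_xlen_t)qy * nx + qx;
      if (out[pq]) continue;
      if (values[pq] < lo || values[pq] > hi) continue;
      if (restrict_ && !allowed[pq]) continue;
      out[pq] = true;
      q.push(pq);
    }
  }
  return out;
}
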
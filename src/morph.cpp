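// Grid morphology and geometry primitives.
//
// All volumes are passed as flat vectors with dims = (nz, ny, nx) and the
// z index fastest (R array with dim = c(nz, ny, nx)); linear index of voxel
// (z, y, x) is z + nz * (y + ny * x).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Large finite sentinel standing in for +Inf inside the envelope pass; far
// larger than any realistic squared distance in mm^2 yet safe to add to.
static const double DT_BIG = 1e20;

// 1D squared-distance lower-envelope pass (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -DT_BIG;
  zb[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    if (s <= zb[k]) { // k == 0 and still dominated: replace
      v[0] = q;
      zb[0] = -DT_BIG;
      zb[1] = DT_BIG;
    } else {
      ++k;
      v[k] = q;
      zb[k] = s;
      zb[k + 1] = DT_BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance (mm) from every voxel to the
// nearest TRUE voxel. spacing = (sz, sy, sx) in mm.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : DT_BIG;

  std::vector<double> f, d;
  // pass along z
  f.resize(nz); d.resize(nz);
  double wz = spacing[0] * spacing[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = D[lidx(z,y,x,nz,ny)];
      dt1d(f, d, nz, wz);
      for (int z = 0; z < nz; ++z) D[lidx(z,y,x,nz,ny)] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  double wy = spacing[1] * spacing[1];
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = D[lidx(z,y,x,nz,ny)];
      dt1d(f, d, ny, wy);
      for (int y = 0; y < ny; ++y) D[lidx(z,y,x,nz,ny)] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  double wx = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = D[lidx(z,y,x,nz,ny)];
      dt1d(f, d, nx, wx);
      for (int x = 0; x < nx; ++x) D[lidx(z,y,x,nz,ny)] = d[x];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    D[i] = (D[i] >= DT_BIG * 0.5) ? R_PosInf : std::sqrt(D[i]);
  return D;
}

// Connected-component labelling (connectivity 6 or 26). Labels 1..k in scan
// order of the first-seen voxel, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dz, dy, dx});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z,y,x,nz,ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % nz), rem = (int)(c / nz);
          int cy = rem % ny, cx = rem / ny;
          for (auto& o : offs) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = lidx(zz,yy,xx,nz,ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  return lab;
}

// Fill holes independently in each axial (fixed-z) slice: background pixels
// (4-connectivity within the slice) not connected to the slice border become
// foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_axial(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> outside((R_xlen_t)ny * nx);
  std::vector<std::pair<int,int>> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        if (!mask[lidx(z,y,x,nz,ny)] && !outside[y + (R_xlen_t)ny * x]) {
          outside[y + (R_xlen_t)ny * x] = 1;
          stack.push_back({y, x});
          while (!stack.empty()) {
            auto [cy, cx] = stack.back(); stack.pop_back();
            const int dy[4] = {1,-1,0,0}, dx[4] = {0,0,1,-1};
            for (int k = 0; k < 4; ++k) {
              int yy = cy + dy[k], xx = cx + dx[k];
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              R_xlen_t s = yy + (R_xlen_t)ny * xx;
              if (!mask[lidx(z,yy,xx,nz,ny)] && !outside[s]) {
                outside[s] = 1;
                stack.push_back({yy, xx});
              }
            }
          }
        }
      }
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if (!mask[lidx(z,y,x,nz,ny)] && !outside[y + (R_xlen_t)ny * x])
          out[lidx(z,y,x,nz,ny)] = true;
  }
  return out;
}

// Surface voxels: mask voxels with at least one 6-connected background
// neighbour; the grid edge counts as background.
// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out((R_xlen_t)nz * ny * nx, false);
  const int dz6[6] = {1,-1,0,0,0,0}, dy6[6] = {0,0,1,-1,0,0}, dx6[6] = {0,0,0,0,1,-1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z,y,x,nz,ny);
        if (!mask[i]) continue;
        for (int k = 0; k < 6; ++k) {
          int zz = z + dz6[k], yy = y + dy6[k], xx = x + dx6[k];
          bool bg = (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            ? true : !mask[lidx(zz,yy,xx,nz,ny)];
          if (bg) { out[i] = true; break; }
        }
      }
  return out;
}

// Closest pair between two point sets (rows = points, mm). Returns 1-based
// row indices and the distance; ties broken by lowest i then lowest j, so
// passing rows in voxel scan order makes the result deterministic.
// [[Rcpp::export]]
List cpp_closest_pair(NumericMatrix A, NumericMatrix B) {
  R_xlen_t na = A.nrow(), nb = B.nrow();
  double best = R_PosInf;
  R_xlen_t bi = 0, bj = 0;
  for (R_xlen_t i = 0; i < na; ++i) {
    double a0 = A(i,0), a1 = A(i,1), a2 = A(i,2);
    for (R_xlen_t j = 0; j < nb; ++j) {
      double d0 = a0 - B(j,0), d1 = a1 - B(j,1), d2 = a2 - B(j,2);
      double d = d0*d0 + d1*d1 + d2*d2;
      if (d < best - 1e-12) { best = d; bi = i; bj = j; }
    }
  }
  return List::create(_["distance"] = std::sqrt(best),
                      _["i"] = (double)(bi + 1), _["j"] = (double)(bj + 1));
}
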
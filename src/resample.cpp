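// Grid resampling under affine maps and displacement fields, plus point
// sampling. Same (nz, ny, nx), z-fastest layout as morph.cpp. World
// coordinates are (z, y, x) mm with world = origin + index * spacing.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Trilinear (or nearest) sample at continuous voxel index (fz, fy, fx);
// outside the grid returns `background`.
static double sample_vox(const NumericVector& vol, int nz, int ny, int nx,
                         double fz, double fy, double fx,
                         bool nearest, double background, bool clamp = false) {
  if (clamp) {
    fz = std::min(std::max(fz, 0.0), nz - 1.0);
    fy = std::min(std::max(fy, 0.0), ny - 1.0);
    fx = std::min(std::max(fx, 0.0), nx - 1.0);
  }
  if (nearest) {
    int z = (int)std::lround(fz), y = (int)std::lround(fy), x = (int)std::lround(fx);
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return background;
    return vol[lidx(z,y,x,nz,ny)];
  }
  if (fz < 0 || fz > nz - 1 || fy < 0 || fy > ny - 1 || fx < 0 || fx > nx - 1)
    return background;
  int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
  int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
  double tz = fz - z0, ty = fy - y0, tx = fx - x0;
  double c000 = vol[lidx(z0,y0,x0,nz,ny)], c100 = vol[lidx(z1,y0,x0,nz,ny)];
  double c010 = vol[lidx(z0,y1,x0,nz,ny)], c110 = vol[lidx(z1,y1,x0,nz,ny)];
  double c001 = vol[lidx(z0,y0,x1,nz,ny)], c101 = vol[lidx(z1,y0,x1,nz,ny)];
  double c011 = vol[lidx(z0,y1,x1,nz,ny)], c111 = vol[lidx(z1,y1,x1,nz,ny)];
  double c00 = c000 * (1 - tz) + c100 * tz;
  double c01 = c001 * (1 - tz) + c101 * tz;
  double c10 = c010 * (1 - tz) + c110 * tz;
  double c11 = c011 * (1 - tz) + c111 * tz;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tx) + c1 * tx;
}

// Resample `vol` onto an output grid. `A` (3x3, row-major) and `t` map each
// output-voxel world coordinate into the input volume's world frame.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector A, NumericVector t,
                                  IntegerVector odims, NumericVector ospacing,
                                  NumericVector oorigin,
                                  bool nearest, double background,
                                  bool clamp = false) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int oz = odims[0], oy = odims[1], ox = odims[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  for (int x = 0; x < ox; ++x)
    for (int y = 0; y < oy; ++y)
      for (int z = 0; z < oz; ++z) {
        double wz = oorigin[0] + z * ospacing[0];
        double wy = oorigin[1] + y * ospacing[1];
        double wx = oorigin[2] + x * ospacing[2];
        double iz = A[0]*wz + A[1]*wy + A[2]*wx + t[0];
        double iy = A[3]*wz + A[4]*wy + A[5]*wx + t[1];
        double ix = A[6]*wz + A[7]*wy + A[8]*wx + t[2];
        double fz = (iz - origin[0]) / spacing[0];
        double fy = (iy - origin[1]) / spacing[1];
        double fx = (ix - origin[2]) / spacing[2];
        out[lidx(z,y,x,oz,oy)] = sample_vox(vol, nz, ny, nx, fz, fy, fx, nearest, background, clamp);
      }
  return out;
}

// Sample a volume at world points (rows of `pts`, (z, y, x) mm).
// Outside the grid -> NA.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, bool nearest) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double fz = (pts(i,0) - origin[0]) / spacing[0];
    double fy = (pts(i,1) - origin[1]) / spacing[1];
    double fx = (pts(i,2) - origin[2]) / spacing[2];
    out[i] = sample_vox(vol, nz, ny, nx, fz, fy, fx, nearest, NA_REAL);
  }
  return out;
}

// Warp by a displacement field living on the same grid as `vol`:
// out(v) = vol(world(v) - u(v)), i.e. content at x is carried to x + u(x)
// to first order. uz/uy/ux in mm; voxels with valid == FALSE -> background.
// [[Rcpp::export]]
NumericVector cpp_warp_field(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector uz, NumericVector uy, NumericVector ux,
                             LogicalVector valid, bool nearest, double background) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z,y,x,nz,ny);
        if (!valid[i]) { out[i] = background; continue; }
        double fz = z - uz[i] / spacing[0];
        double fy = y - uy[i] / spacing[1];
        double fx = x - ux[i] / spacing[2];
        out[i] = sample_vox(vol, nz, ny, nx, fz, fy, fx, nearest, background);
      }
  return out;
}

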
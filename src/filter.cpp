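// Separable Gaussian smoothing and single-scale Hessian tubularity
// (Frangi-type) response. Same (nz, ny, nx), z-fastest layout as morph.cpp.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Reflecting boundary index.
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma_vox) {
  int r = (int)std::ceil(3.0 * sigma_vox);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

static void conv_axis(std::vector<double>& vol, int nz, int ny, int nx,
                      int axis, const std::vector<double>& ker) {
  int r = ((int)ker.size() - 1) / 2;
  int nvec = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(nvec);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) line[z] = vol[lidx(z,y,x,nz,ny)];
        for (int z = 0; z < nz; ++z) {
          double a = 0.0;
          for (int t = -r; t <= r; ++t) a += ker[t + r] * line[refl(z + t, nz)];
          vol[lidx(z,y,x,nz,ny)] = a;
        }
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) line[y] = vol[lidx(z,y,x,nz,ny)];
        for (int y = 0; y < ny; ++y) {
          double a = 0.0;
          for (int t = -r; t <= r; ++t) a += ker[t + r] * line[refl(y + t, ny)];
          vol[lidx(z,y,x,nz,ny)] = a;
        }
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) line[x] = vol[lidx(z,y,x,nz,ny)];
        for (int x = 0; x < nx; ++x) {
          double a = 0.0;
          for (int t = -r; t <= r; ++t) a += ker[t + r] * line[refl(x + t, nx)];
          vol[lidx(z,y,x,nz,ny)] = a;
        }
      }
  }
}

// Gaussian smoothing with per-axis sigma in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma_vox[axis] <= 0) continue;
    conv_axis(v, nz, ny, nx, axis, gauss_kernel(sigma_vox[axis]));
  }
  return NumericVector(v.begin(), v.end());
}

// Eigenvalues of a symmetric 3x3 matrix, analytic (trigonometric) method.
static void eig3(double a11, double a12, double a13,
                 double a22, double a23, double a33,
                 double& e1, double& e2, double& e3) {
  double p1 = a12*a12 + a13*a13 + a23*a23;
  if (p1 < 1e-30) {
    e1 = a11; e2 = a22; e3 = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11-q)*(a11-q) + (a22-q)*(a22-q) + (a33-q)*(a33-q) + 2.0*p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q)/p, b22 = (a22 - q)/p, b33 = (a33 - q)/p;
    double b12 = a12/p, b13 = a13/p, b23 = a23/p;
    double detB = b11*(b22*b33 - b23*b23) - b12*(b12*b33 - b23*b13)
                + b13*(b12*b23 - b22*b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    e1 = q + 2.0*p*std::cos(phi);
    e3 = q + 2.0*p*std::cos(phi + 2.0*M_PI/3.0);
    e2 = 3.0*q - e1 - e3;
  }
  // sort by |e| ascending
  double ev[3] = {e1, e2, e3};
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j)
      if (std::fabs(ev[j]) > std::fabs(ev[j+1])) std::swap(ev[j], ev[j+1]);
  e1 = ev[0]; e2 = ev[1]; e3 = ev[2];
}

// Frangi vesselness for bright tubes, single scale. `vol` must already be
// Gaussian-smoothed at that scale; spacing in mm; c <= 0 requests the
// data-driven default c = half the maximum Hessian Frobenius norm.
// [[Rcpp::export]]
NumericVector cpp_vesselness(NumericVector vol, IntegerVector dims,
                             NumericVector spacing,
                             double alpha, double beta, double c) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  std::vector<double> l1(n), l2(n), l3(n), S(n);
  double maxS = 0.0;

  auto at = [&](int z, int y, int x) -> double {
    return vol[lidx(refl(z,nz), refl(y,ny), refl(x,nx), nz, ny)];
  };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v0 = at(z,y,x);
        double hzz = (at(z+1,y,x) - 2*v0 + at(z-1,y,x)) / (sz*sz);
        double hyy = (at(z,y+1,x) - 2*v0 + at(z,y-1,x)) / (sy*sy);
        double hxx = (at(z,y,x+1) - 2*v0 + at(z,y,x-1)) / (sx*sx);
        double hzy = (at(z+1,y+1,x) - at(z+1,y-1,x) - at(z-1,y+1,x) + at(z-1,y-1,x)) / (4*sz*sy);
        double hzx = (at(z+1,y,x+1) - at(z+1,y,x-1) - at(z-1,y,x+1) + at(z-1,y,x-1)) / (4*sz*sx);
        double hyx = (at(z,y+1,x+1) - at(z,y+1,x-1) - at(z,y-1,x+1) + at(z,y-1,x-1)) / (4*sy*sx);
        double e1, e2, e3;
        eig3(hzz, hzy, hzx, hyy, hyx, hxx, e1, e2, e3);
        R_xlen_t i = lidx(z,y,x,nz,ny);
        l1[i] = e1; l2[i] = e2; l3[i] = e3;
        double s = std::sqrt(e1*e1 + e2*e2 + e3*e3);
        S[i] = s;
        if (s > maxS) maxS = s;
      }

  if (c <= 0) c = maxS > 0 ? maxS / 2.0 : 1.0;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double e1 = l1[i], e2 = l2[i], e3 = l3[i];
    if (e2 >= 0 || e3 >= 0) { out[i] = 0.0; continue; } // bright structures only
    double Ra = std::fabs(e2) / std::fabs(e3);
    double Rb = std::fabs(e1) / std::sqrt(std::fabs(e2 * e3));
    double v = (1.0 - std::exp(-Ra*Ra / (2*alpha*alpha)))
             * std::exp(-Rb*Rb / (2*beta*beta))
             * (1.0 - std::exp(-S[i]*S[i] / (2*c*c)));
    out[i] = v;
  }
  return out;
}
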
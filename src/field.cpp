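// Selective-control-point displacement-field machinery: DBSCAN over
// displacement vectors, per-voxel control-point subset selection, 3D
// thin-plate-spline (kernel U(r) = r) fitting/evaluation, and the strided
// field builder with subset-keyed fit caching.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Classic DBSCAN, O(n^2); labels: 0 = noise, 1..k = clusters.
static std::vector<int> dbscan_core(const arma::mat& X, double eps, int minpts) {
  int n = X.n_rows;
  std::vector<int> label(n, -1); // -1 unvisited, 0 noise
  double eps2 = eps * eps;
  auto neighbours = [&](int i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      double d = arma::accu(arma::square(X.row(i) - X.row(j)));
      if (d <= eps2) nb.push_back(j);
    }
    return nb;
  };
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (label[i] != -1) continue;
    std::vector<int> nb = neighbours(i);
    if ((int)nb.size() < minpts) { label[i] = 0; continue; }
    ++cl;
    label[i] = cl;
    std::vector<int> seeds = nb;
    for (size_t s = 0; s < seeds.size(); ++s) {
      int j = seeds[s];
      if (label[j] == 0) label[j] = cl;        // border point
      if (label[j] != -1) continue;
      label[j] = cl;
      std::vector<int> nb2 = neighbours(j);
      if ((int)nb2.size() >= minpts)
        seeds.insert(seeds.end(), nb2.begin(), nb2.end());
    }
  }
  return label;
}

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix X, double eps, int minpts) {
  arma::mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  std::vector<int> lab = dbscan_core(Xa, eps, minpts);
  return IntegerVector(lab.begin(), lab.end());
}

// TPS fit: src, dst are N x 3. Returns coefficient matrix (N+4) x 3:
// first N rows kernel weights, last 4 rows affine (1, z, y, x).
static arma::mat tps_solve(const arma::mat& src, const arma::mat& dst, double ridge) {
  int n = src.n_rows;
  arma::mat K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = ridge;
    for (int j = i + 1; j < n; ++j) {
      double r = arma::norm(src.row(i) - src.row(j), 2);
      K(i, j) = r;
      K(j, i) = r;
    }
  }
  arma::mat P(n, 4);
  P.col(0).ones();
  P.cols(1, 3) = src;
  arma::mat L(n + 4, n + 4, arma::fill::zeros);
  L.submat(0, 0, n - 1, n - 1) = K;
  L.submat(0, n, n - 1, n + 3) = P;
  L.submat(n, 0, n + 3, n - 1) = P.t();
  arma::mat rhs(n + 4, 3, arma::fill::zeros);
  rhs.rows(0, n - 1) = dst;
  arma::mat coef;
  bool ok = arma::solve(coef, L, rhs, arma::solve_opts::no_approx);
  if (!ok) {
    // degenerate (e.g. coplanar controls): regularized least-squares solve
    arma::mat LtL = L.t() * L;
    LtL.diag() += 1e-6;
    coef = arma::solve(LtL, L.t() * rhs);
  }
  return coef;
}

static arma::mat tps_apply(const arma::mat& src, const arma::mat& coef,
                           const arma::mat& query) {
  int n = src.n_rows, m = query.n_rows;
  arma::mat out(m, 3);
  for (int q = 0; q < m; ++q) {
    arma::rowvec acc = coef.row(n) + query(q, 0) * coef.row(n + 1)
      + query(q, 1) * coef.row(n + 2) + query(q, 2) * coef.row(n + 3);
    for (int i = 0; i < n; ++i) {
      double r = arma::norm(query.row(q) - src.row(i), 2);
      acc += r * coef.row(i);
    }
    out.row(q) = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tps_fit(NumericMatrix src, NumericMatrix dst, double ridge) {
  arma::mat s(src.begin(), src.nrow(), 3, false);
  arma::mat d(dst.begin(), dst.nrow(), 3, false);
  arma::mat coef = tps_solve(s, d, ridge);
  return wrap(coef);
}

// [[Rcpp::export]]
NumericMatrix cpp_tps_eval(NumericMatrix src, NumericMatrix coef, NumericMatrix query) {
  arma::mat s(src.begin(), src.nrow(), 3, false);
  arma::mat c(coef.begin(), coef.nrow(), 3, false);
  arma::mat q(query.begin(), query.nrow(), 3, false);
  return wrap(tps_apply(s, c, q));
}

// Control-point subset for one query position. Candidates are feature pairs
// whose post-operative point lies within radius R; DBSCAN groups them by
// displacement; the cluster whose mean member position is nearest the query
// wins (tie: larger cluster, then lower label). Falls back to the k nearest
// pairs when candidates are scarce or all noise. Returns 0-based indices.
static std::vector<int> select_cp(const arma::rowvec& voxel, const arma::mat& post_pts,
                                  const arma::mat& disp, double R, double eps,
                                  int minpts, int k_fallback, int max_control) {
  int n = post_pts.n_rows;
  std::vector<int> cand;
  std::vector<double> d2all(n);
  double R2 = R * R;
  for (int i = 0; i < n; ++i) {
    double d2 = arma::accu(arma::square(post_pts.row(i) - voxel));
    d2all[i] = d2;
    if (d2 <= R2) cand.push_back(i);
  }
  std::vector<int> chosen;
  if ((int)cand.size() >= minpts) {
    arma::mat D(cand.size(), 3);
    for (size_t i = 0; i < cand.size(); ++i) D.row(i) = disp.row(cand[i]);
    std::vector<int> lab = dbscan_core(D, eps, minpts);
    int ncl = 0;
    for (int l : lab) ncl = std::max(ncl, l);
    if (ncl > 0) {
      int best = -1, bestSize = 0;
      double bestDist = 0;
      for (int cl = 1; cl <= ncl; ++cl) {
        arma::rowvec mean(3, arma::fill::zeros);
        int sz = 0;
        for (size_t i = 0; i < cand.size(); ++i)
          if (lab[i] == cl) { mean += post_pts.row(cand[i]); ++sz; }
        if (sz == 0) continue;
        mean /= sz;
        double dist = arma::norm(mean - voxel, 2);
        if (best < 0 || dist < bestDist - 1e-9 ||
            (std::fabs(dist - bestDist) <= 1e-9 &&
             (sz > bestSize || (sz == bestSize && cl < best)))) {
          best = cl; bestDist = dist; bestSize = sz;
        }
      }
      for (size_t i = 0; i < cand.size(); ++i)
        if (lab[i] == best) chosen.push_back(cand[i]);
    }
  }
  if (chosen.empty()) {
    // k nearest feature pairs by position
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    int k = std::min(k_fallback, n);
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        if (d2all[a] != d2all[b]) return d2all[a] < d2all[b];
                        return a < b;
                      });
    chosen.assign(ord.begin(), ord.begin() + k);
  }
  if ((int)chosen.size() > max_control) {
    std::sort(chosen.begin(), chosen.end(), [&](int a, int b) {
      if (d2all[a] != d2all[b]) return d2all[a] < d2all[b];
      return a < b;
    });
    chosen.resize(max_control);
  }
  std::sort(chosen.begin(), chosen.end());
  return chosen;
}

// [[Rcpp::export]]
IntegerVector cpp_select_control_points(NumericVector voxel, NumericMatrix post_pts,
                                        NumericMatrix disp, double R, double eps,
                                        int minpts, int k_fallback, int max_control) {
  arma::rowvec v(3);
  v(0) = voxel[0]; v(1) = voxel[1]; v(2) = voxel[2];
  arma::mat P(post_pts.begin(), post_pts.nrow(), 3, false);
  arma::mat D(disp.begin(), disp.nrow(), 3, false);
  std::vector<int> idx = select_cp(v, P, D, R, eps, minpts, k_fallback, max_control);
  IntegerVector out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}

// Build the displacement field on a strided node lattice, nearest-upsampled
// to every domain voxel. post_pts/pre_pts in mm on the common (localized)
// grid; displacement u = f(x) - x with f the per-node selective TPS.
// [[Rcpp::export]]
List cpp_build_field(NumericMatrix post_pts, NumericMatrix pre_pts,
                     IntegerVector dims, NumericVector spacing, NumericVector origin,
                     LogicalVector domain, NumericVector tumor_centroid,
                     double dmax, double a, double eps, int minpts,
                     int k_fallback, int max_control, double ridge, int stride) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  arma::mat P(post_pts.begin(), post_pts.nrow(), 3, false);
  arma::mat Q(pre_pts.begin(), pre_pts.nrow(), 3, false);
  arma::mat D = Q - P;

  int gz = (nz + stride - 1) / stride;
  int gy = (ny + stride - 1) / stride;
  int gx = (nx + stride - 1) / stride;

  // which node cells contain domain voxels
  std::vector<char> cellActive((R_xlen_t)gz * gy * gx, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (domain[lidx(z,y,x,nz,ny)])
          cellActive[(z / stride) + (R_xlen_t)gz * ((y / stride) + (R_xlen_t)gy * (x / stride))] = 1;

  std::map<std::vector<int>, arma::mat> cache; // subset -> coefficients
  std::vector<double> nodeU((R_xlen_t)gz * gy * gx * 3, 0.0);

  arma::rowvec tc(3);
  tc(0) = tumor_centroid[0]; tc(1) = tumor_centroid[1]; tc(2) = tumor_centroid[2];

  for (int cx = 0; cx < gx; ++cx)
    for (int cy = 0; cy < gy; ++cy)
      for (int cz = 0; cz < gz; ++cz) {
        R_xlen_t ci = cz + (R_xlen_t)gz * (cy + (R_xlen_t)gy * cx);
        if (!cellActive[ci]) continue;
        // node position: centre of the cell, in world mm
        double vz = origin[0] + std::min(nz - 1.0, cz * stride + (stride - 1) / 2.0) * spacing[0];
        double vy = origin[1] + std::min(ny - 1.0, cy * stride + (stride - 1) / 2.0) * spacing[1];
        double vx = origin[2] + std::min(nx - 1.0, cx * stride + (stride - 1) / 2.0) * spacing[2];
        arma::rowvec v(3);
        v(0) = vz; v(1) = vy; v(2) = vx;
        double d = arma::norm(v - tc, 2);
        double R = 2.0 * dmax * std::exp(a * (d / dmax - 1.0));
        std::vector<int> idx = select_cp(v, P, D, R, eps, minpts, k_fallback, max_control);
        auto it = cache.find(idx);
        if (it == cache.end()) {
          arma::mat src(idx.size(), 3), dst(idx.size(), 3);
          for (size_t i = 0; i < idx.size(); ++i) {
            src.row(i) = P.row(idx[i]);
            dst.row(i) = Q.row(idx[i]);
          }
          it = cache.emplace(idx, tps_solve(src, dst, ridge)).first;
        }
        arma::mat src(idx.size(), 3);
        for (size_t i = 0; i < idx.size(); ++i) src.row(i) = P.row(idx[i]);
        arma::mat mapped = tps_apply(src, it->second, v);
        nodeU[ci * 3 + 0] = mapped(0, 0) - vz;
        nodeU[ci * 3 + 1] = mapped(0, 1) - vy;
        nodeU[ci * 3 + 2] = mapped(0, 2) - vx;
      }

  NumericVector uz(n), uy(n), ux(n);
  LogicalVector valid(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z,y,x,nz,ny);
        if (!domain[i]) { valid[i] = false; continue; }
        R_xlen_t ci = (z / stride) + (R_xlen_t)gz * ((y / stride) + (R_xlen_t)gy * (x / stride));
        uz[i] = nodeU[ci * 3 + 0];
        uy[i] = nodeU[ci * 3 + 1];
        ux[i] = nodeU[ci * 3 + 2];
        valid[i] = true;
      }
  return List::create(_["uz"] = uz, _["uy"] = uy, _["ux"] = ux, _["valid"] = valid);
}
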
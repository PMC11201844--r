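// Topology-preserving 3D thinning: iteratively deletes simple border voxels
// (object 26-connectivity, background 6-connectivity) in six directional
// subiterations until stable, keeping curve endpoints. Same z-fastest layout.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}
static inline int nb27(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

// Count 26-connected foreground components within the 26-neighbourhood
// (centre excluded).
static int count_fg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack{s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
            int t = zz + 3 * (yy + 3 * xx);
            if (t == 13 || seen[t] || !nb[t]) continue;
            seen[t] = true;
            stack.push_back(t);
          }
    }
  }
  return comps;
}

// Count 6-connected background components within the 18-neighbourhood that
// touch a 6-neighbour of the centre.
static int count_bg_components(const bool nb[27]) {
  auto in18 = [](int s) {
    int dz = s % 3 - 1, dy = (s / 3) % 3 - 1, dx = s / 9 - 1;
    int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
    return m == 1 || m == 2;
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18(s) || nb[s] || seen[s]) continue;
    int dz = s % 3 - 1, dy = (s / 3) % 3 - 1, dx = s / 9 - 1;
    if (std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue; // seed at 6-neighbours
    ++comps;
    std::vector<int> stack{s};
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto& d : d6) {
        int zz = cz + d[0], yy = cy + d[1], xx = cx + d[2];
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int t = zz + 3 * (yy + 3 * xx);
        if (!in18(t) || seen[t] || nb[t]) continue;
        seen[t] = true;
        stack.push_back(t);
      }
    }
  }
  return comps;
}

static void fill_nb(const std::vector<char>& M, int nz, int ny, int nx,
                    int z, int y, int x, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          ? (M[lidx(zz,yy,xx,nz,ny)] != 0) : false;
        nb[nb27(dz,dy,dx)] = v;
      }
}

static bool is_simple(const bool nb[27]) {
  return count_fg_components(nb) == 1 && count_bg_components(nb) == 1;
}

static int n_fg_neighbours(const bool nb[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> M(n);
  for (R_xlen_t i = 0; i < n; ++i) M[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto& d : dirs) {
      // collect border candidates for this direction
      std::vector<R_xlen_t> cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t i = lidx(z,y,x,nz,ny);
            if (!M[i]) continue;
            int zz = z + d[0], yy = y + d[1], xx = x + d[2];
            bool bg = (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              ? true : (M[lidx(zz,yy,xx,nz,ny)] == 0);
            if (bg) cand.push_back(i);
          }
      // sequential deletion with re-check keeps topology exact
      for (R_xlen_t i : cand) {
        int z = (int)(i % nz), rem = (int)(i / nz);
        int y = rem % ny, x = rem / ny;
        fill_nb(M, nz, ny, nx, z, y, x, nb);
        if (n_fg_neighbours(nb) <= 1) continue; // endpoint: keep
        if (is_simple(nb)) {
          M[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = M[i] != 0;
  return out;
}
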
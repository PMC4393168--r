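#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Homotopic 3D curve thinning: iterative sequential removal of simple border
// points (26-connected foreground, 6-connected background), with 6
// directional sub-iterations per pass for centering and preservation of
// curve endpoints (exactly one 26-neighbor).

// Offsets of the 3x3x3 cube, indexed c = (dz+1) + 3*(dy+1) + 9*(dx+1),
// center at c = 13.

static inline int cube_index(int dx, int dy, int dz) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// number of 26-connected components of foreground in N26 (cube minus center)
static int t26_fg(const bool* cube) {
  bool seen[27] = {false};
  int comp = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !cube[c] || seen[c]) continue;
    ++comp;
    int stack[27], sp = 0;
    stack[sp++] = c;
    seen[c] = true;
    while (sp) {
      int cur = stack[--sp];
      int x = cur / 9 - 1, y = (cur / 3) % 3 - 1, z = cur % 3 - 1;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1) continue;
            int nc = cube_index(nx, ny, nz);
            if (nc == 13 || seen[nc] || !cube[nc]) continue;
            seen[nc] = true;
            stack[sp++] = nc;
          }
    }
  }
  return comp;
}

// number of 6-connected components of background within the 18-neighborhood
// that touch a 6-neighbor of the center
static int t6_bg(const bool* cube) {
  // cells of N18: |dx|+|dy|+|dz| in {1,2}
  bool in18[27], seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    int x = c / 9 - 1, y = (c / 3) % 3 - 1, z = c % 3 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[c] = (m == 1 || m == 2);
  }
  int comp = 0;
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int c = 0; c < 27; ++c) {
    if (!in18[c] || cube[c] || seen[c]) continue;
    int x0 = c / 9 - 1, y0 = (c / 3) % 3 - 1, z0 = c % 3 - 1;
    if (std::abs(x0) + std::abs(y0) + std::abs(z0) != 1) continue; // grow from 6-nbrs only
    ++comp;
    int stack[27], sp = 0;
    stack[sp++] = c;
    seen[c] = true;
    while (sp) {
      int cur = stack[--sp];
      int x = cur / 9 - 1, y = (cur / 3) % 3 - 1, z = cur % 3 - 1;
      for (int t = 0; t < 6; ++t) {
        int nx = x + d6[t][0], ny = y + d6[t][1], nz = z + d6[t][2];
        if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1) continue;
        int nc = cube_index(nx, ny, nz);
        if (!in18[nc] || seen[nc] || cube[nc]) continue;
        seen[nc] = true;
        stack[sp++] = nc;
      }
    }
  }
  return comp;
}

static inline bool get_cube(const std::vector<char>& img, int n1, int n2, int n3,
                            int i, int j, int k, bool* cube) {
  int nfg = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int ii = i + dx, jj = j + dy, kk = k + dz;
        bool v = false;
        if (ii >= 0 && jj >= 0 && kk >= 0 && ii < n1 && jj < n2 && kk < n3)
          v = img[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2] != 0;
        cube[cube_index(dx, dy, dz)] = v;
        if (v && !(dx == 0 && dy == 0 && dz == 0)) ++nfg;
      }
  return nfg == 1; // endpoint
}

static inline bool is_simple(const bool* cube) {
  return t26_fg(cube) == 1 && t6_bg(cube) == 1;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims, int max_iter) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> img(N);
  for (R_xlen_t i = 0; i < N; ++i) img[i] = mask[i] ? 1 : 0;

  const int dir[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool cube[27];
  std::vector<R_xlen_t> cand;
  for (int iter = 0; iter < max_iter; ++iter) {
    R_xlen_t removed = 0;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            R_xlen_t idx = i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
            if (!img[idx]) continue;
            int ii = i + dir[d][0], jj = j + dir[d][1], kk = k + dir[d][2];
            bool bg = true;
            if (ii >= 0 && jj >= 0 && kk >= 0 && ii < n1 && jj < n2 && kk < n3)
              bg = img[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2] == 0;
            if (!bg) continue;
            bool endpoint = get_cube(img, n1, n2, n3, i, j, k, cube);
            if (endpoint) continue;
            if (is_simple(cube)) cand.push_back(idx);
          }
      // sequential re-check so each deletion stays topology-preserving
      for (R_xlen_t c = 0; c < (R_xlen_t)cand.size(); ++c) {
        R_xlen_t idx = cand[c];
        int i = (int)(idx % n1), j = (int)((idx / n1) % n2), k = (int)(idx / ((R_xlen_t)n1 * n2));
        bool endpoint = get_cube(img, n1, n2, n3, i, j, k, cube);
        if (endpoint) continue;
        if (is_simple(cube)) {
          img[idx] = 0;
          ++removed;
        }
      }
    }
    if (removed == 0) break;
  }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = img[i] != 0;
  return out;
}

// 26-neighbor count within a logical volume, for skeleton degree fields.
// [[Rcpp::export]]
IntegerVector neighbor_count26_cpp(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(N);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
        if (!mask[idx]) { out[idx] = NA_INTEGER; continue; }
        int cnt = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
              if (mask[ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2]) ++cnt;
            }
        out[idx] = cnt;
      }
  return out;
}
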
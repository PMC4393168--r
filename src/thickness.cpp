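#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along each axis.

static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance from each voxel to the nearest zero (background) voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(N);
  const double BIG = 1e20;
  for (R_xlen_t i = 0; i < N; ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
      for (int i = 0; i < n1; ++i) f[i] = g[base + i];
      edt_1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) g[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * n1 * n2;
      for (int j = 0; j < n2; ++j) f[j] = g[base + (R_xlen_t)j * n1];
      edt_1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)j * n1] = d[j];
    }
  // axis 3
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * n1;
      for (int k = 0; k < n3; ++k) f[k] = g[base + (R_xlen_t)k * plane];
      edt_1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) g[base + (R_xlen_t)k * plane] = d[k];
    }
  return NumericVector(g.begin(), g.end());
}

// Local thickness in voxel units: for each foreground voxel, the diameter
// (2*dt, dt = center-to-nearest-background-voxel distance) of the largest
// inscribed sphere covering it, the usual convention of distance-ridge
// structure-thickness mapping: a tube rasterized at nominal diameter d
// measures ~d (an isolated voxel measures 2). Distance-ridge reduction
// followed by sphere painting.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector dt2 = edt_sq_cpp(mask, dims);
  std::vector<double> dt(N);
  for (R_xlen_t i = 0; i < N; ++i) dt[i] = std::sqrt(dt2[i]);

  // ridge: drop voxels whose inscribed ball lies inside a neighbor's ball
  std::vector<R_xlen_t> ridge;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
        if (!mask[idx]) continue;
        double r = dt[idx];
        bool maximal = true;
        for (int dk = -1; dk <= 1 && maximal; ++dk)
          for (int dj = -1; dj <= 1 && maximal; ++dj)
            for (int di = -1; di <= 1 && maximal; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
              R_xlen_t nb = ii + (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2;
              double step = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (dt[nb] >= r + step - 1e-9) maximal = false;
            }
        if (maximal) ridge.push_back(idx);
      }

  std::sort(ridge.begin(), ridge.end(),
            [&](R_xlen_t a, R_xlen_t b) { return dt[a] > dt[b]; });

  NumericVector th(N, 0.0);
  for (R_xlen_t rp = 0; rp < (R_xlen_t)ridge.size(); ++rp) {
    R_xlen_t idx = ridge[rp];
    double r = dt[idx];
    double val = 2.0 * r;
    double cover = r - 0.5;          // ball radius in voxel-center units
    int ic = (int)(idx % n1), jc = (int)((idx / n1) % n2), kc = (int)(idx / ((R_xlen_t)n1 * n2));
    int rad = (int)std::floor(cover + 1e-9);
    double cov2 = cover * cover + 1e-9;
    for (int dk = -rad; dk <= rad; ++dk) {
      int kk = kc + dk;
      if (kk < 0 || kk >= n3) continue;
      for (int dj = -rad; dj <= rad; ++dj) {
        int jj = jc + dj;
        if (jj < 0 || jj >= n2) continue;
        double d2p = (double)dk * dk + (double)dj * dj;
        if (d2p > cov2) continue;
        int rem = (int)std::floor(std::sqrt(cov2 - d2p));
        int lo = std::max(0, ic - rem), hi = std::min(n1 - 1, ic + rem);
        R_xlen_t base = (R_xlen_t)jj * n1 + (R_xlen_t)kk * n1 * n2;
        for (int ii = lo; ii <= hi; ++ii) {
          R_xlen_t q = base + ii;
          if (mask[q] && th[q] < val) th[q] = val;
        }
      }
    }
  }
  return th;
}
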
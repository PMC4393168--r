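#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinate (x,y,z);
// outside the lattice -> 0.
static inline double interp3(const double* v, int n1, int n2, int n3,
                             double x, double y, double z, bool& inside) {
  if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, n1 - 1), y1 = std::min(y0 + 1, n2 - 1), z1 = std::min(z0 + 1, n3 - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  #define V(i, j, k) v[(i) + (R_xlen_t)(j) * n1 + (R_xlen_t)(k) * plane]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample through the affine source map p_src = A p_out + b (0-based voxel
// coordinates). A is a 3x3 matrix (column-major), b length 3.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector A, NumericVector b) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  const double* v = REAL(vol);
  bool identity = std::fabs(A[0] - 1) < 1e-15 && std::fabs(A[4] - 1) < 1e-15 &&
    std::fabs(A[8] - 1) < 1e-15 && std::fabs(A[1]) < 1e-15 && std::fabs(A[2]) < 1e-15 &&
    std::fabs(A[3]) < 1e-15 && std::fabs(A[5]) < 1e-15 && std::fabs(A[6]) < 1e-15 &&
    std::fabs(A[7]) < 1e-15 && std::fabs(b[0]) < 1e-15 && std::fabs(b[1]) < 1e-15 &&
    std::fabs(b[2]) < 1e-15;
  if (identity) {
    for (R_xlen_t i = 0; i < N; ++i) out[i] = v[i];
    return out;
  }
  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++idx) {
        double sx = A[0] * i + A[3] * j + A[6] * k + b[0];
        double sy = A[1] * i + A[4] * j + A[7] * k + b[1];
        double sz = A[2] * i + A[5] * j + A[8] * k + b[2];
        bool inside;
        out[idx] = interp3(v, n1, n2, n3, sx, sy, sz, inside);
      }
  return out;
}

// Joint intensity histogram between a fixed volume and a moving volume
// evaluated through the affine source map, on a strided voxel subsample.
// Only samples whose mapped coordinate falls inside the moving lattice
// contribute. Bin b = floor((val - lo) / (hi - lo) * bins), clipped.
// [[Rcpp::export]]
NumericMatrix joint_hist_cpp(NumericVector fixed, NumericVector moving,
                             IntegerVector dims, NumericVector A, NumericVector b,
                             int bins, int stride,
                             double flo, double fhi, double mlo, double mhi) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericMatrix H(bins, bins);
  const double* fv = REAL(fixed);
  const double* mv = REAL(moving);
  double fscale = bins / std::max(fhi - flo, 1e-12);
  double mscale = bins / std::max(mhi - mlo, 1e-12);
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int k = 0; k < n3; k += stride)
    for (int j = 0; j < n2; j += stride)
      for (int i = 0; i < n1; i += stride) {
        double sx = A[0] * i + A[3] * j + A[6] * k + b[0];
        double sy = A[1] * i + A[4] * j + A[7] * k + b[1];
        double sz = A[2] * i + A[5] * j + A[8] * k + b[2];
        bool inside;
        double m = interp3(mv, n1, n2, n3, sx, sy, sz, inside);
        if (!inside) continue;
        double f = fv[i + (R_xlen_t)j * n1 + (R_xlen_t)k * plane];
        int bf = (int)((f - flo) * fscale);
        int bm = (int)((m - mlo) * mscale);
        if (bf < 0) bf = 0; if (bf >= bins) bf = bins - 1;
        if (bm < 0) bm = 0; if (bm >= bins) bm = bins - 1;
        H(bf, bm) += 1.0;
      }
  return H;
}

// Rasterize capped cylinders (tubes): segs is n x 7 with columns
// p1x p1y p1z p2x p2y p2z radius, all in continuous 0-based voxel units.
// A voxel is foreground when its center lies within radius of the segment.
// [[Rcpp::export]]
LogicalVector rasterize_tubes_cpp(IntegerVector dims, NumericMatrix segs) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector mask(N);
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int s = 0; s < segs.nrow(); ++s) {
    double p1[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double p2[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    double r = segs(s, 6);
    double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double len2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::max(0, (int)std::floor(std::min(p1[a], p2[a]) - r - 1));
      int nmax = (a == 0 ? n1 : (a == 1 ? n2 : n3)) - 1;
      hi[a] = std::min(nmax, (int)std::ceil(std::max(p1[a], p2[a]) + r + 1));
    }
    double r2 = r * r;
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double w[3] = {i - p1[0], j - p1[1], k - p1[2]};
          double t = 0.0;
          if (len2 > 1e-12) {
            t = (w[0] * d[0] + w[1] * d[1] + w[2] * d[2]) / len2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double dx = w[0] - t * d[0], dy = w[1] - t * d[1], dz = w[2] - t * d[2];
          if (dx * dx + dy * dy + dz * dz <= r2)
            mask[i + (R_xlen_t)j * n1 + (R_xlen_t)k * plane] = true;
        }
  }
  return mask;
}
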
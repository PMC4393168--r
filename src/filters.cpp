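#include <Rcpp.h>
using namespace Rcpp;

// Separable 3D box filters. Arrays are column-major with dim = (n1, n2, n3);
// borders are truncated (the window is clipped to the lattice), which keeps
// the mean filter constant-preserving everywhere.

static void box_pass_max(const std::vector<double>& src, std::vector<double>& dst,
                         int n1, int n2, int n3, int axis, int r) {
  int n[3] = {n1, n2, n3};
  int stride[3] = {1, n1, n1 * n2};
  int len = n[axis], st = stride[axis];
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a = 0; a < n[oa]; ++a) {
      R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < len; ++i) {
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        double m = src[base + (R_xlen_t)lo * st];
        for (int k = lo + 1; k <= hi; ++k)
          m = std::max(m, src[base + (R_xlen_t)k * st]);
        dst[base + (R_xlen_t)i * st] = m;
      }
    }
  }
}

static void box_pass_sum(const std::vector<double>& src, std::vector<double>& dst,
                         std::vector<double>& cnt_in, std::vector<double>& cnt_out,
                         int n1, int n2, int n3, int axis, int r) {
  int n[3] = {n1, n2, n3};
  int stride[3] = {1, n1, n1 * n2};
  int len = n[axis], st = stride[axis];
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a = 0; a < n[oa]; ++a) {
      R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < len; ++i) {
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        double s = 0, c = 0;
        for (int k = lo; k <= hi; ++k) {
          s += src[base + (R_xlen_t)k * st];
          c += cnt_in[base + (R_xlen_t)k * st];
        }
        dst[base + (R_xlen_t)i * st] = s;
        cnt_out[base + (R_xlen_t)i * st] = c;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector max_filter3d_cpp(NumericVector vol, IntegerVector dims, int radius) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(vol.begin(), vol.end()), b(N);
  box_pass_max(a, b, n1, n2, n3, 0, radius);
  box_pass_max(b, a, n1, n2, n3, 1, radius);
  box_pass_max(a, b, n1, n2, n3, 2, radius);
  return NumericVector(b.begin(), b.end());
}

static void gauss_pass(const std::vector<double>& src, std::vector<double>& dst,
                       int n1, int n2, int n3, int axis,
                       const std::vector<double>& kern) {
  int r = (int)(kern.size() - 1) / 2;
  int n[3] = {n1, n2, n3};
  int stride[3] = {1, n1, n1 * n2};
  int len = n[axis], st = stride[axis];
  int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a = 0; a < n[oa]; ++a) {
      R_xlen_t base = (R_xlen_t)a * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < len; ++i) {
        double s = 0, w = 0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int k = lo; k <= hi; ++k) {
          double kv = kern[k - i + r];
          s += kv * src[base + (R_xlen_t)k * st];
          w += kv;
        }
        dst[base + (R_xlen_t)i * st] = s / w;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(vol.begin(), vol.end()), b(N);
  if (sigma <= 0) return vol;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  for (int i = -r; i <= r; ++i) kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  gauss_pass(a, b, n1, n2, n3, 0, kern);
  gauss_pass(b, a, n1, n2, n3, 1, kern);
  gauss_pass(a, b, n1, n2, n3, 2, kern);
  return NumericVector(b.begin(), b.end());
}

// [[Rcpp::export]]
NumericVector mean_filter3d_cpp(NumericVector vol, IntegerVector dims, int radius) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(vol.begin(), vol.end()), b(N);
  std::vector<double> c1(N, 1.0), c2(N);
  box_pass_sum(a, b, c1, c2, n1, n2, n3, 0, radius);
  box_pass_sum(b, a, c2, c1, n1, n2, n3, 1, radius);
  box_pass_sum(a, b, c1, c2, n1, n2, n3, 2, radius);
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = b[i] / c2[i];
  return out;
}
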
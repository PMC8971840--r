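#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Batched 3D im2col. Input x is a 5-D array with dim (C, D, H, W, N),
// column-major. Output matrix has C*k^3 rows (channel fastest, then kernel
// offsets kd, kh, kw) and Do*Ho*Wo*N columns (output depth fastest, then
// height, width, sample). Out-of-range taps read as zero (zero padding).
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims,
                       int k, int stride, int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int rows = C * k * k * k;
  const R_xlen_t cols = (R_xlen_t)Do * Ho * Wo * N;
  NumericMatrix out(rows, cols);
  const double* px = x.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff_n = (R_xlen_t)n * C * D * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          const R_xlen_t col =
            ((R_xlen_t)n * Wo + ow) * Ho * Do + (R_xlen_t)oh * Do + od;
          double* pc = po + col * rows;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride - pad + kh;
              for (int kd = 0; kd < k; ++kd) {
                const int d = od * stride - pad + kd;
                double* dst = pc + (R_xlen_t)C * (kd + k * (kh + k * kw));
                if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                  const double* src =
                    px + xoff_n + (R_xlen_t)C * (d + (R_xlen_t)D * (h + (R_xlen_t)H * w));
                  for (int c = 0; c < C; ++c) dst[c] = src[c];
                }
                // else: already zero-initialized
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add columns back into a (C, D, H, W, N) array.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix colmat, IntegerVector dims,
                       int k, int stride, int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int rows = C * k * k * k;
  NumericVector x((R_xlen_t)C * D * H * W * N);
  const double* pc0 = colmat.begin();
  double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff_n = (R_xlen_t)n * C * D * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          const R_xlen_t col =
            ((R_xlen_t)n * Wo + ow) * Ho * Do + (R_xlen_t)oh * Do + od;
          const double* pc = pc0 + col * rows;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                const int d = od * stride - pad + kd;
                if (d < 0 || d >= D) continue;
                const double* src = pc + (R_xlen_t)C * (kd + k * (kh + k * kw));
                double* dst =
                  px + xoff_n + (R_xlen_t)C * (d + (R_xlen_t)D * (h + (R_xlen_t)H * w));
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}

// Two-pass 8-connected component labeling of a binary matrix.
// Returns an integer matrix with labels 1..n (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // scan previously visited 8-neighbours (column-major order)
      int nb[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) nb[nn++] = lab(r - 1, c);
      if (c > 0) {
        if (mask(r, c - 1)) nb[nn++] = lab(r, c - 1);
        if (r > 0 && mask(r - 1, c - 1)) nb[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && mask(r + 1, c - 1)) nb[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        int m = nb[0];
        for (int i = 1; i < nn; ++i) m = std::min(m, nb[i]);
        lab(r, c) = m;
        for (int i = 0; i < nn; ++i) unite(m, nb[i]);
      }
    }
  }
  // second pass: flatten labels to consecutive ids
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!lab(r, c)) continue;
      const int root = find(lab(r, c));
      if (!remap[root]) remap[root] = ++nlab;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
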
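#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold an H x W x C array into an (H*W) x (k*k*C) matrix of sliding
// k x k patches (stride 1, zero padding `pad`; pad = (k-1)/2 gives a
// same-size convolution). Rows index pixels in column-major order; columns
// index (kernel row, kernel column, channel) in the natural column-major
// flattening of an R array of dim (k, k, C, Cout), so `cols %*% W` is the
// convolution output.
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const int i0 = std::max(0, pad - ki);
        const int i1 = std::min(H, H + pad - ki);
        if (i1 <= i0) continue;
        double* dst0 = out.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* src = x.slice_colptr(c, sj) + i0 + ki - pad;
          std::memcpy(dst0 + (size_t)j * H + i0, src,
                      (size_t)(i1 - i0) * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch rows back onto the image grid.
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C, int k, int pad) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        const int i0 = std::max(0, pad - ki);
        const int i1 = std::min(H, H + pad - ki);
        if (i1 <= i0) continue;
        const double* src0 = cols.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = dx.slice_colptr(c, sj) + i0 + ki - pad;
          const double* src = src0 + (size_t)j * H + i0;
          const int n = i1 - i0;
          for (int t = 0; t < n; ++t) dst[t] += src[t];
        }
      }
    }
  }
  return dx;
}

// Connected-component labeling of a binary mask. Components are labeled
// 1..K in raster-scan (column-major, as stored by R) discovery order.
// connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int di4[] = {-1, 1, 0, 0};
  const int dj4[] = {0, 0, -1, 1};
  const int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* di = (connectivity == 8) ? di8 : di4;
  const int* dj = (connectivity == 8) ? dj8 : dj4;
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int q = 0; q < nn; ++q) {
          const int ni = pi + di[q], nj = pj + dj[q];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  return lab;
}
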
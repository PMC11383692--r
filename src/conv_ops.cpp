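// im2col-based 2-D convolution forward/backward used by the count-regression
// network. Column-major throughout; a feature map is an arma::cube
// (rows = y, cols = x, slices = channels). Zero padding, square kernels.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void out_dims(int H, int W, int k, int stride, int pad, int &Ho, int &Wo) {
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
}

// Unroll k x k patches into a (k*k*C) x (Ho*Wo) matrix. Row layout: channel
// outer, then kernel column, then kernel row (column-major within the patch),
// matching the weight matrix layout built on the R side.
static mat im2col(const cube &x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho, Wo;
  out_dims(H, W, k, stride, pad, Ho, Wo);
  mat cols(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            cols(row, oj * Ho + oi) = x(ii, jj, c);
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of im2col (for the input gradient).
static cube col2im(const mat &cols, int H, int W, int C, int k, int stride,
                   int pad) {
  int Ho, Wo;
  out_dims(H, W, k, stride, pad, Ho, Wo);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int row = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            x(ii, jj, c) += cols(row, oj * Ho + oi);
          }
        }
      }
    }
  }
  return x;
}

// Forward convolution. w: Cout x (k*k*Cin); b: Cout.
// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube &x, const arma::mat &w,
                       const arma::vec &b, int k, int stride, int pad) {
  int Ho, Wo;
  out_dims(x.n_rows, x.n_cols, k, stride, pad, Ho, Wo);
  mat cols = im2col(x, k, stride, pad);
  mat out = w * cols;
  out.each_col() += b;
  cube y(Ho, Wo, w.n_rows);
  for (uword c = 0; c < w.n_rows; ++c)
    y.slice(c) = reshape(out.row(c), Ho, Wo);
  return y;
}

// Backward pass: given input x, weights w and upstream gradient dy, return
// gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube &x, const arma::mat &w,
                       const arma::cube &dy, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho, Wo;
  out_dims(H, W, k, stride, pad, Ho, Wo);
  mat cols = im2col(x, k, stride, pad);
  mat dy_mat(w.n_rows, Ho * Wo);
  for (uword c = 0; c < w.n_rows; ++c)
    dy_mat.row(c) = vectorise(dy.slice(c)).t();
  mat dw = dy_mat * cols.t();
  vec db = sum(dy_mat, 1);
  mat dcols = w.t() * dy_mat;
  cube dx = col2im(dcols, H, W, C, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
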
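// Minimal im2col-based 2-D convolution kernels for the desk-scale detector
// backbone. Feature maps are H x W x C cubes (row = y); weights are
// (kh*kw*Cin) x Cout matrices with column layout ki + kh*(kj + kw*c), i.e.
// kernel-row fastest, then kernel-col, then input channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int C = x.n_slices;
  mat col(Ho * Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int cc = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= (int)x.n_cols) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= (int)x.n_rows) continue;
            col(oi + oj * Ho, cc) = xs(ii, ij);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int Ho = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - kw) / stride + 1;
  const int Cout = W.n_cols;
  mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat out = col * W;
  out.each_row() += b.t();
  cube y(Ho, Wo, Cout);
  for (int k = 0; k < Cout; ++k) {
    y.slice(k) = reshape(out.col(k), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& W,
                           const arma::cube& gy, int kh, int kw, int stride,
                           int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const int Cout = gy.n_slices, Cin = x.n_slices;
  mat gyf(Ho * Wo, Cout);
  for (int k = 0; k < Cout; ++k) {
    gyf.col(k) = vectorise(gy.slice(k));
  }
  mat col = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gW = col.t() * gyf;
  vec gb = sum(gyf, 0).t();
  mat gcol = gyf * W.t();
  cube gx(x.n_rows, x.n_cols, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    mat& gxs = gx.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int cc = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride + kj - pad;
          if (ij < 0 || ij >= (int)x.n_cols) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= (int)x.n_rows) continue;
            gxs(ii, ij) += gcol(oi + oj * Ho, cc);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
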
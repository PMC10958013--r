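// Batched 2-D convolution support: im2col / col2im on "matrix form"
// activations.
//
// An activation tensor (H, W, C, N) is stored as an (H*W*N) x C matrix whose
// row index is h + H*(w + W*n) (0-based, column-major within each image).
// Convolution then becomes one GEMM per layer over the whole mini-batch,
// which is where essentially all training time goes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Patch matrix for a k x k convolution with given stride and zero padding.
// Output: (Ho*Wo*N) x (k*k*C); column index kh + k*kw + k*k*c.
// [[Rcpp::export]]
arma::mat nn_im2col(const arma::mat& X, int H, int W, int N,
                    int k, int stride, int pad) {
  const int C = X.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat cols(static_cast<arma::uword>(Ho) * Wo * N,
                 static_cast<arma::uword>(k) * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* dst = cols.colptr(static_cast<arma::uword>(c) * k * k + kw * k + kh);
        for (int n = 0; n < N; ++n) {
          const arma::uword img_in = static_cast<arma::uword>(n) * H * W;
          const arma::uword img_out = static_cast<arma::uword>(n) * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            const arma::uword col_in = img_in + static_cast<arma::uword>(w) * H;
            const arma::uword col_out = img_out + static_cast<arma::uword>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              dst[col_out + ho] = xc[col_in + h];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Direct 3x3 stride-1 pad-1 convolution (+ optional ReLU) for frozen
// layers: no patch matrix is materialized, which matters because frozen
// layers run forward-only on every mini-batch.
// X: (H*W*N) x Cin matrix form; W: (9*Cin) x Cout with row index
// kh + 3*kw + 9*cin; returns (H*W*N) x Cout.
// [[Rcpp::export]]
arma::mat nn_conv3_direct(const arma::mat& X, int H, int W, int N,
                          const arma::mat& Wt, const arma::vec& b,
                          bool relu) {
  const int Cin = X.n_cols;
  const int Cout = Wt.n_cols;
  arma::mat Y(X.n_rows, Cout);
  for (int co = 0; co < Cout; ++co) Y.col(co).fill(b[co]);
  for (int co = 0; co < Cout; ++co) {
    double* y = Y.colptr(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x = X.colptr(ci);
      for (int kw = 0; kw < 3; ++kw) {
        for (int kh = 0; kh < 3; ++kh) {
          const double wgt = Wt(kh + 3 * kw + 9 * ci, co);
          if (wgt == 0.0) continue;
          const int dh = kh - 1, dw = kw - 1;
          for (int n = 0; n < N; ++n) {
            const arma::uword img = static_cast<arma::uword>(n) * H * W;
            const int w0 = (dw < 0) ? 1 : 0;
            const int w1 = (dw > 0) ? W - 1 : W;
            for (int w = w0; w < w1; ++w) {
              const double* xs = x + img + static_cast<arma::uword>(w + dw) * H;
              double* yd = y + img + static_cast<arma::uword>(w) * H;
              const int h0 = (dh < 0) ? 1 : 0;
              const int h1 = (dh > 0) ? H - 1 : H;
              for (int h = h0; h < h1; ++h) yd[h] += wgt * xs[h + dh];
            }
          }
        }
      }
    }
    if (relu) {
      for (arma::uword i = 0; i < Y.n_rows; ++i) if (y[i] < 0) y[i] = 0;
    }
  }
  return Y;
}

// Adjoint of nn_im2col: scatter-add patch gradients back to the input
// layout. dcols is (Ho*Wo*N) x (k*k*C); the result is (H*W*N) x C.
// [[Rcpp::export]]
arma::mat nn_col2im(const arma::mat& dcols, int H, int W, int N,
                    int k, int stride, int pad) {
  const int C = dcols.n_cols / (k * k);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat dX(static_cast<arma::uword>(H) * W * N, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dX.colptr(c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* src = dcols.colptr(static_cast<arma::uword>(c) * k * k + kw * k + kh);
        for (int n = 0; n < N; ++n) {
          const arma::uword img_in = static_cast<arma::uword>(n) * H * W;
          const arma::uword img_out = static_cast<arma::uword>(n) * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            const arma::uword col_in = img_in + static_cast<arma::uword>(w) * H;
            const arma::uword col_out = img_out + static_cast<arma::uword>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              xc[col_in + h] += src[col_out + ho];
            }
          }
        }
      }
    }
  }
  return dX;
}
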
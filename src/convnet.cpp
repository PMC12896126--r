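// 1-D convolution primitives for the autoencoder.
//
// Layout conventions (shared with the R side):
//   signal batch  : cube (length, channels, batch)
//   conv weights  : mat  (k * C_in, F_out), row index c + C_in * j
//                   for kernel tap j in 0..k-1 and input channel c
//   tconv weights : mat  (C_in, k * C_out), col index f + C_out * j
//
// A convolution with stride s and pad p maps length L to (L + 2p - k)/s + 1;
// with odd k, p = (k-1)/2 and s | L this is exactly L/s.  The transposed
// convolution uses the same index geometry in reverse and maps L to L*s.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather x (Lx x C x B) into the im2col matrix (Lo*B x k*C).
// Row o + Lo*b, column c + C*j holds x(o*s + j - p, c, b), zero off the ends.
static mat im2col(const cube& x, int k, int s, int p, int Lo) {
  const int Lx = x.n_rows, C = x.n_cols, B = x.n_slices;
  mat out(Lo * (size_t)B, (size_t)k * C, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < k; ++j) {
      for (int c = 0; c < C; ++c) {
        const size_t col = c + (size_t)C * j;
        for (int o = 0; o < Lo; ++o) {
          const int i = o * s + j - p;
          if (i >= 0 && i < Lx)
            out(o + (size_t)Lo * b, col) = x(i, c, b);
        }
      }
    }
  }
  return out;
}

// Scatter-add the inverse of im2col: ycol (Lo*B x k*C) back into (Lx x C x B).
static cube col2im(const mat& ycol, int k, int s, int p,
                   int Lx, int C, int B, int Lo) {
  cube out(Lx, C, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < k; ++j) {
      for (int c = 0; c < C; ++c) {
        const size_t col = c + (size_t)C * j;
        for (int o = 0; o < Lo; ++o) {
          const int i = o * s + j - p;
          if (i >= 0 && i < Lx)
            out(i, c, b) += ycol(o + (size_t)Lo * b, col);
        }
      }
    }
  }
  return out;
}

static int conv_out_len(int Lx, int k, int s, int p) {
  return (Lx + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
arma::cube nn_conv1d_fw(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int stride, int pad) {
  const int Lo = conv_out_len(x.n_rows, W.n_rows / x.n_cols, stride, pad);
  const int k = W.n_rows / x.n_cols, F = W.n_cols, B = x.n_slices;
  mat y = im2col(x, k, stride, pad, Lo) * W;      // (Lo*B x F)
  y.each_row() += b.t();
  cube out(Lo, F, B);
  for (int bb = 0; bb < B; ++bb)
    out.slice(bb) = y.rows(Lo * (size_t)bb, Lo * (size_t)(bb + 1) - 1);
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv1d_bw(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, int stride, int pad) {
  const int C = x.n_cols, B = x.n_slices;
  const int k = W.n_rows / C, F = W.n_cols, Lo = dy.n_rows;
  mat dyf(Lo * (size_t)B, F);
  for (int bb = 0; bb < B; ++bb)
    dyf.rows(Lo * (size_t)bb, Lo * (size_t)(bb + 1) - 1) = dy.slice(bb);
  mat xcol = im2col(x, k, stride, pad, Lo);
  mat dW = xcol.t() * dyf;
  vec db = sum(dyf, 0).t();
  cube dx = col2im(dyf * W.t(), k, stride, pad, x.n_rows, C, B, Lo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube nn_tconv1d_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int stride, int pad) {
  const int Li = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int kCout = W.n_cols, Cout = b.n_elem, k = kCout / Cout;
  const int Lo = Li * stride;
  mat xf(Li * (size_t)B, Cin);
  for (int bb = 0; bb < B; ++bb)
    xf.rows(Li * (size_t)bb, Li * (size_t)(bb + 1) - 1) = x.slice(bb);
  cube y = col2im(xf * W, k, stride, pad, Lo, Cout, B, Li);
  for (int bb = 0; bb < B; ++bb)
    y.slice(bb).each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_tconv1d_bw(const arma::cube& x, const arma::mat& W,
                         const arma::cube& dy, int stride, int pad) {
  const int Li = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int kCout = W.n_cols;
  const int Cout = dy.n_cols, k = kCout / Cout;
  mat xf(Li * (size_t)B, Cin);
  for (int bb = 0; bb < B; ++bb)
    xf.rows(Li * (size_t)bb, Li * (size_t)(bb + 1) - 1) = x.slice(bb);
  // dy plays the role of the "image"; gathering it mirrors the forward scatter
  mat dycol = im2col(dy, k, stride, pad, Li);     // (Li*B x k*Cout)
  mat dW = xf.t() * dycol;
  vec db(Cout, fill::zeros);
  for (int bb = 0; bb < B; ++bb)
    db += sum(dy.slice(bb), 0).t();
  mat dxf = dycol * W.t();                        // (Li*B x Cin)
  cube dx(Li, Cin, B);
  for (int bb = 0; bb < B; ++bb)
    dx.slice(bb) = dxf.rows(Li * (size_t)bb, Li * (size_t)(bb + 1) - 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
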
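// 1-D convolution kernels (im2col + BLAS via Armadillo) for the network
// engine in R/nn.R. Activations are (batch, length, channels) arrays in R's
// column-major layout. Padding is implicit: out-of-range taps read zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int B, int L, int C, int K, int stride,
                   int pad_left, int Lout, arma::mat& xc) {
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double* dst = xc.colptr(k + K * c);
      for (int lo = 0; lo < Lout; ++lo) {
        int l = lo * stride + k - pad_left;
        double* d2 = dst + (size_t)lo * B;
        if (l < 0 || l >= L) {
          std::fill(d2, d2 + B, 0.0);
        } else {
          const double* src = x + (size_t)B * ((size_t)l + (size_t)L * c);
          std::copy(src, src + B, d2);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix W, NumericVector b,
                             int K, int stride, int pad_left, int Lout) {
  const int B = xdim[0], L = xdim[1], C = xdim[2];
  const int Co = W.ncol();
  arma::mat xc((size_t)B * Lout, (size_t)K * C);
  im2col(x.begin(), B, L, C, K, stride, pad_left, Lout, xc);
  const arma::mat Wm(W.begin(), (size_t)K * C, Co, false);
  arma::mat y = xc * Wm;
  y.each_row() += arma::rowvec(b.begin(), Co);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(B, Lout, Co);
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector x, IntegerVector xdim, NumericMatrix W,
                    NumericVector dout, int K, int stride, int pad_left,
                    int Lout, bool compute_dx) {
  const int B = xdim[0], L = xdim[1], C = xdim[2];
  const int Co = W.ncol();
  arma::mat xc((size_t)B * Lout, (size_t)K * C);
  im2col(x.begin(), B, L, C, K, stride, pad_left, Lout, xc);
  const arma::mat dy(dout.begin(), (size_t)B * Lout, Co, false);
  const arma::mat Wm(W.begin(), (size_t)K * C, Co, false);
  arma::mat dW = xc.t() * dy;
  arma::rowvec db = arma::sum(dy, 0);
  List res = List::create(_["W"] = wrap(dW),
                          _["b"] = NumericMatrix(1, Co, db.begin()));
  if (compute_dx) {
    arma::mat dxc = dy * Wm.t();              // (B*Lout, K*C)
    NumericVector dx((size_t)B * L * C);      // zero-initialized
    double* dxp = dx.begin();
    for (int c = 0; c < C; ++c) {
      for (int k = 0; k < K; ++k) {
        const double* src = dxc.colptr(k + K * c);
        for (int lo = 0; lo < Lout; ++lo) {
          int l = lo * stride + k - pad_left;
          if (l < 0 || l >= L) continue;
          double* d2 = dxp + (size_t)B * ((size_t)l + (size_t)L * c);
          const double* s2 = src + (size_t)lo * B;
          for (int bb = 0; bb < B; ++bb) d2[bb] += s2[bb];
        }
      }
    }
    dx.attr("dim") = IntegerVector::create(B, L, C);
    res["dx"] = dx;
  }
  return res;
}
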
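// Compiled kernels for the compact CNN backbone: im2col lowering of 3x3
// same-padded convolutions (the matrix product itself runs on BLAS through
// Armadillo) and 2x2 max pooling. Activation batches are (C, H, W, N)
// column-major arrays, channel fastest, matching the R side. The backward
// kernel recomputes the im2col matrix from the cached layer input instead
// of shuttling it through R, which keeps per-batch memory small.

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// x: (C,H,W,N). Fills (9C, H*W*N); rows ordered c fastest within each of
// the 9 kernel offsets, offsets ordered dh fastest within dw.
static void im2col3(const double* x, int C, int H, int W, int N, arma::mat& cols) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* colp = cols.colptr(((arma::uword)n * W + w) * H + h);
        int k = 0;
        for (int dw = 0; dw < 3; ++dw) {
          const int ws = w + dw - 1;
          for (int dh = 0; dh < 3; ++dh, ++k) {
            const int hs = h + dh - 1;
            double* dst = colp + (size_t)k * C;
            if (ws < 0 || ws >= W || hs < 0 || hs >= H) {
              std::fill(dst, dst + C, 0.0);
            } else {
              const double* src = xn + ((size_t)ws * H + hs) * C;
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericVector conv3_fwd(NumericVector x, NumericMatrix W2d, NumericVector b) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[0], H = dm[1], W = dm[2], N = dm[3];
  arma::mat cols(9 * C, (arma::uword)H * W * N);
  im2col3(x.begin(), C, H, W, N, cols);
  const arma::mat Wm(W2d.begin(), W2d.nrow(), W2d.ncol(), false, true);
  NumericVector y((R_xlen_t)W2d.nrow() * H * W * N);
  arma::mat Y(y.begin(), W2d.nrow(), (arma::uword)H * W * N, false, true);
  Y = Wm * cols;
  Y.each_col() += arma::vec(b.begin(), b.size());
  y.attr("dim") = IntegerVector::create(W2d.nrow(), H, W, N);
  return y;
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(NumericVector x, NumericMatrix W2d, NumericVector dy) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[0], H = dm[1], W = dm[2], N = dm[3];
  const int Cout = W2d.nrow();
  const arma::uword HWN = (arma::uword)H * W * N;
  arma::mat cols(9 * C, HWN);
  im2col3(x.begin(), C, H, W, N, cols);
  const arma::mat dY(dy.begin(), Cout, HWN, false, true);
  const arma::mat Wm(W2d.begin(), Cout, W2d.ncol(), false, true);
  NumericMatrix dWr(Cout, W2d.ncol());
  arma::mat dW(dWr.begin(), Cout, W2d.ncol(), false, true);
  dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcols = Wm.t() * dY;   // reuse: col2im accumulation below
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* colp = dcols.colptr(((arma::uword)n * W + w) * H + h);
        int k = 0;
        for (int dw = 0; dw < 3; ++dw) {
          const int ws = w + dw - 1;
          for (int dh = 0; dh < 3; ++dh, ++k) {
            const int hs = h + dh - 1;
            if (ws < 0 || ws >= W || hs < 0 || hs >= H) continue;
            double* dst = xn + ((size_t)ws * H + hs) * C;
            const double* src = colp + (size_t)k * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = dm;
  return List::create(_["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int C = dm[0], H = dm[1], W = dm[2], N = dm[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  IntegerVector which((R_xlen_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* wp = which.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t obase = (((size_t)n * Wo + wo) * Ho + ho) * C;
        // the four source pixels of this window, channel-contiguous each
        const double* s[4];
        int k = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh, ++k)
            s[k] = xn + ((size_t)(2 * wo + dw) * H + (2 * ho + dh)) * C;
        for (int c = 0; c < C; ++c) {
          double best = s[0][c];
          int arg = 0;                       // ties: first window position
          for (int kk = 1; kk < 4; ++kk)
            if (s[kk][c] > best) { best = s[kk][c]; arg = kk; }
          yp[obase + c] = best;
          wp[obase + c] = arg;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  which.attr("dim") = y.attr("dim");
  return List::create(_["out"] = y, _["which"] = which, _["dims"] = dm);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector which, NumericVector dy,
                           IntegerVector xdim) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* wp = which.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t obase = (((size_t)n * Wo + wo) * Ho + ho) * C;
        for (int c = 0; c < C; ++c) {
          const int k = wp[obase + c];
          const int dh = k & 1, dw = k >> 1;
          xn[((size_t)(2 * wo + dw) * H + (2 * ho + dh)) * C + c] += dyp[obase + c];
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
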
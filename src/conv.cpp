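// Dense 2-D convolution via im2col + GEMM, plus its reverse-mode gradients.
// Array layout everywhere: activations (H, W, C, N), weights (K, K, Cin, Cout),
// all column-major as R stores them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `col` (Ho*Wo x K*K*Cin) from sample slice x_n (H*W*C doubles).
// Column index j = kh + K*kw + K*K*c matches the column-major flattening of a
// (K, K, Cin, Cout) weight array into a (K*K*Cin x Cout) matrix.
static void im2col(const double* xn, int H, int W, int C, int K, int stride,
                   int pad, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* plane = xn + (std::size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* dst = col.colptr(kh + K * kw + K * K * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh) dst[oh + Ho * ow] = 0.0;
            continue;
          }
          const double* src = plane + (std::size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride + kh - pad;
            dst[oh + Ho * ow] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

// Scatter-add of a column buffer back onto the input gradient (col2im).
static void col2im(const arma::mat& col, int H, int W, int C, int K, int stride,
                   int pad, int Ho, int Wo, double* gxn) {
  for (int c = 0; c < C; ++c) {
    double* plane = gxn + (std::size_t)c * H * W;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* src = col.colptr(kh + K * kw + K * K * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride + kw - pad;
          if (iw < 0 || iw >= W) continue;
          double* dplane = plane + (std::size_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride + kh - pad;
            if (ih >= 0 && ih < H) dplane[ih] += src[oh + Ho * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;

  arma::mat Wmat(const_cast<double*>(w.begin()), K * K * Cin, Cout, false, true);
  NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col(Ho * Wo, K * K * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat on(out.begin() + (std::size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    on = col * Wmat;
    for (int co = 0; co < Cout; ++co) on.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;

  arma::mat Wmat(const_cast<double*>(w.begin()), K * K * Cin, Cout, false, true);
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((std::size_t)K * K * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWmat(gw.begin(), K * K * Cin, Cout, false, true);

  arma::mat col(Ho * Wo, K * K * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, K, stride, pad, Ho, Wo, col);
    arma::mat gn(const_cast<double*>(gout.begin()) + (std::size_t)n * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    gWmat += col.t() * gn;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gn.col(co));
    arma::mat gcol = gn * Wmat.t();
    col2im(gcol, H, W, C, K, stride, pad, Ho, Wo,
           gx.begin() + (std::size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Connected-component labeling of a binary mask by breadth-first search.
// `connectivity` is 4 or 8; labels are assigned in row-major scan order of the
// first pixel met, which makes the labeling (and any tie-break built on it)
// deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity == 8 ? 8 : 4;
  // row-major scan: rows within a row first
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r);
      stack.push_back(c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int cc = stack.back(); stack.pop_back();
        int rr = stack.back(); stack.pop_back();
        for (int k = 0; k < nd; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2);
            stack.push_back(c2);
          }
        }
      }
    }
  }
  return lab;
}
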
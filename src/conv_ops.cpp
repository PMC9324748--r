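// Convolution kernels for the CycleGAN networks.
//
// Tensor layout follows R's column-major arrays:
//   activations x : [h, w, c, n]
//   weights     w : [kh, kw, cin, cout]
// im2col produces a (kh*kw*cin) x (oh*ow) matrix per sample with row index
// r = ki + kh*(kj + kw*c) and column index p = oi + oh*oj, so the flattened
// weight array is directly the (K x cout) multiplication matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xs, int h, int w, int cin,
                   int kh, int kw, int oh, int ow,
                   int stride, int pad, arma::mat& col) {
  for (int c = 0; c < cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int jj = oj * stride - pad + kj;
          double* colp = col.colptr(oh * oj) + r;
          if (jj < 0 || jj >= w) {
            for (int oi = 0; oi < oh; ++oi, colp += col.n_rows) *colp = 0.0;
            continue;
          }
          const double* xcol = xs + h * (jj + (long)w * c);
          for (int oi = 0; oi < oh; ++oi, colp += col.n_rows) {
            const int ii = oi * stride - pad + ki;
            *colp = (ii < 0 || ii >= h) ? 0.0 : xcol[ii];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int h, int w, int cin,
                       int kh, int kw, int oh, int ow,
                       int stride, int pad, double* dxs) {
  for (int c = 0; c < cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int jj = oj * stride - pad + kj;
          if (jj < 0 || jj >= w) continue;
          const double* colp = col.colptr(oh * oj) + r;
          double* xcol = dxs + h * (jj + (long)w * c);
          for (int oi = 0; oi < oh; ++oi, colp += col.n_rows) {
            const int ii = oi * stride - pad + ki;
            if (ii >= 0 && ii < h) xcol[ii] += *colp;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector bias, int stride, int pad) {
  const int h = xdim[0], wd = xdim[1], cin = xdim[2], n = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cout = wdim[3];
  const int oh = (h + 2 * pad - kh) / stride + 1;
  const int ow = (wd + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * cin, P = oh * ow;
  if (oh < 1 || ow < 1) stop("conv2d: output size would be non-positive");
  if (wdim[2] != cin) stop("conv2d: channel mismatch");

  NumericVector y((R_xlen_t)oh * ow * cout * n);
  y.attr("dim") = IntegerVector::create(oh, ow, cout, n);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat col(K, P);
  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + (long)s * h * wd * cin, h, wd, cin,
           kh, kw, oh, ow, stride, pad, col);
    arma::mat ys(y.begin() + (long)s * P * cout, P, cout, false, true);
    ys = col.t() * Wm;
    for (int co = 0; co < cout; ++co) ys.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector dy, int stride, int pad, bool need_dx) {
  const int h = xdim[0], wd = xdim[1], cin = xdim[2], n = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cout = wdim[3];
  const int oh = (h + 2 * pad - kh) / stride + 1;
  const int ow = (wd + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * cin, P = oh * ow;

  const arma::mat Wm(const_cast<double*>(w.begin()), K, cout, false, true);
  NumericVector dwv((R_xlen_t)kh * kw * cin * cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  arma::mat dW(dwv.begin(), K, cout, false, true);
  NumericVector dbv(cout);
  arma::vec db(dbv.begin(), cout, false, true);
  NumericVector dxv;
  if (need_dx) {
    dxv = NumericVector((R_xlen_t)h * wd * cin * n);
    dxv.attr("dim") = IntegerVector::create(h, wd, cin, n);
  }

  arma::mat col(K, P);
  for (int s = 0; s < n; ++s) {
    const double* xs = x.begin() + (long)s * h * wd * cin;
    im2col(xs, h, wd, cin, kh, kw, oh, ow, stride, pad, col);
    const arma::mat dYs(const_cast<double*>(dy.begin()) + (long)s * P * cout,
                        P, cout, false, true);
    dW += col * dYs;
    db += arma::sum(dYs, 0).t();
    if (need_dx) {
      arma::mat dcol = Wm * dYs.t();  // K x P
      col2im_add(dcol, h, wd, cin, kh, kw, oh, ow, stride, pad,
                 dxv.begin() + (long)s * h * wd * cin);
    }
  }
  return List::create(_["dx"] = dxv, _["dW"] = dwv, _["db"] = dbv);
}
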
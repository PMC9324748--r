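// First (hard-thresholding) stage of block-matching and 3D collaborative
// filtering, used as a denoising comparator.
//
// For each reference 8x8 block: find the most similar blocks (L2 patch
// distance) inside a local search window, stack the best power-of-two-sized
// group, apply a 2D DCT per block and a 1D orthonormal Haar transform across
// the stack, hard-threshold the 3D coefficients at lambda*sigma, invert, and
// aggregate the filtered blocks with weights 1/(number of retained
// coefficients).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat dct_matrix(int b) {
  arma::mat D(b, b);
  for (int i = 0; i < b; ++i)
    for (int j = 0; j < b; ++j)
      D(i, j) = (i == 0 ? std::sqrt(1.0 / b) : std::sqrt(2.0 / b)) *
                std::cos(M_PI * (2 * j + 1) * i / (2.0 * b));
  return D;
}

static void haar_fw(double* v, int g) {
  std::vector<double> tmp(g);
  const double s2 = std::sqrt(2.0);
  for (int m = g; m > 1; m /= 2) {
    for (int i = 0; i < m / 2; ++i) {
      tmp[i]        = (v[2 * i] + v[2 * i + 1]) / s2;
      tmp[m / 2 + i] = (v[2 * i] - v[2 * i + 1]) / s2;
    }
    std::copy(tmp.begin(), tmp.begin() + m, v);
  }
}

static void haar_bw(double* v, int g) {
  std::vector<double> tmp(g);
  const double s2 = std::sqrt(2.0);
  for (int m = 2; m <= g; m *= 2) {
    for (int i = 0; i < m / 2; ++i) {
      tmp[2 * i]     = (v[i] + v[m / 2 + i]) / s2;
      tmp[2 * i + 1] = (v[i] - v[m / 2 + i]) / s2;
    }
    std::copy(tmp.begin(), tmp.begin() + m, v);
  }
}

// [[Rcpp::export]]
NumericMatrix bm3d_ht_cpp(NumericMatrix img, double sigma, double lambda,
                          int block, int step, int search, int max_group) {
  const int h = img.nrow(), w = img.ncol(), b = block;
  if (h < b || w < b) stop("image smaller than the matching block");
  const arma::mat X(img.begin(), h, w, false, true);
  const arma::mat D = dct_matrix(b);
  const double thr = lambda * sigma;

  arma::mat num(h, w, arma::fill::zeros), den(h, w, arma::fill::zeros);

  std::vector<int> ri, rj;
  for (int i = 0; i <= h - b; i += step) ri.push_back(i);
  if (ri.back() != h - b) ri.push_back(h - b);
  for (int j = 0; j <= w - b; j += step) rj.push_back(j);
  if (rj.back() != w - b) rj.push_back(w - b);

  std::vector<std::pair<double, std::pair<int, int>>> cand;
  for (int a = 0; a < (int)ri.size(); ++a) {
    for (int c = 0; c < (int)rj.size(); ++c) {
      const int i0 = ri[a], j0 = rj[c];
      const arma::mat Ref = X.submat(i0, j0, i0 + b - 1, j0 + b - 1);

      cand.clear();
      const int ilo = std::max(0, i0 - search), ihi = std::min(h - b, i0 + search);
      const int jlo = std::max(0, j0 - search), jhi = std::min(w - b, j0 + search);
      for (int i = ilo; i <= ihi; ++i)
        for (int j = jlo; j <= jhi; ++j) {
          double d = arma::accu(arma::square(
              X.submat(i, j, i + b - 1, j + b - 1) - Ref));
          cand.push_back({d, {i, j}});
        }
      const int navail = (int)cand.size();
      int keep = std::min(max_group, navail);
      std::partial_sort(cand.begin(), cand.begin() + keep, cand.end());
      int g = 1;
      while (2 * g <= keep) g *= 2;

      // stack of 2D-DCT blocks: coeffs(pos, k) for k-th block in the group
      arma::mat coeffs(b * b, g);
      for (int k = 0; k < g; ++k) {
        const int i = cand[k].second.first, j = cand[k].second.second;
        arma::mat T = D * X.submat(i, j, i + b - 1, j + b - 1) * D.t();
        coeffs.col(k) = arma::vectorise(T);
      }

      int nret = 0;
      for (int p = 0; p < b * b; ++p) {
        arma::rowvec row = coeffs.row(p);
        haar_fw(row.memptr(), g);
        for (int k = 0; k < g; ++k) {
          if (std::abs(row[k]) < thr) row[k] = 0.0; else ++nret;
        }
        haar_bw(row.memptr(), g);
        coeffs.row(p) = row;
      }
      const double wgt = 1.0 / std::max(1, nret);

      for (int k = 0; k < g; ++k) {
        const int i = cand[k].second.first, j = cand[k].second.second;
        arma::mat B = D.t() * arma::reshape(coeffs.col(k), b, b) * D;
        num.submat(i, j, i + b - 1, j + b - 1) += wgt * B;
        den.submat(i, j, i + b - 1, j + b - 1) += wgt;
      }
    }
  }

  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      out(i, j) = den(i, j) > 0 ? num(i, j) / den(i, j) : X(i, j);
  return out;
}
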
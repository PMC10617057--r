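// Dense 2D convolution kernels (same padding, stride 1) used by the
// autodiff tape. Array layout follows R: H x W x C x N, column-major.
// Weights are stored as a (kh*kw*Cin) x Cout matrix whose row index is
// di + dj*kh + c*kh*kw, matching an R array of dim c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* xp, int H, int W, int C,
                   int kh, int kw, arma::mat& col) {
  const int ph = kh / 2, pw = kw / 2;
  col.zeros((arma::uword)H * W, (arma::uword)kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + dj * kh + c * kh * kw;
        double* colk = col.colptr(k);
        const int i0 = std::max(0, ph - di);
        const int i1 = std::min(H, H + ph - di);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          const double* src = xc + (size_t)jj * H + (di - ph);
          double* dst = colk + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& dcol, int H, int W, int C,
                       int kh, int kw, double* dxp) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int k = di + dj * kh + c * kh * kw;
        const double* colk = dcol.colptr(k);
        const int i0 = std::max(0, ph - di);
        const int i1 = std::min(H, H + ph - di);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          double* dst = dxc + (size_t)jj * H + (di - ph);
          const double* src = colk + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w,
                         NumericVector b, int kh, int kw) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  if ((int)w.nrow() != kh * kw * C)
    stop("weight rows (%d) do not match kh*kw*Cin (%d)",
         (int)w.nrow(), kh * kw * C);
  arma::mat wm(w.begin(), w.nrow(), Cout, false, true);
  arma::rowvec bv(b.begin(), Cout, false, true);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout,
                 (arma::uword)H * W, Cout, false, true);
    if (kh == 1 && kw == 1) {
      const arma::mat xm(const_cast<double*>(xp), (arma::uword)H * W, C,
                         false, true);
      ym = xm * wm;
    } else {
      im2col(xp, H, W, C, kh, kw, col);
      ym = col * wm;
    }
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                int kh, int kw) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = dims;
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat dwm(dw.begin(), w.nrow(), Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    arma::mat dym(dy.begin() + (size_t)n * H * W * Cout,
                  (arma::uword)H * W, Cout, false, true);
    dbv += arma::sum(dym, 0);
    if (kh == 1 && kw == 1) {
      const arma::mat xm(const_cast<double*>(xp), (arma::uword)H * W, C,
                         false, true);
      arma::mat dxm(dx.begin() + (size_t)n * H * W * C,
                    (arma::uword)H * W, C, false, true);
      dwm += xm.t() * dym;
      dxm = dym * wm.t();
    } else {
      im2col(xp, H, W, C, kh, kw, col);
      dwm += col.t() * dym;
      arma::mat dcol = dym * wm.t();
      col2im_add(dcol, H, W, C, kh, kw,
                 dx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw,
                      Named("db") = db);
}
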
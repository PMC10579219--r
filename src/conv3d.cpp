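// 3D convolution forward/backward via im2col + BLAS gemm.
//
// Array layouts (R column-major):
//   activations  x : [T, H, W, C, N]
//   weights      w : [kt, kh, kw, Cin, Cout]
//   output       y : [To, Ho, Wo, Cout, N]
// The im2col patch matrix is K x P with K = kt*kh*kw*Cin and
// P = To*Ho*Wo, row index r = it + kt*(ih + kh*(iw + kw*c)), column index
// p = to + To*(ho + Ho*wo) — both consistent with the flattened R arrays, so
// gemm results copy straight back into R memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int T, int H, int W, int C,
                   int kt, int kh, int kw,
                   int st, int sh, int sw,
                   int pt, int ph, int pw,
                   int To, int Ho, int Wo, arma::mat& P) {
  // P is K x (To*Ho*Wo); columns (output positions) are filled contiguously
  const int THW = T * H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        int p = to + To * (ho + Ho * wo);
        double* col = P.colptr(p);
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (size_t)c * THW;
          for (int iw = 0; iw < kw; ++iw) {
            int wi = wo * sw - pw + iw;
            bool wok = (wi >= 0 && wi < W);
            for (int ih = 0; ih < kh; ++ih) {
              int hi = ho * sh - ph + ih;
              bool hok = wok && (hi >= 0 && hi < H);
              const double* xrow = hok ? xc + T * (hi + H * wi) : nullptr;
              int base = to * st - pt;
              for (int it = 0; it < kt; ++it) {
                int ti = base + it;
                int r = it + kt * (ih + kh * (iw + kw * c));
                col[r] = (hok && ti >= 0 && ti < T) ? xrow[ti] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& P, int T, int H, int W, int C,
                       int kt, int kh, int kw,
                       int st, int sh, int sw,
                       int pt, int ph, int pw,
                       int To, int Ho, int Wo, double* dx) {
  const int THW = T * H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        int p = to + To * (ho + Ho * wo);
        const double* col = P.colptr(p);
        for (int c = 0; c < C; ++c) {
          double* xc = dx + (size_t)c * THW;
          for (int iw = 0; iw < kw; ++iw) {
            int wi = wo * sw - pw + iw;
            if (wi < 0 || wi >= W) continue;
            for (int ih = 0; ih < kh; ++ih) {
              int hi = ho * sh - ph + ih;
              if (hi < 0 || hi >= H) continue;
              double* xrow = xc + T * (hi + H * wi);
              int base = to * st - pt;
              for (int it = 0; it < kt; ++it) {
                int ti = base + it;
                if (ti < 0 || ti >= T) continue;
                xrow[ti] += col[it + kt * (ih + kh * (iw + kw * c))];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int T = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int kt = wd[0], kh = wd[1], kw = wd[2], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: channel mismatch");
  int st = stride[0], sh = stride[1], sw = stride[2];
  int pt = pad[0], ph = pad[1], pw = pad[2];
  int To = out_size(T, kt, pt, st), Ho = out_size(H, kh, ph, sh),
      Wo = out_size(W, kw, pw, sw);
  if (To < 1 || Ho < 1 || Wo < 1) stop("conv3d: output size < 1");

  int K = kt * kh * kw * C;
  int P = To * Ho * Wo;
  NumericVector y((size_t)To * Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(To, Ho, Wo, Cout, N);

  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat Pm(K, P);

  const size_t xstep = (size_t)T * H * W * C;
  const size_t ystep = (size_t)P * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xstep, T, H, W, C, kt, kh, kw, st, sh, sw,
           pt, ph, pw, To, Ho, Wo, Pm);
    arma::mat Ymat(y.begin() + n * ystep, P, Cout, false, true);
    Ymat = Pm.t() * Wmat;
    Ymat.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                IntegerVector stride, IntegerVector pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int T = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int kt = wd[0], kh = wd[1], kw = wd[2], Cout = wd[4];
  int To = yd[0], Ho = yd[1], Wo = yd[2];
  int st = stride[0], sh = stride[1], sw = stride[2];
  int pt = pad[0], ph = pad[1], pw = pad[2];

  int K = kt * kh * kw * C;
  int P = To * Ho * Wo;

  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx(need_dx ? (size_t)T * H * W * C * N : 1);
  if (need_dx) dx.attr("dim") = xd;

  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWmat(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat Pm(K, P);

  const size_t xstep = (size_t)T * H * W * C;
  const size_t ystep = (size_t)P * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat dYmat(const_cast<double*>(dy.begin()) + n * ystep, P, Cout, false, true);
    im2col(x.begin() + n * xstep, T, H, W, C, kt, kh, kw, st, sh, sw,
           pt, ph, pw, To, Ho, Wo, Pm);
    dWmat += Pm * dYmat;
    dbv += arma::sum(dYmat, 0).t();
    if (need_dx) {
      arma::mat dP = Wmat * dYmat.t(); // K x P
      col2im_add(dP, T, H, W, C, kt, kh, kw, st, sh, sw, pt, ph, pw,
                 To, Ho, Wo, dx.begin() + n * xstep);
    }
  }
  return List::create(Named("dw") = dw, Named("db") = db,
                      Named("dx") = need_dx ? SEXP(dx) : R_NilValue);
}
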
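// 2-D multi-channel convolution kernels (zero-padded, stride 1) and their
// gradients. These back the residual convolutional regularizer; plain loops
// ordered for column-major locality are fast enough at the image sizes the
// package trains on.
#include <Rcpp.h>
using namespace Rcpp;

// x: (H, W, Cin), w: (KH, KW, Cin, Cout), b: (Cout) -> out (H, W, Cout)
// "same" zero padding; kernel center at (KH/2, KW/2) (0-based).
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("channel mismatch in conv2d_fwd");
  const int ph = KH / 2, pw = KW / 2;
  NumericVector out(H * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *px = x.begin(), *pw_ = w.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bias = pb[co];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        po[i + H * (j + W * co)] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (size_t)H * W * ci;
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const double wv = pw_[kh + KH * (kw + KW * (ci + Cin * co))];
          if (wv == 0.0) continue;
          const int di = kh - ph, dj = kw - pw;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xc + (size_t)H * (j + dj) + di;
            double *ocol = po + i0 + (size_t)H * (j + W * co);
            const double *xp = xcol + i0;
            const int n = i1 - i0;
            for (int i = 0; i < n; ++i) ocol[i] += wv * xp[i];
          }
        }
      }
    }
  }
  return out;
}

// gradients of sum(loss) wrt x, w, b given upstream gradient gy (H, W, Cout)
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2];
  const int KH = dw[0], KW = dw[1], Cout = dw[3];
  const int ph = KH / 2, pw = KW / 2;
  NumericVector gx(H * W * Cin), gw(KH * KW * Cin * Cout), gb(Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = dw;
  const double *px = x.begin(), *pw_ = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gc = pg + (size_t)H * W * co;
    double s = 0.0;
    for (size_t k = 0; k < (size_t)H * W; ++k) s += gc[k];
    pgb[co] += s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (size_t)H * W * ci;
      double *gxc = pgx + (size_t)H * W * ci;
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const int di = kh - ph, dj = kw - pw;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double wv = pw_[kh + KH * (kw + KW * (ci + Cin * co))];
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double *xp = xc + (size_t)H * (j + dj) + di + i0;
            const double *gp = gc + (size_t)H * j + i0;
            double *gxp = gxc + (size_t)H * (j + dj) + di + i0;
            const int n = i1 - i0;
            for (int i = 0; i < n; ++i) {
              acc += xp[i] * gp[i];
              gxp[i] += wv * gp[i];
            }
          }
          pgw[kh + KH * (kw + KW * (ci + Cin * co))] += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
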
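#include <Rcpp.h>
using namespace Rcpp;

// 2D convolution with stride 1 and zero "same" padding, for small CNNs.
// x: (H, W, Cin) array, w: (kh, kw, Cin, Cout), b: length Cout.
// R arrays are column-major: x[i,j,k] lives at i + H*j + H*W*k.

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = kh / 2, pw = kw / 2;
  NumericVector y(H * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *X = x.begin(), *Wt = w.begin(), *B = b.begin();
  double *Y = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = B[co];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        Y[i + H * j + H * W * co] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *Xc = X + (size_t)H * W * ci;
      for (int v = 0; v < kw; ++v) {
        for (int u = 0; u < kh; ++u) {
          double wt = Wt[u + kh * v + kh * kw * ci + kh * kw * Cin * co];
          if (wt == 0.0) continue;
          int di = u - ph, dj = v - pw;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int j = j0; j < j1; ++j) {
            const double *src = Xc + (size_t)H * (j + dj);
            double *dst = Y + (size_t)H * j + (size_t)H * W * co;
            for (int i = i0; i < i1; ++i) dst[i] += wt * src[i + di];
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: given upstream gradient gy (H, W, Cout), return gradients
// with respect to the input, the weights and the bias.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = kh / 2, pw = kw / 2;
  NumericVector gx(H * W * Cin), gw(kh * kw * Cin * Cout), gb(Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  const double *X = x.begin(), *Wt = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin(), *GB = gb.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *Gc = GY + (size_t)H * W * co;
    double s = 0.0;
    for (int t = 0; t < H * W; ++t) s += Gc[t];
    GB[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *Xc = X + (size_t)H * W * ci;
      double *GXc = GX + (size_t)H * W * ci;
      for (int v = 0; v < kw; ++v) {
        for (int u = 0; u < kh; ++u) {
          int di = u - ph, dj = v - pw;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          double wt = Wt[u + kh * v + kh * kw * ci + kh * kw * Cin * co];
          double acc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double *src = Xc + (size_t)H * (j + dj);
            const double *g = Gc + (size_t)H * j;
            double *gxp = GXc + (size_t)H * (j + dj);
            for (int i = i0; i < i1; ++i) {
              acc += g[i] * src[i + di];
              gxp[i + di] += g[i] * wt;
            }
          }
          GW[u + kh * v + kh * kw * ci + kh * kw * Cin * co] = acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
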
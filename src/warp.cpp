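#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sampling of a 2D image at arbitrary (row, col) coordinates.
// Coordinates are 0-based; samples falling outside the image contribute 0
// (out-of-bounds corners of the interpolation cell are treated as 0).

static inline double sample_one(const NumericMatrix &img, double r, double c) {
  int H = img.nrow(), W = img.ncol();
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int rr = r0 + dr;
    if (rr < 0 || rr >= H) continue;
    double wr = dr ? fr : 1.0 - fr;
    for (int dc = 0; dc <= 1; ++dc) {
      int cc = c0 + dc;
      if (cc < 0 || cc >= W) continue;
      double wc = dc ? fc : 1.0 - fc;
      v += wr * wc * img(rr, cc);
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_bilinear(NumericMatrix img, NumericMatrix mapr,
                                  NumericMatrix mapc) {
  int H = mapr.nrow(), W = mapr.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = sample_one(img, mapr(i, j), mapc(i, j));
  return out;
}

// Gradient of sum(gout * sampled) with respect to the sampling coordinates.
// Returns d/d mapr and d/d mapc, the backward pass of a spatial-transformer
// style warp where only the coordinates (the flow) are learnable.
// [[Rcpp::export]]
List cpp_sample_bilinear_grad(NumericMatrix img, NumericMatrix mapr,
                              NumericMatrix mapc, NumericMatrix gout) {
  int H = mapr.nrow(), W = mapr.ncol();
  int IH = img.nrow(), IW = img.ncol();
  NumericMatrix gr(H, W), gc(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double r = mapr(i, j), c = mapc(i, j);
      int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      double fr = r - r0, fc = c - c0;
      // image values at the 4 cell corners, 0 outside
      double v[2][2];
      for (int dr = 0; dr <= 1; ++dr)
        for (int dc = 0; dc <= 1; ++dc) {
          int rr = r0 + dr, cc = c0 + dc;
          v[dr][dc] = (rr < 0 || rr >= IH || cc < 0 || cc >= IW)
                          ? 0.0
                          : img(rr, cc);
        }
      double dvdr = (1.0 - fc) * (v[1][0] - v[0][0]) + fc * (v[1][1] - v[0][1]);
      double dvdc = (1.0 - fr) * (v[0][1] - v[0][0]) + fr * (v[1][1] - v[1][0]);
      gr(i, j) = gout(i, j) * dvdr;
      gc(i, j) = gout(i, j) * dvdc;
    }
  }
  return List::create(_["gr"] = gr, _["gc"] = gc);
}
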
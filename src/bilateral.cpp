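// Brute-force bilateral filter, window truncated at 3*sigma_spatial.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".bilateral_filter")]]
NumericMatrix bilateral_filter(NumericMatrix img, double sigma_s,
                               double sigma_r) {
  int H = img.nrow(), W = img.ncol();
  int rad = (int)std::ceil(3.0 * sigma_s);
  if (rad < 1) rad = 1;
  std::vector<double> gs(2 * rad + 1);
  for (int k = -rad; k <= rad; ++k)
    gs[k + rad] = std::exp(-0.5 * k * k / (sigma_s * sigma_s));
  double inv2r2 = 0.5 / (sigma_r * sigma_r);
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double c = img(i, j), num = 0, den = 0;
      int i0 = std::max(0, i - rad), i1 = std::min(H - 1, i + rad);
      int j0 = std::max(0, j - rad), j1 = std::min(W - 1, j + rad);
      for (int jj = j0; jj <= j1; ++jj) {
        double wj = gs[jj - j + rad];
        for (int ii = i0; ii <= i1; ++ii) {
          double v = img(ii, jj);
          double dv = v - c;
          double w = wj * gs[ii - i + rad] * std::exp(-dv * dv * inv2r2);
          num += w * v;
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}
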
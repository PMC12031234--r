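// Spatial filters used by the preprocessing chain. Reflect padding at the
// borders everywhere, matching the R-level contract.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int refl(int i, int n) {
  // reflect-101-less: mirror without repeating the edge twice is the usual
  // "reflect" (abcba); here we use symmetric reflect (abccba) which is what
  // base R / scipy mode "reflect" does for kernel radius < n.
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int kernel) {
  int H = img.nrow(), W = img.ncol(), r = kernel / 2, K = kernel * kernel;
  NumericMatrix out(H, W);
  std::vector<double> buf(K);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int t = 0;
      for (int dj = -r; dj <= r; ++dj)
        for (int di = -r; di <= r; ++di)
          buf[t++] = img(refl(i + di, H), refl(j + dj, W));
      std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
      double m = buf[K / 2];
      if (K % 2 == 0) {  // even count cannot happen for odd kernels; kept safe
        std::nth_element(buf.begin(), buf.begin() + K / 2 - 1, buf.end());
        m = 0.5 * (m + buf[K / 2 - 1]);
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Grayscale morphology over a disk structuring element: op 0 = dilate (max),
// op 1 = erode (min). The disk contains offsets with di^2 + dj^2 <= radius^2.
// [[Rcpp::export]]
NumericMatrix morph_filter_cpp(NumericMatrix img, int radius, int op) {
  int H = img.nrow(), W = img.ncol();
  std::vector<std::pair<int, int>> offs;
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      if (di * di + dj * dj <= radius * radius) offs.push_back({di, dj});
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = img(refl(i + offs[0].first, H), refl(j + offs[0].second, W));
      for (size_t t = 1; t < offs.size(); ++t) {
        double u = img(refl(i + offs[t].first, H),
                       refl(j + offs[t].second, W));
        v = op == 0 ? std::max(v, u) : std::min(v, u);
      }
      out(i, j) = v;
    }
  return out;
}
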
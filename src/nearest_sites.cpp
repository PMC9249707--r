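#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest and second-nearest jittered hexagonal lattice site per pixel.
// Sites live on rows y = j*h (x staggered by d/2 on odd rows) with per-site
// jitter (sx, sy) and brightness sv, indexed column-major over
// i in [imin, imax], j in [jmin, jmax]. Pixels are the n x n grid with
// x = column, y = row (0-based); output vectors are column-major.
// Only the 3x3 lattice neighbourhood of each pixel is searched, which is
// exact for the jitter magnitudes the generator uses.
// [[Rcpp::export]]
List nearest_two_sites(int n, double d, double h,
                       int imin, int imax, int jmin, int jmax,
                       NumericVector sx, NumericVector sy, NumericVector sv) {
  const int ni = imax - imin + 1;
  NumericVector d1(n * n), d2(n * n), v1(n * n);
  for (int col = 0; col < n; ++col) {
    const double x = col;
    for (int row = 0; row < n; ++row) {
      const double y = row;
      const int j0 = (int) std::lround(y / h);
      double b1 = R_PosInf, b2 = R_PosInf, bv = 0.0;
      for (int dj = -1; dj <= 1; ++dj) {
        int j = j0 + dj;
        if (j < jmin) j = jmin; else if (j > jmax) j = jmax;
        const double xoff = (((j % 2) + 2) % 2) * (d / 2.0);
        const int i0 = (int) std::lround((x - xoff) / d);
        for (int di = -1; di <= 1; ++di) {
          int i = i0 + di;
          if (i < imin) i = imin; else if (i > imax) i = imax;
          const int idx = (i - imin) + (j - jmin) * ni;
          const double ddx = x - (i * d + xoff + sx[idx]);
          const double ddy = y - (j * h + sy[idx]);
          const double dist2 = ddx * ddx + ddy * ddy;
          if (dist2 < b1) {
            b2 = b1; b1 = dist2; bv = sv[idx];
          } else if (dist2 < b2) {
            b2 = dist2;
          }
        }
      }
      const int k = col * n + row;
      d1[k] = b1;
      d2[k] = b2;
      v1[k] = bv;
    }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["v1"] = v1);
}
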
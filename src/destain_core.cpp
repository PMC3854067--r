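#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rolling-ball background estimate: grayscale opening of the image with a
// non-flat spherical structuring element of the given radius. Heights are
// h(dr,dc) = sqrt(R^2 - dr^2 - dc^2) in intensity units. Out-of-bounds
// neighbours are skipped, which keeps the opening <= image everywhere.
// [[Rcpp::export]]
NumericMatrix rolling_ball_background(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ri = (int)std::floor(radius);
  std::vector<int> dr, dc;
  std::vector<double> h;
  for (int a = -ri; a <= ri; ++a) {
    for (int b = -ri; b <= ri; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        dr.push_back(a);
        dc.push_back(b);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
  const int k = (int)dr.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  // erosion: e(x) = min_d img(x + d) - h(d)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_PosInf;
      for (int j = 0; j < k; ++j) {
        int rr = r + dr[j], cc = c + dc[j];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) - h[j];
        if (v < m) m = v;
      }
      ero(r, c) = m;
    }
  }
  // dilation (SE symmetric): bg(x) = max_d e(x + d) + h(d)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (int j = 0; j < k; ++j) {
        int rr = r + dr[j], cc = c + dc[j];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = ero(rr, cc) + h[j];
        if (v > m) m = v;
      }
      bg(r, c) = m;
    }
  }
  return bg;
}

// Normalized cross-correlation over every integer displacement within
// +/- max_shift. Entry [i, j] is the Pearson correlation between
// ref(r, c) and mov(r + dr, c + dc) over the overlap, with
// dr = i - max_shift - 1, dc = j - max_shift - 1 (1-based from R).
// Overlaps with zero variance on either side give NA.
// [[Rcpp::export]]
NumericMatrix ncc_shift_surface(NumericMatrix ref, NumericMatrix mov,
                                int max_shift) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int w = 2 * max_shift + 1;
  NumericMatrix out(w, w);
  for (int i = 0; i < w; ++i) {
    int dr = i - max_shift;
    int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
    for (int j = 0; j < w; ++j) {
      int dc = j - max_shift;
      int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      long n = 0;
      for (int c = c0; c < c1; ++c) {
        for (int r = r0; r < r1; ++r) {
          double x = ref(r, c), y = mov(r + dr, c + dc);
          sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
          ++n;
        }
      }
      if (n < 2) { out(i, j) = NA_REAL; continue; }
      double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
      if (vx <= 0 || vy <= 0) { out(i, j) = NA_REAL; continue; }
      out(i, j) = (sxy - sx * sy / n) / std::sqrt(vx * vy);
    }
  }
  return out;
}
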
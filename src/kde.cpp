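#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Evaluate a 2-D Gaussian kernel density estimate on a rectangular grid.
//
// The kernel covariance (bandwidth) is passed in as the 2x2 matrix
// {c11, c12, c22}; callers apply Scott's rule upstream. Each point's
// kernel is truncated at 8 sigma (mass loss < 1e-14), which turns the
// naive O(n * grid) sum into a per-point local window update.
//
// Returns a gx x gy matrix of densities (rows follow gx).
// [[Rcpp::export]]
NumericMatrix kde_grid_eval(NumericVector x, NumericVector y,
                            NumericVector gx, NumericVector gy,
                            double c11, double c12, double c22) {
  const int n = x.size();
  const int nx = gx.size(), ny = gy.size();
  NumericMatrix out(nx, ny);

  const double det = c11 * c22 - c12 * c12;
  if (det <= 0.0 || n == 0)
    stop("kde_grid_eval: singular kernel covariance");
  const double i11 = c22 / det, i12 = -c12 / det, i22 = c11 / det;
  const double norm = 1.0 / (2.0 * M_PI * std::sqrt(det) * n);

  // window half-widths: 8 * marginal sigma
  const double wx = 8.0 * std::sqrt(c11);
  const double wy = 8.0 * std::sqrt(c22);
  const double dx = nx > 1 ? gx[1] - gx[0] : 1.0;
  const double dy = ny > 1 ? gy[1] - gy[0] : 1.0;

  for (int p = 0; p < n; ++p) {
    int i0 = (int)std::floor((x[p] - wx - gx[0]) / dx);
    int i1 = (int)std::ceil((x[p] + wx - gx[0]) / dx);
    int j0 = (int)std::floor((y[p] - wy - gy[0]) / dy);
    int j1 = (int)std::ceil((y[p] + wy - gy[0]) / dy);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    for (int i = i0; i <= i1; ++i) {
      const double u = gx[i] - x[p];
      for (int j = j0; j <= j1; ++j) {
        const double v = gy[j] - y[p];
        const double q = u * (i11 * u + i12 * v) + v * (i12 * u + i22 * v);
        if (q < 128.0) out(i, j) += norm * std::exp(-0.5 * q);
      }
    }
  }
  return out;
}
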
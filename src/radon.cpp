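// Parallel-beam Radon transform and backprojection for the phantom simulator.
// The image is sampled on a unit-pitch grid; rays are integrated with
// bilinear interpolation at a fixed arc-length step. Angles are spaced
// uniformly over [0, pi).

#include <Rcpp.h>
using namespace Rcpp;

static inline double bilin(const NumericMatrix& img, double X, double Y) {
  // X is the column coordinate, Y the row coordinate (0-based)
  const int h = img.nrow(), w = img.ncol();
  if (X < 0.0 || Y < 0.0 || X > w - 1.0 || Y > h - 1.0) return 0.0;
  int j0 = (int)std::floor(X), i0 = (int)std::floor(Y);
  if (j0 == w - 1) j0--;
  if (i0 == h - 1) i0--;
  const double fx = X - j0, fy = Y - i0;
  return (1 - fx) * ((1 - fy) * img(i0, j0) + fy * img(i0 + 1, j0)) +
         fx * ((1 - fy) * img(i0, j0 + 1) + fy * img(i0 + 1, j0 + 1));
}

// [[Rcpp::export]]
NumericMatrix cpp_radon_fw(NumericMatrix img, int n_angles, int n_det, double step) {
  const int h = img.nrow(), w = img.ncol();
  const double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  const double L = std::sqrt((double)h * h + (double)w * w);
  const int n_s = (int)std::ceil(L / step) + 1;
  const double t0 = -(n_det - 1) / 2.0;
  NumericMatrix sino(n_angles, n_det);
  for (int a = 0; a < n_angles; ++a) {
    const double th = M_PI * a / n_angles;
    const double ct = std::cos(th), st = std::sin(th);
    for (int k = 0; k < n_det; ++k) {
      const double t = t0 + k;
      const double bx = cx + t * ct, by = cy + t * st;
      double acc = 0.0;
      for (int m = 0; m < n_s; ++m) {
        const double u = -L / 2.0 + m * step;
        acc += bilin(img, bx - u * st, by + u * ct);
      }
      sino(a, k) = acc * step;
    }
  }
  return sino;
}

// Backproject a (filtered) sinogram onto a size x size grid, with linear
// interpolation along the detector axis. The pi/(2*n_angles) scaling is
// applied by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_radon_bp(NumericMatrix sino, int size) {
  const int n_angles = sino.nrow(), n_det = sino.ncol();
  const double c0 = (size - 1) / 2.0;
  const double t0 = (n_det - 1) / 2.0;
  NumericMatrix img(size, size);
  std::vector<double> ct(n_angles), st(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    const double th = M_PI * a / n_angles;
    ct[a] = std::cos(th);
    st[a] = std::sin(th);
  }
  for (int j = 0; j < size; ++j) {
    const double X = j - c0;
    for (int i = 0; i < size; ++i) {
      const double Y = i - c0;
      double acc = 0.0;
      for (int a = 0; a < n_angles; ++a) {
        const double t = X * ct[a] + Y * st[a] + t0;
        if (t < 0.0 || t > n_det - 1.0) continue;
        int k0 = (int)std::floor(t);
        if (k0 == n_det - 1) k0--;
        const double f = t - k0;
        acc += (1 - f) * sino(a, k0) + f * sino(a, k0 + 1);
      }
      img(i, j) = acc;
    }
  }
  return img;
}
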
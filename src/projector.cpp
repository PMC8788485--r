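#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Antiderivative of the strip-projection footprint of a square pixel.
// The projection of a square of side px onto the detector axis at angle
// theta is the convolution of two boxes of widths px*|cos| and px*|sin|:
// a trapezoid of total integral px^2 (the pixel area), plateau half-width
// B = (hi-lo)/2, support half-width A = (hi+lo)/2, height h = px^2/hi.
static inline double trap_F(double t, double A, double B, double h,
                            double lo, double area) {
  if (t <= -A) return 0.0;
  if (t >=  A) return area;
  if (lo <= 1e-12) return h * (t + A); // degenerate box (axis-aligned angle)
  if (t < -B) { double d = t + A; return 0.5 * h * d * d / lo; }
  if (t <= B) return 0.5 * h * lo + h * (t + B);
  double d = A - t; return area - 0.5 * h * d * d / lo;
}

// Parallel-beam strip-integral system matrix in triplet form.
// Rows i = angle * n_bins + bin, columns j = col * grid_size + row
// (R column-major order of a grid_size x grid_size image).
// Entry = area of pixel j inside the strip of bin i, in units of
// (reference-pixel)^2: bin_width and px are both expressed in the
// physical units of the reference LR grid, so the same geometry serves
// LR (px = 1) and finer super-resolution grids (px = 1/2).
// [[Rcpp::export]]
List build_strip_matrix_cpp(int n_bins, int n_angles, double angular_span,
                            double bin_width, int grid_size, double px) {
  const double s0 = -0.5 * n_bins * bin_width; // detector axis centered on FOV
  const double area = px * px;
  std::vector<int> ri, ci;
  std::vector<double> xv;
  size_t guess = (size_t)n_angles * grid_size * grid_size * 2;
  ri.reserve(guess); ci.reserve(guess); xv.reserve(guess);

  for (int t = 0; t < n_angles; ++t) {
    double th = t * angular_span / n_angles;
    double c = std::cos(th), s = std::sin(th);
    double u = px * std::fabs(c), v = px * std::fabs(s);
    double hi = u > v ? u : v, lo = u > v ? v : u;
    double A = 0.5 * (hi + lo), B = 0.5 * (hi - lo);
    double h = area / hi;
    for (int col = 0; col < grid_size; ++col) {
      double x = (col + 0.5 - 0.5 * grid_size) * px;
      for (int row = 0; row < grid_size; ++row) {
        double y = (row + 0.5 - 0.5 * grid_size) * px;
        double sc = x * c + y * s;
        int b0 = (int)std::floor((sc - A - s0) / bin_width);
        int b1 = (int)std::floor((sc + A - s0) / bin_width);
        if (b0 < 0) b0 = 0;
        if (b1 > n_bins - 1) b1 = n_bins - 1;
        for (int b = b0; b <= b1; ++b) {
          double e1 = s0 + b * bin_width - sc;
          double w = trap_F(e1 + bin_width, A, B, h, lo, area) -
                     trap_F(e1, A, B, h, lo, area);
          if (w > 1e-14) {
            ri.push_back(t * n_bins + b);
            ci.push_back(col * grid_size + row);
            xv.push_back(w);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xv));
}
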
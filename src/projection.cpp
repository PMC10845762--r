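// Parallel-beam line-integral projector (Joseph-style, bilinear in the
// transverse coordinate), its exact adjoint, and a pixel-driven
// backprojector with linear detector interpolation for FBP.
//
// Conventions (documented in ?scan_geometry):
//   image row i (0-based, top) -> y = ((n-1)/2 - i) * pixel_size
//   image col j               -> x = (j - (n-1)/2) * pixel_size
//   detector bin k            -> s = (k - (n_bins-1)/2) * bin_spacing
//   view angle theta (rad), counter-clockwise from +x; ray direction
//   (-sin, cos), detector coordinate s = x cos + y sin.
#ifdef __GNUC__
#pragma GCC optimize("O3")
#endif
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles,
                                  int n_bins, double bin_spacing,
                                  double pixel_size) {
  const int n = img.nrow();
  const int nv = angles.size();
  NumericMatrix sino(n_bins, nv);
  const double half = (n - 1) / 2.0;
  const double shalf = (n_bins - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]), si = std::sin(angles[v]);
    const double dx = -si, dy = c;  // unit ray direction
    for (int k = 0; k < n_bins; ++k) {
      const double s = (k - shalf) * bin_spacing;
      double acc = 0.0;
      if (std::fabs(dx) >= std::fabs(dy)) {
        // march across columns
        const double step = pixel_size / std::fabs(dx);
        for (int j = 0; j < n; ++j) {
          const double x = (j - half) * pixel_size;
          const double t = (x - s * c) / dx;
          const double y = s * si + t * dy;
          const double fi = half - y / pixel_size;  // continuous row
          const int i0 = (int)std::floor(fi);
          const double f = fi - i0;
          double val = 0.0;
          if (i0 >= 0 && i0 < n) val += img(i0, j) * (1.0 - f);
          if (i0 + 1 >= 0 && i0 + 1 < n) val += img(i0 + 1, j) * f;
          acc += val;
        }
        acc *= step;
      } else {
        // march across rows
        const double step = pixel_size / std::fabs(dy);
        for (int i = 0; i < n; ++i) {
          const double y = (half - i) * pixel_size;
          const double t = (y - s * si) / dy;
          const double x = s * c + t * dx;
          const double fj = x / pixel_size + half;  // continuous column
          const int j0 = (int)std::floor(fj);
          const double f = fj - j0;
          double val = 0.0;
          if (j0 >= 0 && j0 < n) val += img(i, j0) * (1.0 - f);
          if (j0 + 1 >= 0 && j0 + 1 < n) val += img(i, j0 + 1) * f;
          acc += val;
        }
        acc *= step;
      }
      sino(k, v) = acc;
    }
  }
  return sino;
}

// Exact transpose of cpp_forward_project, used as A^T in iterative
// reconstruction so that the data-term gradient is a true gradient.
// [[Rcpp::export]]
NumericMatrix cpp_forward_adjoint(NumericMatrix sino, NumericVector angles,
                                  int n, double bin_spacing,
                                  double pixel_size) {
  const int n_bins = sino.nrow();
  const int nv = angles.size();
  NumericMatrix img(n, n);
  const double half = (n - 1) / 2.0;
  const double shalf = (n_bins - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]), si = std::sin(angles[v]);
    const double dx = -si, dy = c;
    for (int k = 0; k < n_bins; ++k) {
      const double g = sino(k, v);
      if (g == 0.0) continue;
      const double s = (k - shalf) * bin_spacing;
      if (std::fabs(dx) >= std::fabs(dy)) {
        const double w = g * pixel_size / std::fabs(dx);
        for (int j = 0; j < n; ++j) {
          const double x = (j - half) * pixel_size;
          const double t = (x - s * c) / dx;
          const double y = s * si + t * dy;
          const double fi = half - y / pixel_size;
          const int i0 = (int)std::floor(fi);
          const double f = fi - i0;
          if (i0 >= 0 && i0 < n) img(i0, j) += w * (1.0 - f);
          if (i0 + 1 >= 0 && i0 + 1 < n) img(i0 + 1, j) += w * f;
        }
      } else {
        const double w = g * pixel_size / std::fabs(dy);
        for (int i = 0; i < n; ++i) {
          const double y = (half - i) * pixel_size;
          const double t = (y - s * si) / dy;
          const double x = s * c + t * dx;
          const double fj = x / pixel_size + half;
          const int j0 = (int)std::floor(fj);
          const double f = fj - j0;
          if (j0 >= 0 && j0 < n) img(i, j0) += w * (1.0 - f);
          if (j0 + 1 >= 0 && j0 + 1 < n) img(i, j0 + 1) += w * f;
        }
      }
    }
  }
  return img;
}

// Pixel-driven backprojection with linear interpolation in the detector
// coordinate; tie at an exact half-bin resolves toward the lower index
// (floor). Used by filtered backprojection.
// [[Rcpp::export]]
NumericMatrix cpp_pixel_backproject(NumericMatrix sino, NumericVector angles,
                                    int n, double bin_spacing,
                                    double pixel_size) {
  const int n_bins = sino.nrow();
  const int nv = angles.size();
  NumericMatrix img(n, n);
  const double half = (n - 1) / 2.0;
  const double shalf = (n_bins - 1) / 2.0;
  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]), si = std::sin(angles[v]);
    for (int j = 0; j < n; ++j) {
      const double x = (j - half) * pixel_size;
      for (int i = 0; i < n; ++i) {
        const double y = (half - i) * pixel_size;
        const double u = (x * c + y * si) / bin_spacing + shalf;
        const int k0 = (int)std::floor(u);
        const double f = u - k0;
        double val = 0.0;
        if (k0 >= 0 && k0 < n_bins) val += sino(k0, v) * (1.0 - f);
        if (k0 + 1 >= 0 && k0 + 1 < n_bins) val += sino(k0 + 1, v) * f;
        img(i, j) += val;
      }
    }
  }
  return img;
}

// Bilinear sampling of an image at fractional (row, col) positions
// (1-based, matching R indexing); used by line_profile.
// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector rows,
                                  NumericVector cols) {
  const int n = rows.size();
  const int nr = img.nrow(), nc = img.ncol();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double ri = rows[p] - 1.0, cj = cols[p] - 1.0;
    if (ri < 0) ri = 0; if (ri > nr - 1) ri = nr - 1;
    if (cj < 0) cj = 0; if (cj > nc - 1) cj = nc - 1;
    int i0 = (int)std::floor(ri), j0 = (int)std::floor(cj);
    if (i0 > nr - 2) i0 = nr - 2;
    if (j0 > nc - 2) j0 = nc - 2;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    const double fi = ri - i0, fj = cj - j0;
    out[p] = img(i0, j0) * (1 - fi) * (1 - fj) +
             img(i0 + 1, j0) * fi * (1 - fj) +
             img(i0, j0 + 1) * (1 - fi) * fj +
             img(i0 + 1, j0 + 1) * fi * fj;
  }
  return out;
}
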
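#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Offsets of a Euclidean disk of the given radius: dx^2 + dy^2 <= r^2.
static void disk_offsets(double radius, std::vector<int> &dx, std::vector<int> &dy) {
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int j = -r; j <= r; ++j)
    for (int i = -r; i <= r; ++i)
      if ((double)i * i + (double)j * j <= r2) {
        dx.push_back(i);
        dy.push_back(j);
      }
}

// Median filter over a Euclidean disk, boundary by edge replication.
// x is an nrow x ncol matrix (R column-major).
// [[Rcpp::export(name = ".disk_median_cpp")]]
NumericMatrix disk_median_cpp(NumericMatrix x, double radius) {
  int nr = x.nrow(), nc = x.ncol();
  std::vector<int> dx, dy;
  disk_offsets(radius, dx, dy);
  size_t k = dx.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (size_t m = 0; m < k; ++m) {
        int ii = i + dx[m];
        int jj = j + dy[m];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        buf[m] = x(ii, jj);
      }
      size_t mid = k / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (k % 2 == 0) {
        // R's median of an even count averages the two middle order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Grayscale erosion/dilation by a hemispherical (ball) structuring element
// b(v) = height_scale * sqrt(r^2 - |v|^2). Out-of-bounds neighbours are
// ignored, which is the +Inf (erosion) / -Inf (dilation) padding convention.
// height_scale != 1 turns the ball into an ellipsoid; the downsampled
// rolling-ball path uses it to keep the intensity semi-axis at the full
// radius while the spatial extent is divided by the shrink factor.
// [[Rcpp::export(name = ".ball_morph_cpp")]]
NumericMatrix ball_morph_cpp(NumericMatrix x, double radius, bool erode,
                             double height_scale = 1.0) {
  int nr = x.nrow(), nc = x.ncol();
  std::vector<int> dx, dy;
  disk_offsets(radius, dx, dy);
  size_t k = dx.size();
  std::vector<double> h(k);
  for (size_t m = 0; m < k; ++m)
    h[m] = height_scale *
      std::sqrt(radius * radius - (double)(dx[m] * dx[m] + dy[m] * dy[m]));
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = erode ? R_PosInf : R_NegInf;
      for (size_t m = 0; m < k; ++m) {
        int ii = i + dx[m];
        int jj = j + dy[m];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = erode ? x(ii, jj) - h[m] : x(ii, jj) + h[m];
        if (erode ? (v < acc) : (v > acc)) acc = v;
      }
      out(i, j) = acc;
    }
  }
  return out;
}
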
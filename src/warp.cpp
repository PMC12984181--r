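// Bicubic (Catmull-Rom) resampling under rigid transforms: frame synthesis
// from a reference texture, scale normalization, and feathered warp patches
// for incremental mosaicking.
//
// Rigid map convention (matches the R side): destination pixel u = (x, y),
// source coords v = R(theta) %*% (prescale * u) + t, with
// R = [cos -sin; sin cos] acting on (x, y), 0-based pixel centers.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline void cubic_w(double t, double* w) {
  // Catmull-Rom, a = -0.5
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// bicubic sample with clamped borders; caller guarantees finite x, y
static double bicubic(const double* img, int h, int w, double x, double y) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double wx[4], wy[4];
  cubic_w(x - x0, wx);
  cubic_w(y - y0, wy);
  double acc = 0.0;
  for (int m = 0; m < 4; ++m) {
    int yy = clampi(y0 - 1 + m, 0, h - 1);
    double row = 0.0;
    for (int n = 0; n < 4; ++n) {
      int xx = clampi(x0 - 1 + n, 0, w - 1);
      row += wx[n] * img[(size_t)xx * h + yy];  // column-major (R layout)
    }
    acc += wy[m] * row;
  }
  return acc;
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sample_rigid(NumericVector src, IntegerVector src_dim,
                               int out_h, int out_w,
                               double theta, double tx, double ty,
                               double prescale, double fill) {
  int h = src_dim[0], w = src_dim[1];
  int nc = src_dim.size() > 2 ? src_dim[2] : 1;
  double ct = std::cos(theta), st = std::sin(theta);
  NumericVector out((size_t)out_h * out_w * nc);
  const double* sp = src.begin();
  double* op = out.begin();
  for (int x = 0; x < out_w; ++x) {
    for (int y = 0; y < out_h; ++y) {
      double u = prescale * x, v = prescale * y;
      double sx = ct * u - st * v + tx;
      double sy = st * u + ct * v + ty;
      bool inside = sx >= 0.0 && sx <= w - 1.0 && sy >= 0.0 && sy <= h - 1.0;
      for (int c = 0; c < nc; ++c) {
        double val = inside
          ? bicubic(sp + (size_t)c * h * w, h, w, sx, sy)
          : fill;
        op[(size_t)c * out_h * out_w + (size_t)x * out_h + y] = val;
      }
    }
  }
  if (nc > 1)
    out.attr("dim") = IntegerVector::create(out_h, out_w, nc);
  else
    out.attr("dim") = IntegerVector::create(out_h, out_w);
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_warp_patch(NumericVector frame, IntegerVector frame_dim,
                    double theta, double tx, double ty,
                    int x0, int y0, int out_w, int out_h) {
  // Frame pixel p maps to canvas coords R(theta) p + t; for each canvas pixel
  // (x0 + j, y0 + i) invert, sample bicubically, and return a linear
  // edge-distance feather weight (zero where the frame does not cover).
  int h = frame_dim[0], w = frame_dim[1];
  int nc = frame_dim.size() > 2 ? frame_dim[2] : 1;
  double ct = std::cos(theta), st = std::sin(theta);
  NumericVector val((size_t)out_h * out_w * nc);
  NumericMatrix wgt(out_h, out_w);
  const double* fp = frame.begin();
  double* vp = val.begin();
  for (int j = 0; j < out_w; ++j) {
    for (int i = 0; i < out_h; ++i) {
      double cx = x0 + j - tx, cy = y0 + i - ty;
      double px = ct * cx + st * cy;   // R(-theta) applied
      double py = -st * cx + ct * cy;
      if (px < 0.0 || px > w - 1.0 || py < 0.0 || py > h - 1.0) continue;
      double dedge = std::min(std::min(px, w - 1.0 - px),
                              std::min(py, h - 1.0 - py)) + 0.5;
      wgt(i, j) = dedge;
      for (int c = 0; c < nc; ++c)
        vp[(size_t)c * out_h * out_w + (size_t)j * out_h + i] =
          dedge * bicubic(fp + (size_t)c * h * w, h, w, px, py);
    }
  }
  if (nc > 1)
    val.attr("dim") = IntegerVector::create(out_h, out_w, nc);
  else
    val.attr("dim") = IntegerVector::create(out_h, out_w);
  return List::create(_["wval"] = val, _["w"] = wgt);
}
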
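// Multi-scale keypoint detection and description for rigid image
// registration.  Difference-of-Gaussian extrema with subpixel refinement,
// dominant-orientation assignment and 4x4x8 gradient-histogram descriptors,
// in the style of the classic scale-invariant feature transform.
//
// Image convention: NumericMatrix img(y, x), 0-based pixel coordinates,
// x rightward (column), y downward (row), values in [0, 1].

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double PI2 = 2.0 * M_PI;

// reflect-101 border index (symmetric, no edge duplication)
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

typedef std::vector<double> Vec;

struct Img {
  int h, w;
  Vec d;
  Img() : h(0), w(0) {}
  Img(int h_, int w_) : h(h_), w(w_), d((size_t)h_ * w_, 0.0) {}
  inline double& at(int y, int x) { return d[(size_t)y * w + x]; }
  inline double at(int y, int x) const { return d[(size_t)y * w + x]; }
};

static Img from_matrix(const NumericMatrix& m) {
  Img im(m.nrow(), m.ncol());
  for (int y = 0; y < im.h; ++y)
    for (int x = 0; x < im.w; ++x)
      im.at(y, x) = m(y, x);
  return im;
}

static void gauss_blur_inplace(const Img& src, Img& dst, double sigma) {
  int h = src.h, w = src.w;
  dst = Img(h, w);
  if (sigma <= 0) { dst = src; return; }
  int radius = std::max(1, (int)std::ceil(3.5 * sigma));
  Vec k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double& v : k) v /= s;
  Img tmp(h, w);
  // horizontal pass
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * src.at(y, refl(x + i, w));
      tmp.at(y, x) = acc;
    }
  // vertical pass
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp.at(refl(y + i, h), x);
      dst.at(y, x) = acc;
    }
}

static Img downsample2(const Img& src) {
  Img out((src.h + 1) / 2, (src.w + 1) / 2);
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x)
      out.at(y, x) = src.at(std::min(2 * y, src.h - 1), std::min(2 * x, src.w - 1));
  return out;
}

struct Keypoint {
  double x, y;       // base-image pixel coords
  double sigma;      // absolute scale
  double angle;      // radians in [0, 2*pi)
  double response;   // |DoG| contrast
  int octave, layer;
  double xo, yo;     // coords within octave image
  double sigma_rel;  // scale relative to octave sampling
};

// 36-bin gradient-orientation histogram; returns peak orientations
static void orientation_peaks(const Img& g, double xo, double yo,
                              double sigma_rel, std::vector<double>& out) {
  const int nbins = 36;
  double hist[36] = {0.0};
  double sig_w = 1.5 * sigma_rel;
  int radius = std::max(1, (int)std::lround(3.0 * sig_w));
  int xc = (int)std::lround(xo), yc = (int)std::lround(yo);
  double expf = -0.5 / (sig_w * sig_w);
  for (int i = -radius; i <= radius; ++i) {
    int y = yc + i;
    if (y < 1 || y > g.h - 2) continue;
    for (int j = -radius; j <= radius; ++j) {
      int x = xc + j;
      if (x < 1 || x > g.w - 2) continue;
      double dx = g.at(y, x + 1) - g.at(y, x - 1);
      double dy = g.at(y + 1, x) - g.at(y - 1, x);
      double mag = std::sqrt(dx * dx + dy * dy);
      if (mag <= 0) continue;
      double wgt = std::exp(((double)i * i + (double)j * j) * expf);
      double ang = std::atan2(dy, dx);
      if (ang < 0) ang += PI2;
      int bin = (int)std::floor(ang / PI2 * nbins);
      if (bin >= nbins) bin = nbins - 1;
      hist[bin] += wgt * mag;
    }
  }
  // two passes of circular [1 2 1]/4 smoothing
  for (int pass = 0; pass < 2; ++pass) {
    double prev = hist[nbins - 1], first = hist[0];
    for (int b = 0; b < nbins; ++b) {
      double next = (b == nbins - 1) ? first : hist[b + 1];
      double cur = hist[b];
      hist[b] = 0.25 * prev + 0.5 * cur + 0.25 * next;
      prev = cur;
    }
  }
  double hmax = *std::max_element(hist, hist + nbins);
  if (hmax <= 0) return;
  for (int b = 0; b < nbins; ++b) {
    double l = hist[(b + nbins - 1) % nbins];
    double r = hist[(b + 1) % nbins];
    double c = hist[b];
    if (c > l && c > r && c >= 0.8 * hmax) {
      double denom = l - 2.0 * c + r;
      double off = (std::fabs(denom) > 1e-12) ? 0.5 * (l - r) / denom : 0.0;
      double bin = b + off;
      double ang = bin * PI2 / nbins;
      if (ang < 0) ang += PI2;
      if (ang >= PI2) ang -= PI2;
      out.push_back(ang);
    }
  }
}

// 4x4 spatial x 8 orientation gradient histogram descriptor
static void compute_descriptor(const Img& g, double xo, double yo,
                               double sigma_rel, double angle, double* dst) {
  const int d = 4, n = 8;
  double cos_t = std::cos(angle), sin_t = std::sin(angle);
  double hist_width = 3.0 * sigma_rel;
  int radius = (int)std::lround(hist_width * M_SQRT2 * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)g.h * g.h + (double)g.w * g.w));
  cos_t /= hist_width;
  sin_t /= hist_width;
  double exp_scale = -1.0 / (d * d * 0.5);
  int xc = (int)std::lround(xo), yc = (int)std::lround(yo);
  // (d+2)^3 padded histogram for trilinear scatter
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      // offset (j, i) expressed in the keypoint's rotated frame
      double c_rot = j * cos_t + i * sin_t;
      double r_rot = -j * sin_t + i * cos_t;
      double rbin = r_rot + d / 2 - 0.5;
      double cbin = c_rot + d / 2 - 0.5;
      int y = yc + i, x = xc + j;
      if (rbin > -1 && rbin < d && cbin > -1 && cbin < d &&
          y >= 1 && y <= g.h - 2 && x >= 1 && x <= g.w - 2) {
        double dx = g.at(y, x + 1) - g.at(y, x - 1);
        double dy = g.at(y + 1, x) - g.at(y - 1, x);
        double mag = std::sqrt(dx * dx + dy * dy);
        if (mag <= 0) continue;
        double wgt = std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
        double ang = std::atan2(dy, dx) - angle;
        while (ang < 0) ang += PI2;
        while (ang >= PI2) ang -= PI2;
        double obin = ang / PI2 * n;
        double m = mag * wgt;
        int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
            o0 = (int)std::floor(obin);
        double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
        if (o0 >= n) o0 -= n;
        // trilinear scatter
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc)
            for (int dob = 0; dob <= 1; ++dob) {
              double wv = m * (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc) *
                          (dob ? fo : 1 - fo);
              int rr = r0 + 1 + dr, cc = c0 + 1 + dc, oo = (o0 + dob) % n;
              hist[((size_t)rr * (d + 2) + cc) * (n + 2) + oo] += wv;
            }
      }
    }
  }
  int k = 0;
  double nrm = 0.0;
  for (int r = 1; r <= d; ++r)
    for (int c = 1; c <= d; ++c)
      for (int o = 0; o < n; ++o) {
        dst[k] = hist[((size_t)r * (d + 2) + c) * (n + 2) + o];
        nrm += dst[k] * dst[k];
        ++k;
      }
  nrm = std::sqrt(nrm);
  if (nrm < 1e-12) return;
  double thr = 0.2;
  double nrm2 = 0.0;
  for (int i = 0; i < d * d * n; ++i) {
    dst[i] = std::min(dst[i] / nrm, thr);
    nrm2 += dst[i] * dst[i];
  }
  nrm2 = std::sqrt(nrm2);
  if (nrm2 < 1e-12) return;
  for (int i = 0; i < d * d * n; ++i) dst[i] /= nrm2;
}

//' @noRd
// [[Rcpp::export]]
List cpp_detect_features(NumericMatrix image,
                         double contrast_thresh = 0.03,
                         double edge_thresh = 10.0,
                         double sigma0 = 1.6,
                         int n_scales = 3,
                         int max_octaves = 8,
                         double assumed_blur = 0.5) {
  Img base = from_matrix(image);
  if (base.h < 16 || base.w < 16)
    return List::create(_["keypoints"] = NumericMatrix(0, 5),
                        _["descriptors"] = NumericMatrix(0, 128));
  // bring base image to sigma0
  {
    double sd = std::sqrt(std::max(sigma0 * sigma0 - assumed_blur * assumed_blur, 0.01));
    Img blurred;
    gauss_blur_inplace(base, blurred, sd);
    base = blurred;
  }
  int n_oct = 0;
  {
    int m = std::min(base.h, base.w);
    while (m >= 16 && n_oct < max_octaves) { ++n_oct; m /= 2; }
  }
  int n_g = n_scales + 3;
  // per-octave incremental blur amounts
  Vec sig(n_g);
  sig[0] = sigma0;
  for (int i = 1; i < n_g; ++i) {
    double sp = sigma0 * std::pow(2.0, (double)(i - 1) / n_scales);
    double st = sigma0 * std::pow(2.0, (double)i / n_scales);
    sig[i] = std::sqrt(st * st - sp * sp);
  }
  std::vector<std::vector<Img> > gauss(n_oct), dog(n_oct);
  for (int o = 0; o < n_oct; ++o) {
    gauss[o].resize(n_g);
    dog[o].resize(n_g - 1);
    if (o == 0) gauss[o][0] = base;
    else gauss[o][0] = downsample2(gauss[o - 1][n_scales]);
    for (int i = 1; i < n_g; ++i)
      gauss_blur_inplace(gauss[o][i - 1], gauss[o][i], sig[i]);
    for (int i = 0; i < n_g - 1; ++i) {
      Img d(gauss[o][i].h, gauss[o][i].w);
      for (int y = 0; y < d.h; ++y)
        for (int x = 0; x < d.w; ++x)
          d.at(y, x) = gauss[o][i + 1].at(y, x) - gauss[o][i].at(y, x);
      dog[o][i] = d;
    }
  }

  std::vector<Keypoint> kps;
  const int border = 5;
  double prelim = 0.5 * contrast_thresh / n_scales;
  for (int o = 0; o < n_oct; ++o) {
    int h = dog[o][0].h, w = dog[o][0].w;
    for (int l = 1; l <= n_scales; ++l) {
      const Img& D0 = dog[o][l - 1];
      const Img& D1 = dog[o][l];
      const Img& D2 = dog[o][l + 1];
      for (int y = border; y < h - border; ++y) {
        for (int x = border; x < w - border; ++x) {
          double v = D1.at(y, x);
          if (std::fabs(v) <= prelim) continue;
          bool is_max = true, is_min = true;
          for (int dy = -1; dy <= 1 && (is_max || is_min); ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              double a = D0.at(y + dy, x + dx);
              double b = D1.at(y + dy, x + dx);
              double c = D2.at(y + dy, x + dx);
              if (a > v || c > v || (b > v && !(dy == 0 && dx == 0))) is_max = false;
              if (a < v || c < v || (b < v && !(dy == 0 && dx == 0))) is_min = false;
              if (!is_max && !is_min) break;
            }
          if (!is_max && !is_min) continue;
          // iterative subpixel refinement
          int yy = y, xx = x, ll = l;
          double ox = 0, oy = 0, os = 0, contr = 0;
          bool ok = false;
          for (int it = 0; it < 5; ++it) {
            const Img& Dm = dog[o][ll - 1];
            const Img& Dc = dog[o][ll];
            const Img& Dp = dog[o][ll + 1];
            double gx = 0.5 * (Dc.at(yy, xx + 1) - Dc.at(yy, xx - 1));
            double gy = 0.5 * (Dc.at(yy + 1, xx) - Dc.at(yy - 1, xx));
            double gs = 0.5 * (Dp.at(yy, xx) - Dm.at(yy, xx));
            double dxx = Dc.at(yy, xx + 1) + Dc.at(yy, xx - 1) - 2 * Dc.at(yy, xx);
            double dyy = Dc.at(yy + 1, xx) + Dc.at(yy - 1, xx) - 2 * Dc.at(yy, xx);
            double dss = Dp.at(yy, xx) + Dm.at(yy, xx) - 2 * Dc.at(yy, xx);
            double dxy = 0.25 * (Dc.at(yy + 1, xx + 1) - Dc.at(yy + 1, xx - 1) -
                                 Dc.at(yy - 1, xx + 1) + Dc.at(yy - 1, xx - 1));
            double dxs = 0.25 * (Dp.at(yy, xx + 1) - Dp.at(yy, xx - 1) -
                                 Dm.at(yy, xx + 1) + Dm.at(yy, xx - 1));
            double dys = 0.25 * (Dp.at(yy + 1, xx) - Dp.at(yy - 1, xx) -
                                 Dm.at(yy + 1, xx) + Dm.at(yy - 1, xx));
            // solve H * off = -g  (3x3 symmetric, Cramer)
            double det = dxx * (dyy * dss - dys * dys) -
                         dxy * (dxy * dss - dys * dxs) +
                         dxs * (dxy * dys - dyy * dxs);
            if (std::fabs(det) < 1e-30) break;
            double b1 = -gx, b2 = -gy, b3 = -gs;
            ox = (b1 * (dyy * dss - dys * dys) -
                  dxy * (b2 * dss - dys * b3) +
                  dxs * (b2 * dys - dyy * b3)) / det;
            oy = (dxx * (b2 * dss - b3 * dys) -
                  b1 * (dxy * dss - dys * dxs) +
                  dxs * (dxy * b3 - b2 * dxs)) / det;
            os = (dxx * (dyy * b3 - b2 * dys) -
                  dxy * (dxy * b3 - b2 * dxs) +
                  b1 * (dxy * dys - dyy * dxs)) / det;
            if (std::fabs(ox) < 0.5 && std::fabs(oy) < 0.5 && std::fabs(os) < 0.5) {
              contr = Dc.at(yy, xx) + 0.5 * (gx * ox + gy * oy + gs * os);
              ok = true;
              break;
            }
            if (std::fabs(ox) > 1e5 || std::fabs(oy) > 1e5 || std::fabs(os) > 1e5) break;
            xx += (int)std::lround(ox);
            yy += (int)std::lround(oy);
            ll += (int)std::lround(os);
            if (ll < 1 || ll > n_scales || xx < border || xx >= w - border ||
                yy < border || yy >= h - border)
              break;
          }
          if (!ok) continue;
          if (std::fabs(contr) * n_scales < contrast_thresh) continue;
          // edge rejection on 2x2 spatial Hessian
          {
            const Img& Dc = dog[o][ll];
            double dxx = Dc.at(yy, xx + 1) + Dc.at(yy, xx - 1) - 2 * Dc.at(yy, xx);
            double dyy = Dc.at(yy + 1, xx) + Dc.at(yy - 1, xx) - 2 * Dc.at(yy, xx);
            double dxy = 0.25 * (Dc.at(yy + 1, xx + 1) - Dc.at(yy + 1, xx - 1) -
                                 Dc.at(yy - 1, xx + 1) + Dc.at(yy - 1, xx - 1));
            double tr = dxx + dyy, det2 = dxx * dyy - dxy * dxy;
            double e = edge_thresh;
            if (det2 <= 0 || tr * tr * e >= (e + 1) * (e + 1) * det2) continue;
          }
          Keypoint kp;
          kp.octave = o;
          kp.layer = ll;
          kp.xo = xx + ox;
          kp.yo = yy + oy;
          kp.sigma_rel = sigma0 * std::pow(2.0, (ll + os) / n_scales);
          double scl = std::pow(2.0, o);
          kp.x = kp.xo * scl;
          kp.y = kp.yo * scl;
          kp.sigma = kp.sigma_rel * scl;
          kp.response = std::fabs(contr);
          kps.push_back(kp);
        }
      }
    }
  }

  // orientation assignment (possibly several per keypoint) + descriptors
  std::vector<Keypoint> out;
  std::vector<std::vector<double> > descs;
  for (size_t i = 0; i < kps.size(); ++i) {
    const Keypoint& kp = kps[i];
    const Img& g = gauss[kp.octave][kp.layer];
    std::vector<double> angles;
    orientation_peaks(g, kp.xo, kp.yo, kp.sigma_rel, angles);
    for (size_t a = 0; a < angles.size(); ++a) {
      Keypoint k2 = kp;
      k2.angle = angles[a];
      std::vector<double> dsc(128, 0.0);
      compute_descriptor(g, kp.xo, kp.yo, kp.sigma_rel, k2.angle, dsc.data());
      out.push_back(k2);
      descs.push_back(dsc);
    }
  }

  int n = (int)out.size();
  NumericMatrix km(n, 5), dm(n, 128);
  for (int i = 0; i < n; ++i) {
    km(i, 0) = out[i].x;
    km(i, 1) = out[i].y;
    km(i, 2) = out[i].sigma;
    km(i, 3) = out[i].angle;
    km(i, 4) = out[i].response;
    for (int j = 0; j < 128; ++j) dm(i, j) = descs[i][j];
  }
  colnames(km) = CharacterVector::create("x", "y", "sigma", "angle", "response");
  return List::create(_["keypoints"] = km, _["descriptors"] = dm);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix image, double sigma) {
  Img src = from_matrix(image), dst;
  gauss_blur_inplace(src, dst, sigma);
  NumericMatrix out(src.h, src.w);
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x)
      out(y, x) = dst.at(y, x);
  return out;
}
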
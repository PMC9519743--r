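// Image-processing kernels: separable filtering with symmetric padding and
// its exact adjoint (used by the SSIM loss gradient), bilinear sampling of
// the phantom reference grid, Gaussian vessel splatting, Keys bicubic
// resampling, and a windowed bilateral filter.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// symmetric padding (edge pixel repeated once at the fold)
static inline int symref(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// filter columns (along H) with kernel centred at radius r
static arma::mat filt_cols(const arma::mat& x, const arma::vec& k) {
  int H = x.n_rows, W = x.n_cols, r = (k.n_elem - 1) / 2;
  arma::mat y(H, W, arma::fill::zeros);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double s = 0;
      for (int j = 0; j < (int)k.n_elem; ++j) s += k[j] * x(symref(h + j - r, H), w);
      y(h, w) = s;
    }
  return y;
}

static arma::mat filt_cols_adjoint(const arma::mat& g, const arma::vec& k) {
  int H = g.n_rows, W = g.n_cols, r = (k.n_elem - 1) / 2;
  arma::mat y(H, W, arma::fill::zeros);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double gv = g(h, w);
      for (int j = 0; j < (int)k.n_elem; ++j) y(symref(h + j - r, H), w) += k[j] * gv;
    }
  return y;
}

// separable correlation with symmetric padding: rows then columns
// [[Rcpp::export]]
arma::mat cpp_sep_filter(const arma::mat& x, const arma::vec& kern) {
  return filt_cols(filt_cols(x.t(), kern).t(), kern);
}

// exact adjoint of cpp_sep_filter (transposes the two stages in reverse)
// [[Rcpp::export]]
arma::mat cpp_sep_filter_adjoint(const arma::mat& g, const arma::vec& kern) {
  return filt_cols_adjoint(filt_cols_adjoint(g, kern).t(), kern).t();
}

// bilinear interpolation at pixel coordinates (0-based), clamped to edge
// [[Rcpp::export]]
arma::mat cpp_bilinear_sample(const arma::mat& img, const arma::mat& xs,
                              const arma::mat& ys) {
  int H = img.n_rows, W = img.n_cols;
  arma::mat out(xs.n_rows, xs.n_cols);
  for (size_t i = 0; i < xs.n_elem; ++i) {
    double x = clampd(xs[i], 0.0, W - 1.0);
    double y = clampd(ys[i], 0.0, H - 1.0);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
    double fx = x - x0, fy = y - y0;
    out[i] = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
             fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
  }
  return out;
}

// Rasterize vessel centreline samples as Gaussian cross-sections, taking
// the per-pixel maximum over samples. pts columns: x_px, y_px, sigma_px,
// amplitude, depth_mm. Returns amplitude (floored at `background`) and the
// depth of the strongest vessel contribution (NaN where none exceeds
// background).
// [[Rcpp::export]]
List cpp_splat_render(const arma::mat& pts, int H, int W, double background) {
  arma::mat amp(H, W); amp.fill(background);
  arma::mat best(H, W, arma::fill::zeros);
  arma::mat depth(H, W); depth.fill(NA_REAL);
  for (size_t i = 0; i < pts.n_rows; ++i) {
    double cx = pts(i, 0), cy = pts(i, 1), sg = pts(i, 2), a = pts(i, 3), d = pts(i, 4);
    int rad = (int)std::ceil(3.0 * sg);
    int x0 = std::max(0, (int)std::floor(cx) - rad), x1 = std::min(W - 1, (int)std::ceil(cx) + rad);
    int y0 = std::max(0, (int)std::floor(cy) - rad), y1 = std::min(H - 1, (int)std::ceil(cy) + rad);
    double inv2s2 = 1.0 / (2.0 * sg * sg);
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y) {
        double dx = x - cx, dy = y - cy;
        double v = a * std::exp(-(dx * dx + dy * dy) * inv2s2);
        if (v > best(y, x)) {
          best(y, x) = v;
          if (v > background) depth(y, x) = d;
        }
        if (v > amp(y, x)) amp(y, x) = v;
      }
  }
  return List::create(_["amplitude"] = amp, _["depth"] = depth);
}

// Keys cubic convolution kernel, a = -0.5
static inline double keys(double t) {
  t = std::fabs(t);
  if (t <= 1) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

static arma::mat bicubic_cols(const arma::mat& x, int Ho) {
  int H = x.n_rows, W = x.n_cols;
  arma::mat y(Ho, W);
  double sc = (double)H / Ho;
  for (int oh = 0; oh < Ho; ++oh) {
    double src = (oh + 0.5) * sc - 0.5;
    int i0 = (int)std::floor(src) - 1;
    double wgt[4], tot = 0;
    for (int j = 0; j < 4; ++j) { wgt[j] = keys(src - (i0 + j)); tot += wgt[j]; }
    for (int w = 0; w < W; ++w) {
      double s = 0;
      for (int j = 0; j < 4; ++j) {
        int ih = std::min(std::max(i0 + j, 0), H - 1);
        s += wgt[j] * x(ih, w);
      }
      y(oh, w) = s / tot;
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_bicubic_resize(const arma::mat& img, int Ho, int Wo) {
  return bicubic_cols(bicubic_cols(img, Ho).t(), Wo).t();
}

// [[Rcpp::export]]
arma::mat cpp_bilateral(const arma::mat& img, int radius,
                        double sigma_color, double sigma_space) {
  int H = img.n_rows, W = img.n_cols;
  arma::mat out(H, W);
  double ic = 1.0 / (2.0 * sigma_color * sigma_color);
  double is = 1.0 / (2.0 * sigma_space * sigma_space);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double c = img(y, x), num = 0, den = 0;
      for (int dx = -radius; dx <= radius; ++dx)
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = symref(y + dy, H), xx = symref(x + dx, W);
          double v = img(yy, xx);
          double w = std::exp(-(dx * dx + dy * dy) * is - (v - c) * (v - c) * ic);
          num += w * v; den += w;
        }
      out(y, x) = num / den;
    }
  return out;
}
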
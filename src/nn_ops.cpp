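// Low-level array kernels: 2-D convolution (im2col + GEMM) with reflective
// 'same' padding and its exact backward pass, pixel shuffle/unshuffle, and
// median pooling. Feature maps are stored as R arrays dim = (H, W, C, N),
// column-major, so element (h,w,c,n) sits at h + H*(w + W*(c + C*n)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// reflect-101 (mirror about edge pixel, edge not repeated)
static inline int refl101(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill im2col matrix M (HoWo x k*k*C) for sample n.
// Column order: c*k*k + kx*k + ky; row order: oy + Ho*ox.
static void im2col(const double* x, int H, int W, int C, int n,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& M) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)H * W * c;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        int col = c * k * k + kx * k + ky;
        double* Mcol = M.colptr(col);
        for (int ox = 0; ox < Wo; ++ox) {
          int ix = refl101(ox * stride + kx - pad, W);
          const double* xcol = xc + (size_t)H * ix;
          for (int oy = 0; oy < Ho; ++oy) {
            int iy = refl101(oy * stride + ky - pad, H);
            Mcol[oy + Ho * ox] = xcol[iy];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, const arma::mat& Wm,
                                 const arma::vec& b, int k, int stride) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if ((int)Wm.n_rows != k * k * C) stop("weight rows != k*k*C_in");
  int Cout = Wm.n_cols;
  int pad = (k - 1) / 2;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, k, stride, pad, Ho, Wo, M);
    arma::mat Y = M * Wm;           // (HoWo x Cout)
    Y.each_row() += b.t();
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, const arma::mat& Wm,
                         NumericVector dy, int k, int stride) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho, Wo, Cout, N2; dims4(dy, Ho, Wo, Cout, N2);
  if (N2 != N) stop("batch mismatch");
  int pad = (k - 1) / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M(Ho * Wo, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, k, stride, pad, Ho, Wo, M);
    arma::mat G(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                Ho * Wo, Cout, false, true);
    dW += M.t() * G;
    db += arma::sum(G, 0).t();
    arma::mat dM = G * Wm.t();      // (HoWo x k2C)
    // scatter-add back to input (adjoint of im2col incl. reflect padding)
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)H * W * c;
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          int col = c * k * k + kx * k + ky;
          const double* dMcol = dM.colptr(col);
          for (int ox = 0; ox < Wo; ++ox) {
            int ix = refl101(ox * stride + kx - pad, W);
            double* dxcol = dxc + (size_t)H * ix;
            for (int oy = 0; oy < Ho; ++oy) {
              int iy = refl101(oy * stride + ky - pad, H);
              dxcol[iy] += dMcol[oy + Ho * ox];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// sub-pixel rearrangement: input channel c*r^2 + dy*r + dx -> output
// channel c at spatial (h*r + dy, w*r + dx); matches the usual
// depth-to-space convention (row-major within each r x r block).
// [[Rcpp::export]]
NumericVector cpp_pixel_shuffle(NumericVector x, int r) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (C % (r * r) != 0) stop("channel count not divisible by r^2");
  int Co = C / (r * r), Ho = H * r, Wo = W * r;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c)
      for (int dy = 0; dy < r; ++dy)
        for (int dx = 0; dx < r; ++dx) {
          int cin = c * r * r + dy * r + dx;
          const double* xs = x.begin() + (size_t)H * W * (cin + (size_t)C * n);
          double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)Co * n);
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              ys[(h * r + dy) + (size_t)Ho * (w * r + dx)] = xs[h + (size_t)H * w];
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_pixel_unshuffle(NumericVector y, int r) {
  int Ho, Wo, Co, N; dims4(y, Ho, Wo, Co, N);
  if (Ho % r != 0 || Wo % r != 0) stop("spatial dims not divisible by r");
  int H = Ho / r, W = Wo / r, C = Co * r * r;
  NumericVector x((size_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c)
      for (int dy = 0; dy < r; ++dy)
        for (int dx = 0; dx < r; ++dx) {
          int cin = c * r * r + dy * r + dx;
          double* xs = x.begin() + (size_t)H * W * (cin + (size_t)C * n);
          const double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)Co * n);
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              xs[h + (size_t)H * w] = ys[(h * r + dy) + (size_t)Ho * (w * r + dx)];
        }
  return x;
}

// blockwise median downsampling; even block sizes use the mean of the two
// central order statistics
// [[Rcpp::export]]
NumericVector cpp_median_pool(NumericVector x, int f) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (H % f != 0 || W % f != 0) stop("image dimensions not divisible by pooling factor");
  int Ho = H / f, Wo = W / f;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<double> buf(f * f);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          int m = 0;
          for (int dw = 0; dw < f; ++dw)
            for (int dh = 0; dh < f; ++dh)
              buf[m++] = xs[(oh * f + dh) + (size_t)H * (ow * f + dw)];
          std::sort(buf.begin(), buf.end());
          double med = (m % 2 == 1) ? buf[m / 2]
                                    : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
          ys[oh + (size_t)Ho * ow] = med;
        }
    }
  return y;
}
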
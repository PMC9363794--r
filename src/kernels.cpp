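#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tensor layout throughout: column-major R arrays with dims (H, W, C, N).
// Weight layout for dense conv: (kh, kw, Cin, Cout); depthwise: (kh, kw, C).

static inline int out_extent(int H, int pad, int k, int dil, int stride) {
  if (stride < 1 || dil < 1) stop("stride and dilation must be >= 1");
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector x, IntegerVector xdim,
                        int kh, int kw, int stride, int dil, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_extent(H, ph, kh, dil, stride);
  const int Wo = out_extent(W, pw, kw, dil, stride);
  const int K = kh * kw * C;
  NumericMatrix out(K, (R_xlen_t)Ho * Wo * N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (R_xlen_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double* oc = op + col * K;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (R_xlen_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj * dil;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki * dil;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = xc[(R_xlen_t)wi * H + hi];
              oc[(R_xlen_t)c * kh * kw + kj * kh + ki] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, IntegerVector xdim,
                        int kh, int kw, int stride, int dil, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_extent(H, ph, kh, dil, stride);
  const int Wo = out_extent(W, pw, kw, dil, stride);
  const int K = kh * kw * C;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* cp = REAL(cols);
  double* dp = REAL(dx);
  for (int n = 0; n < N; ++n) {
    double* dn = dp + (R_xlen_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double* cc = cp + col * K;
        for (int c = 0; c < C; ++c) {
          double* dc = dn + (R_xlen_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj * dil;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki * dil;
              if (hi < 0 || hi >= H) continue;
              dc[(R_xlen_t)wi * H + hi] += cc[(R_xlen_t)c * kh * kw + kj * kh + ki];
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_dwconv_fwd(NumericVector x, IntegerVector xdim, NumericVector w,
                            int kh, int kw, int stride, int dil, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_extent(H, ph, kh, dil, stride);
  const int Wo = out_extent(W, pw, kw, dil, stride);
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * kh * kw;
      double* yc = yp + ((R_xlen_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj * dil;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki * dil;
              if (hi < 0 || hi >= H) continue;
              acc += xc[(R_xlen_t)wi * H + hi] * wc[kj * kh + ki];
            }
          }
          yc[(R_xlen_t)wo * Ho + ho] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List nn_dwconv_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                   NumericVector dy,
                   int kh, int kw, int stride, int dil, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_extent(H, ph, kh, dil, stride);
  const int Wo = out_extent(W, pw, kw, dil, stride);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  NumericVector dw((R_xlen_t)kh * kw * C);
  dw.attr("dim") = IntegerVector::create(kh, kw, C);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(dy);
  double* dxp = REAL(dx);
  double* dwp = REAL(dw);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * kh * kw;
      const double* gc = gp + ((R_xlen_t)n * C + c) * Ho * Wo;
      double* dxc = dxp + ((R_xlen_t)n * C + c) * H * W;
      double* dwc = dwp + (R_xlen_t)c * kh * kw;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[(R_xlen_t)wo * Ho + ho];
          if (g == 0.0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride - pw + kj * dil;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride - ph + ki * dil;
              if (hi < 0 || hi >= H) continue;
              dxc[(R_xlen_t)wi * H + hi] += g * wc[kj * kh + ki];
              dwc[kj * kh + ki] += g * xc[(R_xlen_t)wi * H + hi];
            }
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Bilinear resize, half-pixel (align_corners = FALSE) convention.
// [[Rcpp::export]]
NumericVector nn_resize_bilinear(NumericVector x, IntegerVector xdim, int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* xp = REAL(x);
  double* yp = REAL(y);
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> ah(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    ah[i] = s - h0[i];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> aw(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    aw[j] = s - w0[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
      double* yc = yp + ((R_xlen_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double v00 = xc[(R_xlen_t)w0[j] * H + h0[i]];
          const double v10 = xc[(R_xlen_t)w0[j] * H + h1[i]];
          const double v01 = xc[(R_xlen_t)w1[j] * H + h0[i]];
          const double v11 = xc[(R_xlen_t)w1[j] * H + h1[i]];
          const double top = v00 * (1 - aw[j]) + v01 * aw[j];
          const double bot = v10 * (1 - aw[j]) + v11 * aw[j];
          yc[(R_xlen_t)j * Ho + i] = top * (1 - ah[i]) + bot * ah[i];
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_resize_bilinear_bwd(NumericVector dy, IntegerVector ydim, int H, int W) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* gp = REAL(dy);
  double* dp = REAL(dx);
  std::vector<int> h0(Ho), h1(Ho);
  std::vector<double> ah(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = std::min(h0[i] + 1, H - 1);
    ah[i] = s - h0[i];
  }
  std::vector<int> w0(Wo), w1(Wo);
  std::vector<double> aw(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = std::min(w0[j] + 1, W - 1);
    aw[j] = s - w0[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + ((R_xlen_t)n * C + c) * Ho * Wo;
      double* dc = dp + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = gc[(R_xlen_t)j * Ho + i];
          if (g == 0.0) continue;
          dc[(R_xlen_t)w0[j] * H + h0[i]] += g * (1 - aw[j]) * (1 - ah[i]);
          dc[(R_xlen_t)w1[j] * H + h0[i]] += g * aw[j] * (1 - ah[i]);
          dc[(R_xlen_t)w0[j] * H + h1[i]] += g * (1 - aw[j]) * ah[i];
          dc[(R_xlen_t)w1[j] * H + h1[i]] += g * aw[j] * ah[i];
        }
    }
  return dx;
}

// 8-connected component labeling of a binary mask (matrix of 0/1).
// Labels are assigned in raster scan order (column-major, as stored),
// so ties between equal-sized components resolve deterministically.
// [[Rcpp::export]]
IntegerMatrix cc_label8(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dh[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dw[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back((R_xlen_t)j * H + i);
      while (!stack.empty()) {
        R_xlen_t p = stack.back();
        stack.pop_back();
        const int pi = (int)(p % H), pj = (int)(p / H);
        for (int d = 0; d < 8; ++d) {
          const int qi = pi + dh[d], qj = pj + dw[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (m(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back((R_xlen_t)qj * H + qi);
          }
        }
      }
    }
  return lab;
}

// ---- Minimum enclosing circle: Welzl-style randomized incremental ----

struct Circ { double x, y, r; };

static inline bool in_circ(const Circ& c, double px, double py, double eps) {
  const double dx = px - c.x, dy = py - c.y;
  return std::sqrt(dx * dx + dy * dy) <= c.r + eps;
}

static Circ circ2(double ax, double ay, double bx, double by) {
  Circ c;
  c.x = 0.5 * (ax + bx);
  c.y = 0.5 * (ay + by);
  c.r = 0.5 * std::hypot(ax - bx, ay - by);
  return c;
}

static Circ circ3(double ax, double ay, double bx, double by, double cx, double cy) {
  const double bxa = bx - ax, bya = by - ay, cxa = cx - ax, cya = cy - ay;
  const double d = 2.0 * (bxa * cya - bya * cxa);
  if (std::fabs(d) < 1e-14) {
    // collinear: fall back to the widest pair
    Circ c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy), c3 = circ2(bx, by, cx, cy);
    Circ best = c1;
    if (c2.r > best.r) best = c2;
    if (c3.r > best.r) best = c3;
    return best;
  }
  const double b2 = bxa * bxa + bya * bya, c2_ = cxa * cxa + cya * cya;
  Circ c;
  c.x = ax + (cya * b2 - bya * c2_) / d;
  c.y = ay + (bxa * c2_ - cxa * b2) / d;
  c.r = std::hypot(c.x - ax, c.y - ay);
  return c;
}

// [[Rcpp::export]]
NumericVector mec_welzl(NumericVector px, NumericVector py) {
  const int n = px.size();
  if (n < 1) stop("empty point set");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::mt19937 rng(88172645u);  // fixed: result independent of R's RNG
  std::shuffle(idx.begin(), idx.end(), rng);
  const double eps = 1e-10;
  Circ c = {px[idx[0]], py[idx[0]], 0.0};
  for (int i = 1; i < n; ++i) {
    const double xi = px[idx[i]], yi = py[idx[i]];
    if (in_circ(c, xi, yi, eps * (1 + c.r))) continue;
    c = {xi, yi, 0.0};
    for (int j = 0; j < i; ++j) {
      const double xj = px[idx[j]], yj = py[idx[j]];
      if (in_circ(c, xj, yj, eps * (1 + c.r))) continue;
      c = circ2(xi, yi, xj, yj);
      for (int k = 0; k < j; ++k) {
        const double xk = px[idx[k]], yk = py[idx[k]];
        if (in_circ(c, xk, yk, eps * (1 + c.r))) continue;
        c = circ3(xi, yi, xj, yj, xk, yk);
      }
    }
  }
  return NumericVector::create(c.x, c.y, c.r);
}
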
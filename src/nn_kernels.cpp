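#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim c(H, W, C, N); H varies fastest.
// im2col row order: (kh, kw, c), column order: (ho, wo, n).

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw,
                         int edge) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  const int rows = kh * kw * C;
  NumericMatrix cols(rows, Ho * Wo * (size_t)N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        double* cp = &cols(0, col);
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + ((size_t)n * C + c) * H * W;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pw + j;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - ph + i;
              const size_t r = (size_t)c * kh * kw + (size_t)j * kh + i;
              if (edge) {
                const int hc = hi < 0 ? 0 : (hi >= H ? H - 1 : hi);
                const int wc = wi < 0 ? 0 : (wi >= W ? W - 1 : wi);
                cp[r] = xc[(size_t)wc * H + hc];
              } else {
                cp[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                          ? xc[(size_t)wi * H + hi] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw,
                         int edge) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        const double* cp = &cols(0, col);
        for (int c = 0; c < C; ++c) {
          double* xc = xp + ((size_t)n * C + c) * H * W;
          for (int j = 0; j < kw; ++j) {
            int wi = wo * sw - pw + j;
            if (edge) wi = wi < 0 ? 0 : (wi >= W ? W - 1 : wi);
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * sh - ph + i;
              if (edge) hi = hi < 0 ? 0 : (hi >= H ? H - 1 : hi);
              if (hi < 0 || hi >= H) continue;
              xc[(size_t)wi * H + hi] += cp[(size_t)c * kh * kw + (size_t)j * kh + i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Depthwise convolution, weight dim c(kh, kw, C).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                             NumericVector w, int kh, int kw,
                             int sh, int sw, int ph, int pw,
                             NumericVector bias, int edge) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector y((size_t)Ho * Wo * C * N);
  const double* xp = x.begin(); const double* wp = w.begin();
  double* yp = y.begin();
  const bool has_b = bias.size() == C;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      const double* wc = wp + (size_t)c * kh * kw;
      double* yc = yp + ((size_t)n * C + c) * Ho * Wo;
      const double b = has_b ? bias[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b;
          for (int j = 0; j < kw; ++j) {
            int wi = wo * sw - pw + j;
            if (edge) wi = wi < 0 ? 0 : (wi >= W ? W - 1 : wi);
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * sh - ph + i;
              if (edge) hi = hi < 0 ? 0 : (hi >= H ? H - 1 : hi);
              if (hi < 0 || hi >= H) continue;
              acc += xc[(size_t)wi * H + hi] * wc[(size_t)j * kh + i];
            }
          }
          yc[(size_t)wo * Ho + ho] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, int H, int W, int C, int N,
                    NumericVector w, int kh, int kw,
                    int sh, int sw, int ph, int pw,
                    NumericVector dy, bool has_bias, int edge) {
  const int Ho = out_size(H, kh, sh, ph), Wo = out_size(W, kw, sw, pw);
  NumericVector dx((size_t)H * W * C * N), dw((size_t)kh * kw * C), db(C);
  const double* xp = x.begin(); const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin(); double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * H * W;
      const double* wc = wp + (size_t)c * kh * kw;
      const double* gyc = dyp + ((size_t)n * C + c) * Ho * Wo;
      double* gxc = dxp + ((size_t)n * C + c) * H * W;
      double* gwc = dwp + (size_t)c * kh * kw;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gyc[(size_t)wo * Ho + ho];
          if (g == 0.0) continue;
          db[c] += g;
          for (int j = 0; j < kw; ++j) {
            int wi = wo * sw - pw + j;
            if (edge) wi = wi < 0 ? 0 : (wi >= W ? W - 1 : wi);
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int hi = ho * sh - ph + i;
              if (edge) hi = hi < 0 ? 0 : (hi >= H ? H - 1 : hi);
              if (hi < 0 || hi >= H) continue;
              gxc[(size_t)wi * H + hi] += g * wc[(size_t)j * kh + i];
              gwc[(size_t)j * kh + i] += g * xc[(size_t)wi * H + hi];
            }
          }
        }
      }
    }
  }
  // db accumulated above regardless; caller drops it when has_bias is FALSE
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(kh, kw, C);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = has_bias ? db : NumericVector(0));
}

// Bilinear resize, half-pixel centers (align_corners = FALSE).
static inline void bil_coef(int out, int in, int o, double scale,
                            int& i0, int& i1, double& w0, double& w1) {
  double src = (o + 0.5) * scale - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)src; i1 = i0 + 1 < in ? i0 + 1 : i0;
  w1 = src - i0; w0 = 1.0 - w1;
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                               int Ho, int Wo) {
  NumericVector y((size_t)Ho * Wo * C * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* xp = x.begin(); double* yp = y.begin();
  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int o = 0; o < Ho; ++o) bil_coef(Ho, H, o, sh, h0[o], h1[o], ha[o], hb[o]);
  for (int o = 0; o < Wo; ++o) bil_coef(Wo, W, o, sw, w0i[o], w1i[o], wa[o], wb[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        yc[(size_t)wo * Ho + ho] =
          ha[ho] * (wa[wo] * xc[(size_t)w0i[wo] * H + h0[ho]] +
                    wb[wo] * xc[(size_t)w1i[wo] * H + h0[ho]]) +
          hb[ho] * (wa[wo] * xc[(size_t)w0i[wo] * H + h1[ho]] +
                    wb[wo] * xc[(size_t)w1i[wo] * H + h1[ho]]);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int Ho, int Wo, int C, int N,
                               int H, int W) {
  NumericVector dx((size_t)H * W * C * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double* gp = dy.begin(); double* dp = dx.begin();
  std::vector<int> h0(Ho), h1(Ho), w0i(Wo), w1i(Wo);
  std::vector<double> ha(Ho), hb(Ho), wa(Wo), wb(Wo);
  for (int o = 0; o < Ho; ++o) bil_coef(Ho, H, o, sh, h0[o], h1[o], ha[o], hb[o]);
  for (int o = 0; o < Wo; ++o) bil_coef(Wo, W, o, sw, w0i[o], w1i[o], wa[o], wb[o]);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gc = gp + cn * Ho * Wo;
    double* dc = dp + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = gc[(size_t)wo * Ho + ho];
        dc[(size_t)w0i[wo] * H + h0[ho]] += g * ha[ho] * wa[wo];
        dc[(size_t)w1i[wo] * H + h0[ho]] += g * ha[ho] * wb[wo];
        dc[(size_t)w0i[wo] * H + h1[ho]] += g * hb[ho] * wa[wo];
        dc[(size_t)w1i[wo] * H + h1[ho]] += g * hb[ho] * wb[wo];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Spatial max pooling (forward only; used by the reference residual net).
// [[Rcpp::export]]
NumericVector maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                              int k, int s, int p) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector y((size_t)Ho * Wo * C * N);
  const double* xp = x.begin(); double* yp = y.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double m = R_NegInf;
        for (int j = 0; j < k; ++j) {
          const int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int hi = ho * s - p + i;
            if (hi < 0 || hi >= H) continue;
            const double v = xc[(size_t)wi * H + hi];
            if (v > m) m = v;
          }
        }
        yc[(size_t)wo * Ho + ho] = m;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}
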
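#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays with dim (H, W, C): element (h, w, c) sits at
// h + H*(w + W*c), 0-based.  Convolution weights have dim (K, K, Cin, Cout).
// All kernels are plain loops; desk-scale maps are small enough that cache
// tricks would not pay for their complexity.

static inline int idx3(int h, int w, int c, int H, int W) {
  return h + H * (w + W * c);
}

// For each (kh, kw) tap the valid output range is computed once, so the
// innermost loops over output rows are branch-free and run over contiguous
// memory (column-major, H fastest).

static inline void tap_range(int pad, int k, int stride, int n_in, int n_out,
                             int *lo, int *hi) {
  // valid out: 0 <= out*stride - pad + k < n_in
  int l = 0;
  int off = pad - k;
  if (off > 0) l = (off + stride - 1) / stride;
  int h = n_out - 1;
  int top = n_in - 1 + off;  // out*stride <= top
  if (top < 0) { *lo = 0; *hi = -1; return; }
  if (top / stride < h) h = top / stride;
  *lo = l; *hi = h;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector wgt,
                            NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wgt.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int K = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector out(Ho * Wo * Cout);
  out.attr("dim") = Dimension(Ho, Wo, Cout);
  const double *px = x.begin();
  const double *pw = wgt.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    double *oc = po + (R_xlen_t)co * Ho * Wo;
    const double b = bias[co];
    for (int i = 0; i < Ho * Wo; ++i) oc[i] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (R_xlen_t)ci * H * W;
      for (int kw = 0; kw < K; ++kw) {
        int wlo, whi;
        tap_range(pad, kw, stride, W, Wo, &wlo, &whi);
        for (int kh = 0; kh < K; ++kh) {
          const double wv = pw[kh + K * (kw + K * (ci + Cin * co))];
          if (wv == 0.0) continue;
          int hlo, hhi;
          tap_range(pad, kh, stride, H, Ho, &hlo, &hhi);
          for (int wo = wlo; wo <= whi; ++wo) {
            const int wi = wo * stride - pad + kw;
            double *orow = oc + (R_xlen_t)wo * Ho;
            const double *xrow = xc + (R_xlen_t)wi * H - pad + kh;
            if (stride == 1) {
              for (int ho = hlo; ho <= hhi; ++ho) {
                orow[ho] += wv * xrow[ho];
              }
            } else {
              for (int ho = hlo; ho <= hhi; ++ho) {
                orow[ho] += wv * xrow[ho * stride];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bw_x(NumericVector gout, NumericVector wgt,
                              int H, int W, int stride, int pad) {
  IntegerVector gd = gout.attr("dim");
  IntegerVector wd = wgt.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int K = wd[0], Cin = wd[2];
  NumericVector gx(H * W * Cin);
  gx.attr("dim") = Dimension(H, W, Cin);
  const double *pg = gout.begin();
  const double *pw = wgt.begin();
  double *pgx = gx.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gc = pg + (R_xlen_t)co * Ho * Wo;
    for (int ci = 0; ci < Cin; ++ci) {
      double *xc = pgx + (R_xlen_t)ci * H * W;
      for (int kw = 0; kw < K; ++kw) {
        int wlo, whi;
        tap_range(pad, kw, stride, W, Wo, &wlo, &whi);
        for (int kh = 0; kh < K; ++kh) {
          const double wv = pw[kh + K * (kw + K * (ci + Cin * co))];
          if (wv == 0.0) continue;
          int hlo, hhi;
          tap_range(pad, kh, stride, H, Ho, &hlo, &hhi);
          for (int wo = wlo; wo <= whi; ++wo) {
            const int wi = wo * stride - pad + kw;
            const double *grow = gc + (R_xlen_t)wo * Ho;
            double *xrow = xc + (R_xlen_t)wi * H - pad + kh;
            if (stride == 1) {
              for (int ho = hlo; ho <= hhi; ++ho) {
                xrow[ho] += wv * grow[ho];
              }
            } else {
              for (int ho = hlo; ho <= hhi; ++ho) {
                xrow[ho * stride] += wv * grow[ho];
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bw_w(NumericVector gout, NumericVector x,
                              int K, int stride, int pad) {
  IntegerVector gd = gout.attr("dim");
  IntegerVector xd = x.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  const int H = xd[0], W = xd[1], Cin = xd[2];
  NumericVector gw(K * K * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(K, K, Cin, Cout);
  const double *pg = gout.begin();
  const double *px = x.begin();
  double *pgw = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gc = pg + (R_xlen_t)co * Ho * Wo;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + (R_xlen_t)ci * H * W;
      for (int kw = 0; kw < K; ++kw) {
        int wlo, whi;
        tap_range(pad, kw, stride, W, Wo, &wlo, &whi);
        for (int kh = 0; kh < K; ++kh) {
          int hlo, hhi;
          tap_range(pad, kh, stride, H, Ho, &hlo, &hhi);
          double acc = 0.0;
          for (int wo = wlo; wo <= whi; ++wo) {
            const int wi = wo * stride - pad + kw;
            const double *grow = gc + (R_xlen_t)wo * Ho;
            const double *xrow = xc + (R_xlen_t)wi * H - pad + kh;
            if (stride == 1) {
              for (int ho = hlo; ho <= hhi; ++ho) {
                acc += grow[ho] * xrow[ho];
              }
            } else {
              for (int ho = hlo; ho <= hhi; ++ho) {
                acc += grow[ho] * xrow[ho * stride];
              }
            }
          }
          pgw[kh + K * (kw + K * (ci + Cin * co))] = acc;
        }
      }
    }
  }
  return gw;
}

// Involution: a per-position kernel shared across the channels of a group.
// ker has dim (Ho, Wo, G*K*K); the tap (g, kh, kw) lives in kernel channel
// g*K*K + kw*K + kh (column-major within the K x K window, matching how the
// kernel-generating convolution's output channels are reshaped in R).
// [[Rcpp::export]]
NumericVector cpp_involution_fw(NumericVector x, NumericVector ker,
                                int K, int G, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = ker.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = kd[0], Wo = kd[1];
  const int cpg = C / G;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = Dimension(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int kw = 0; kw < K; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            acc += ker[idx3(ho, wo, g * K * K + kw * K + kh, Ho, Wo)] *
                   x[idx3(hi, wi, c, H, W)];
          }
        }
        out[idx3(ho, wo, c, Ho, Wo)] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_involution_bw(NumericVector gout, NumericVector x, NumericVector ker,
                       int K, int G, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = ker.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = kd[0], Wo = kd[1];
  const int cpg = C / G;
  NumericVector gx(H * W * C), gk(Ho * Wo * G * K * K);
  gx.attr("dim") = Dimension(H, W, C);
  gk.attr("dim") = Dimension(Ho, Wo, G * K * K);
  for (int c = 0; c < C; ++c) {
    const int g = c / cpg;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double go = gout[idx3(ho, wo, c, Ho, Wo)];
        if (go == 0.0) continue;
        for (int kw = 0; kw < K; ++kw) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            const int kc = g * K * K + kw * K + kh;
            gx[idx3(hi, wi, c, H, W)] += go * ker[idx3(ho, wo, kc, Ho, Wo)];
            gk[idx3(ho, wo, kc, Ho, Wo)] += go * x[idx3(hi, wi, c, H, W)];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gk"] = gk);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  NumericVector out(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  out.attr("dim") = Dimension(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride + kh;
            const int ii = idx3(hi, wi, c, H, W);
            if (x[ii] > best) { best = x[ii]; besti = ii; }
          }
        }
        out[idx3(ho, wo, c, Ho, Wo)] = best;
        arg[idx3(ho, wo, c, Ho, Wo)] = besti;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector arg,
                             int H, int W, int C) {
  NumericVector gx(H * W * C);
  gx.attr("dim") = Dimension(H, W, C);
  const int n = gout.size();
  for (int i = 0; i < n; ++i) gx[arg[i]] += gout[i];
  return gx;
}

// Breadth-first region growing on an RGB image (H, W, 3), criterion:
// Euclidean RGB distance to the *seed pixel's* colour <= threshold.
// Fixed criterion keeps the result independent of visiting order.
// conn is 4 or 8; returns a logical mask (H, W).  maxpix < 0 disables the
// size bound; when exceeded the function returns a mask with attribute
// handled on the R side (we just signal via size).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector img, int seed_h, int seed_w,
                              double threshold, int conn, int maxpix) {
  IntegerVector xd = img.attr("dim");
  const int H = xd[0], W = xd[1];
  LogicalVector mask(H * W);
  mask.attr("dim") = Dimension(H, W);
  std::vector<int> queue;
  queue.reserve(256);
  const double sr = img[idx3(seed_h, seed_w, 0, H, W)];
  const double sg = img[idx3(seed_h, seed_w, 1, H, W)];
  const double sb = img[idx3(seed_h, seed_w, 2, H, W)];
  const double t2 = threshold * threshold;
  mask[seed_h + H * seed_w] = true;
  queue.push_back(seed_h + H * seed_w);
  size_t head = 0;
  int npix = 1;
  const int dh4[4] = { -1, 1, 0, 0 }, dw4[4] = { 0, 0, -1, 1 };
  const int dh8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dw8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const int nn = (conn == 8) ? 8 : 4;
  const int *dh = (conn == 8) ? dh8 : dh4;
  const int *dw = (conn == 8) ? dw8 : dw4;
  while (head < queue.size()) {
    const int cur = queue[head++];
    const int ch = cur % H, cw = cur / H;
    for (int d = 0; d < nn; ++d) {
      const int nh = ch + dh[d], nw = cw + dw[d];
      if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
      const int ni = nh + H * nw;
      if (mask[ni]) continue;
      const double dr = img[idx3(nh, nw, 0, H, W)] - sr;
      const double dg = img[idx3(nh, nw, 1, H, W)] - sg;
      const double db = img[idx3(nh, nw, 2, H, W)] - sb;
      if (dr * dr + dg * dg + db * db <= t2) {
        mask[ni] = true;
        queue.push_back(ni);
        if (maxpix >= 0 && ++npix > maxpix) {
          mask.attr("overflow") = true;
          return mask;
        }
      }
    }
  }
  return mask;
}
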
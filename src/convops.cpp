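#include <Rcpp.h>
using namespace Rcpp;

// Arrays are column-major (H, W, C): index h + H*w + H*W*c.

static inline int idx3(int h, int w, int c, int H, int W) {
  return h + H * (w + W * c);
}

// Same-padding 2-D convolution. w has dim (kh, kw, Cin, Cout), b length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector y(H * W * Cout);
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    for (int wcol = 0; wcol < W; ++wcol) {
      for (int h = 0; h < H; ++h) {
        double acc = bias;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            const int wj = wcol + kj - pw;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = h + ki - ph;
              if (hi < 0 || hi >= H) continue;
              acc += x[idx3(hi, wj, ci, H, W)] *
                     w[ki + kh * (kj + kw * (ci + Cin * co))];
            }
          }
        }
        y[idx3(h, wcol, co, H, W)] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector dx(H * W * Cin), dw(kh * kw * Cin * Cout), db(Cout);
  for (int co = 0; co < Cout; ++co) {
    double dbacc = 0.0;
    for (int wcol = 0; wcol < W; ++wcol) {
      for (int h = 0; h < H; ++h) {
        const double g = dy[idx3(h, wcol, co, H, W)];
        if (g == 0.0) continue;
        dbacc += g;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            const int wj = wcol + kj - pw;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = h + ki - ph;
              if (hi < 0 || hi >= H) continue;
              const int wi = ki + kh * (kj + kw * (ci + Cin * co));
              dx[idx3(hi, wj, ci, H, W)] += g * w[wi];
              dw[wi] += g * x[idx3(hi, wj, ci, H, W)];
            }
          }
        }
      }
    }
    db[co] = dbacc;
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled values and
// 0-based argmax linear indices into x.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector am(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf; int besti = -1;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int i = idx3(2 * ho + di, 2 * wo + dj, c, H, W);
            if (x[i] > best) { best = x[i]; besti = i; }
          }
        }
        const int o = ho + Ho * (wo + Wo * c);
        y[o] = best; am[o] = besti;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                               IntegerVector xdim) {
  NumericVector dx(xdim[0] * xdim[1] * xdim[2]);
  for (int i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        y[idx3(ho, wo, c, Ho, Wo)] = x[idx3(ho / 2, wo / 2, c, H, W)];
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        dx[idx3(ho / 2, wo / 2, c, H, W)] += dy[idx3(ho, wo, c, Ho, Wo)];
  dx.attr("dim") = xdim;
  return dx;
}

// Center-aligned bilinear resize of an (H, W, C) array: destination pixel
// centers map to source coordinates via s = (d + 0.5) * (S / D) - 0.5, the
// convention that makes down-then-up round trips symmetric.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int newH, int newW) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  const double sy = (double)H / newH, sx = (double)W / newW;
  NumericVector y(newH * newW * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < newW; ++j) {
      double fx = (j + 0.5) * sx - 0.5;
      if (fx < 0) fx = 0;
      if (fx > W - 1) fx = W - 1;
      const int x0 = (int)fx, x1 = x0 + 1 < W ? x0 + 1 : x0;
      const double wx = fx - x0;
      for (int i = 0; i < newH; ++i) {
        double fy = (i + 0.5) * sy - 0.5;
        if (fy < 0) fy = 0;
        if (fy > H - 1) fy = H - 1;
        const int y0 = (int)fy, y1 = y0 + 1 < H ? y0 + 1 : y0;
        const double wy = fy - y0;
        const double v =
            (1 - wy) * ((1 - wx) * x[idx3(y0, x0, c, H, W)] +
                        wx * x[idx3(y0, x1, c, H, W)]) +
            wy * ((1 - wx) * x[idx3(y1, x0, c, H, W)] +
                  wx * x[idx3(y1, x1, c, H, W)]);
        y[i + newH * (j + newW * c)] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(newH, newW, C);
  return y;
}

// 8-connected component labelling of a logical matrix (H x W), BFS-based.
// Returns an integer matrix with 0 = background and components numbered from
// 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> queue;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      queue.clear();
      queue.push_back(h + H * w);
      lab(h, w) = next;
      while (!queue.empty()) {
        const int cur = queue.back();
        queue.pop_back();
        const int ch = cur % H, cw = cur / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int nh = ch + di, nw = cw + dj;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              queue.push_back(nh + H * nw);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Soft normalized-cut building blocks. Affinity between pixels u, v:
//   w(u,v) = exp(-||F(u)-F(v)||^2 / sI^2) * exp(-||X(u)-X(v)||^2 / sX^2)
// for spatial distance ||X(u)-X(v)|| < r, zero otherwise (self-pair included,
// weight 1). feat is (H, W, F), p is (H, W, K). Returns Wp (H, W, K) with
// Wp_k(u) = sum_v w(u,v) p_k(v) and degree d(u) = sum_v w(u,v).
// [[Rcpp::export]]
List cpp_ncut_terms(NumericVector feat, NumericVector p, IntegerVector fdim,
                    IntegerVector pdim, int radius, double sigmaI,
                    double sigmaX) {
  const int H = fdim[0], W = fdim[1], F = fdim[2], K = pdim[2];
  const double sI2 = sigmaI * sigmaI, sX2 = sigmaX * sigmaX;
  NumericVector Wp(H * W * K), d(H * W);
  for (int dj = -radius + 1; dj <= radius - 1; ++dj) {
    for (int di = -radius + 1; di <= radius - 1; ++di) {
      const double sp2 = (double)(di * di + dj * dj);
      if (sp2 >= (double)(radius * radius)) continue;
      const double spatial = std::exp(-sp2 / sX2);
      for (int w = 0; w < W; ++w) {
        const int wv = w + dj;
        if (wv < 0 || wv >= W) continue;
        for (int h = 0; h < H; ++h) {
          const int hv = h + di;
          if (hv < 0 || hv >= H) continue;
          double fd2 = 0.0;
          for (int f = 0; f < F; ++f) {
            const double df =
                feat[idx3(h, w, f, H, W)] - feat[idx3(hv, wv, f, H, W)];
            fd2 += df * df;
          }
          const double wt = std::exp(-fd2 / sI2) * spatial;
          const int u = h + H * w;
          d[u] += wt;
          for (int k = 0; k < K; ++k)
            Wp[idx3(h, w, k, H, W)] += wt * p[idx3(hv, wv, k, H, W)];
        }
      }
    }
  }
  Wp.attr("dim") = IntegerVector::create(H, W, K);
  d.attr("dim") = IntegerVector::create(H, W);
  return List::create(_["Wp"] = Wp, _["d"] = d);
}
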
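#include <Rcpp.h>
using namespace Rcpp;

// Batched image tensors are numeric arrays with dim (H, W, C, N), column-major.
// im2col unrolls k x k patches so a convolution becomes one matrix product:
// rows index (ki, kj, c), columns index (ho, wo, n).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * (wo + Wo * n);
        double* ocol = op + (R_xlen_t)col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xplane = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            const bool wok = (w >= 0 && w < W);
            for (int ki = 0; ki < kh; ++ki) {
              const int h = h0 + ki;
              double v = 0.0;
              if (wok && h >= 0 && h < H) v = xplane[h + (R_xlen_t)H * w];
              ocol[ki + kh * (kj + kw * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add transpose of im2col: accumulates patch gradients back onto the
// (H, W, C, N) input gradient.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C * N);
  double* op = out.begin();
  const double* cp = cols.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = ho + Ho * (wo + Wo * n);
        const double* ccol = cp + (R_xlen_t)col * nrow;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* oplane = op + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = h0 + ki;
              if (h < 0 || h >= H) continue;
              oplane[h + (R_xlen_t)H * w] += ccol[ki + kh * (kj + kw * c)];
            }
          }
        }
      }
    }
  }
  return out;
}

// Bilinear resampling of a stack of frames (H, W, N) through one shared
// coordinate map: output(h, w, n) = frame_n sampled at (map_y(h,w),
// map_x(h,w)), 0-based pixel coordinates. Out-of-bounds samples take the
// fill value (background black for ultrasound-style frames).

// [[Rcpp::export]]
NumericVector warp_bilinear_cpp(NumericVector x, int H, int W, int N,
                                NumericMatrix map_y, NumericMatrix map_x,
                                double fill) {
  NumericVector out((R_xlen_t)H * W * N);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const double sy = map_y(h, w);
      const double sx = map_x(h, w);
      const int y0 = (int)std::floor(sy);
      const int x0 = (int)std::floor(sx);
      const double fy = sy - y0;
      const double fx = sx - x0;
      for (int n = 0; n < N; ++n) {
        const double* plane = xp + (R_xlen_t)H * W * n;
        double acc = 0.0;
        for (int dy = 0; dy <= 1; ++dy) {
          const int yy = y0 + dy;
          const double wy = dy ? fy : 1.0 - fy;
          for (int dx = 0; dx <= 1; ++dx) {
            const int xx = x0 + dx;
            const double wx = dx ? fx : 1.0 - fx;
            double v = fill;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W)
              v = plane[yy + (R_xlen_t)H * xx];
            acc += wy * wx * v;
          }
        }
        op[h + (R_xlen_t)H * (w + (R_xlen_t)W * n)] = acc;
      }
    }
  }
  return out;
}

// Fast layout permutes between (H, W, C, N) and (C, H, W, N), the two
// orders the convolution layer moves between (BLAS output is
// channel-major). Plain aperm() is a measurable bottleneck here.

// [[Rcpp::export]]
NumericVector hwcn_to_chwn_cpp(NumericVector x, int H, int W, int C, int N) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + HW * C * n;
    double* on = op + HW * C * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + HW * c;
      for (R_xlen_t hw = 0; hw < HW; ++hw)
        on[c + (R_xlen_t)C * hw] = xc[hw];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector chwn_to_hwcn_cpp(NumericVector x, int H, int W, int C, int N) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + HW * C * n;
    double* on = op + HW * C * n;
    for (int c = 0; c < C; ++c) {
      double* oc = on + HW * c;
      for (R_xlen_t hw = 0; hw < HW; ++hw)
        oc[hw] = xn[c + (R_xlen_t)C * hw];
    }
  }
  return out;
}

// Group normalisation forward/backward over (H, W, C, N) tensors with
// per-(group, sample) statistics; the dominant elementwise cost of the
// network, so done in one compiled pass.

// [[Rcpp::export]]
List gn_forward_cpp(NumericVector x, int HW, int C, int G, int N,
                    NumericVector gamma, NumericVector beta, double eps) {
  const int cpg = C / G;
  const R_xlen_t m = (R_xlen_t)HW * cpg;
  const int ncol = G * N;
  NumericVector y(x.size()), xhat(x.size()), sd(ncol);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int col = 0; col < ncol; ++col) {
    const double* xc = xp + m * col;
    double* hc = hp + m * col;
    double* yc = yp + m * col;
    double mu = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) mu += xc[i];
    mu /= m;
    double var = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double d = xc[i] - mu;
      var += d * d;
    }
    var /= m;
    const double s = std::sqrt(var + eps);
    sd[col] = s;
    const int g = col % G;
    for (int cc = 0; cc < cpg; ++cc) {
      const double ga = gamma[g * cpg + cc];
      const double be = beta[g * cpg + cc];
      for (R_xlen_t i = 0; i < HW; ++i) {
        const R_xlen_t k = (R_xlen_t)cc * HW + i;
        hc[k] = (xc[k] - mu) / s;
        yc[k] = hc[k] * ga + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sd);
}

// [[Rcpp::export]]
List gn_backward_cpp(NumericVector dout, NumericVector xhat, NumericVector sd,
                     NumericVector gamma, int HW, int C, int G, int N) {
  const int cpg = C / G;
  const R_xlen_t m = (R_xlen_t)HW * cpg;
  const int ncol = G * N;
  NumericVector dx(dout.size()), dgamma(C), dbeta(C);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  double* op = dx.begin();
  for (int col = 0; col < ncol; ++col) {
    const double* dc = dp + m * col;
    const double* hc = hp + m * col;
    double* oc = op + m * col;
    const int g = col % G;
    double mu1 = 0.0, mu2 = 0.0;
    for (int cc = 0; cc < cpg; ++cc) {
      const double ga = gamma[g * cpg + cc];
      double sg = 0.0, sb = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const R_xlen_t k = (R_xlen_t)cc * HW + i;
        const double dh = dc[k] * ga;
        mu1 += dh;
        mu2 += dh * hc[k];
        sg += dc[k] * hc[k];
        sb += dc[k];
      }
      dgamma[g * cpg + cc] += sg;
      dbeta[g * cpg + cc] += sb;
    }
    mu1 /= m;
    mu2 /= m;
    const double inv_s = 1.0 / sd[col];
    for (int cc = 0; cc < cpg; ++cc) {
      const double ga = gamma[g * cpg + cc];
      for (R_xlen_t i = 0; i < HW; ++i) {
        const R_xlen_t k = (R_xlen_t)cc * HW + i;
        oc[k] = (dc[k] * ga - mu1 - hc[k] * mu2) * inv_s;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Coordinate-descent Lasso path on the centred Gram formulation:
// G = X_c' X_c / N, q = X_c' y_c / N for column-centred X and centred y;
// the unpenalised intercept separates out as b = mean(y) - w . colmeans(X).
// Warm starts down the (decreasing) alpha grid with active-set sweeps;
// the gradient vector g = G w is maintained incrementally so one
// coordinate update costs O(D).

// [[Rcpp::export]]
List lasso_path_cpp(NumericMatrix G, NumericVector q, NumericVector alphas,
                    NumericVector w0, double tol, int max_iter) {
  const int D = G.nrow();
  const int A = alphas.size();
  NumericMatrix W(D, A);
  IntegerVector iters(A);
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> g(D, 0.0);
  for (int j = 0; j < D; ++j) {
    if (w[j] == 0.0) continue;
    const double* Gj = &G(0, j);
    for (int k = 0; k < D; ++k) g[k] += Gj[k] * w[j];
  }
  std::vector<int> all_idx(D), active;
  for (int j = 0; j < D; ++j) all_idx[j] = j;
  for (int a = 0; a < A; ++a) {
    const double alpha = alphas[a];
    auto sweep_set = [&](const std::vector<int>& idx) {
      double delta_max = 0.0;
      for (int j : idx) {
        const double cjj = G(j, j);
        if (cjj == 0.0) continue;
        const double z = q[j] - g[j] + cjj * w[j];
        double wn = 0.0;
        if (z > alpha) wn = (z - alpha) / cjj;
        else if (z < -alpha) wn = (z + alpha) / cjj;
        const double d = wn - w[j];
        if (d != 0.0) {
          const double* Gj = &G(0, j);
          for (int k = 0; k < D; ++k) g[k] += Gj[k] * d;
          w[j] = wn;
          if (std::abs(d) > delta_max) delta_max = std::abs(d);
        }
      }
      return delta_max;
    };
    int it = 0;
    while (it < max_iter) {
      ++it;
      const double dm = sweep_set(all_idx);
      if (dm < tol) break;
      active.clear();
      for (int j = 0; j < D; ++j) if (w[j] != 0.0) active.push_back(j);
      while (!active.empty() && it < max_iter) {
        ++it;
        if (sweep_set(active) < tol) break;
      }
    }
    iters[a] = it;
    for (int j = 0; j < D; ++j) W(j, a) = w[j];
  }
  return List::create(_["W"] = W, _["iterations"] = iters);
}
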
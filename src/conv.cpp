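// Grouped 2-D convolution, forward and backward, via im2col + GEMM.
// Tensor layout follows R's column-major array convention:
//   feature maps  (H, W, C, N)   index h + H*(w + W*(c + C*n))
//   kernels       (kh, kw, Cin/g, Cout)
// Stride and symmetric zero padding; groups=1 is dense, groups=Cin is
// depthwise. Backward recomputes im2col rather than caching it, trading a
// little time for a much smaller training-memory footprint.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (K x Ho*Wo) for one sample and one channel group.
// K = kh*kw*Cg; column j = ho + Ho*wo.
static void im2col_group(const double* x, int H, int W, int C,
                         int c0, int Cg, int kh, int kw,
                         int pad, int stride, int Ho, int Wo,
                         arma::mat& col) {
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          double* dst = col.colptr(0) + row; // stride K between columns
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(row, ho + Ho * wo) = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            col(row, ho + Ho * wo) =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the (padded) input gradient.
static void col2im_group(const arma::mat& col, double* gx, int H, int W,
                         int C, int c0, int Cg, int kh, int kw,
                         int pad, int stride, int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* gc = gx + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fw", rng = false)]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector b, int stride, int pad,
                            int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C / groups != Cg) stop("channel/group mismatch");
  int Cout_g = Cout / groups;
  int Ho = out_dim(H, kh, pad, stride), Wo = out_dim(W, kw, pad, stride);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  int K = kh * kw * Cg;
  size_t hw = (size_t)Ho * Wo;
  // fast path: 1x1 stride-1 convolution is a plain channel-mixing GEMM
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        arma::mat Xg(const_cast<double*>(x.begin()) +
                         (size_t)n * hw * C + (size_t)g * Cg * hw,
                     hw, Cg, false, true);
        arma::mat Wg(const_cast<double*>(w.begin()) +
                         (size_t)g * Cg * Cout_g,
                     Cg, Cout_g, false, true);
        arma::mat Og(out.begin() + (size_t)n * hw * Cout +
                         (size_t)g * Cout_g * hw,
                     hw, Cout_g, false, true);
        Og = Xg * Wg;
        for (int co = 0; co < Cout_g; ++co) {
          double bias = b[g * Cout_g + co];
          if (bias != 0.0) Og.col(co) += bias;
        }
      }
    }
    return out;
  }
  // chunk samples so the im2col buffer stays within ~64 MB
  int chunk = (int)std::max((size_t)1,
                            std::min((size_t)N, (size_t)250000 / (K * hw)));
  arma::mat col(K, hw * chunk);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nb = std::min(chunk, N - n0);
    for (int g = 0; g < groups; ++g) {
      for (int s = 0; s < nb; ++s) {
        arma::mat sub(col.colptr(s * hw), K, hw, false, true);
        im2col_group(xp + (size_t)(n0 + s) * H * W * C, H, W, C, g * Cg,
                     Cg, kh, kw, pad, stride, Ho, Wo, sub);
      }
      arma::mat colv(col.memptr(), K, hw * nb, false, true);
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * K * Cout_g,
                   K, Cout_g, false, true);
      arma::mat M = colv.t() * Wg; // (hw*nb) x Cout_g
      for (int s = 0; s < nb; ++s) {
        double* dst = op + (size_t)(n0 + s) * hw * Cout +
                      (size_t)g * Cout_g * hw;
        for (int co = 0; co < Cout_g; ++co) {
          const double* src = M.colptr(co) + (size_t)s * hw;
          double* d = dst + (size_t)co * hw;
          double bias = b[g * Cout_g + co];
          if (bias == 0.0) {
            std::memcpy(d, src, sizeof(double) * hw);
          } else {
            for (size_t i = 0; i < hw; ++i) d[i] = src[i] + bias;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw", rng = false)]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gout,
                   int stride, int pad, int groups, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Cout_g = Cout / groups;
  int Ho = out_dim(H, kh, pad, stride), Wo = out_dim(W, kw, pad, stride);
  int K = kh * kw * Cg;
  size_t hw = (size_t)Ho * Wo;
  NumericVector gx(need_gx ? (R_xlen_t)H * W * C * N : 0);
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((R_xlen_t)kh * kw * Cg * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cg, Cout);
  NumericVector gb(Cout);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      for (int g = 0; g < groups; ++g) {
        arma::mat Xg(const_cast<double*>(x.begin()) +
                         (size_t)n * hw * C + (size_t)g * Cg * hw,
                     hw, Cg, false, true);
        arma::mat Gg(const_cast<double*>(gout.begin()) +
                         (size_t)n * hw * Cout + (size_t)g * Cout_g * hw,
                     hw, Cout_g, false, true);
        arma::mat Gw(gw.begin() + (size_t)g * Cg * Cout_g, Cg, Cout_g,
                     false, true);
        Gw += Xg.t() * Gg;
        for (int co = 0; co < Cout_g; ++co)
          gb[g * Cout_g + co] += arma::accu(Gg.col(co));
        if (need_gx) {
          arma::mat Wg(const_cast<double*>(w.begin()) +
                           (size_t)g * Cg * Cout_g,
                       Cg, Cout_g, false, true);
          arma::mat GXg(gx.begin() + (size_t)n * hw * C +
                            (size_t)g * Cg * hw,
                        hw, Cg, false, true);
          GXg += Gg * Wg.t();
        }
      }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  int chunk = (int)std::max((size_t)1,
                            std::min((size_t)N, (size_t)250000 / (K * hw)));
  arma::mat col(K, hw * chunk);
  arma::mat Gm(hw * chunk, Cout_g);
  const double* xp = x.begin();
  const double* gp = gout.begin();
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nb = std::min(chunk, N - n0);
    for (int g = 0; g < groups; ++g) {
      for (int s = 0; s < nb; ++s) {
        arma::mat sub(col.colptr(s * hw), K, hw, false, true);
        im2col_group(xp + (size_t)(n0 + s) * H * W * C, H, W, C, g * Cg,
                     Cg, kh, kw, pad, stride, Ho, Wo, sub);
        for (int co = 0; co < Cout_g; ++co) {
          std::memcpy(Gm.colptr(co) + (size_t)s * hw,
                      gp + (size_t)(n0 + s) * hw * Cout +
                          (size_t)(g * Cout_g + co) * hw,
                      sizeof(double) * hw);
        }
      }
      arma::mat colv(col.memptr(), K, hw * nb, false, true);
      arma::mat Gmv(Gm.memptr(), hw * nb, Cout_g, false, true);
      arma::mat Gw(gw.begin() + (size_t)g * K * Cout_g, K, Cout_g, false,
                   true);
      Gw += colv * Gmv;
      for (int co = 0; co < Cout_g; ++co)
        gb[g * Cout_g + co] += arma::accu(Gmv.col(co));
      if (need_gx) {
        arma::mat Wg(const_cast<double*>(w.begin()) +
                         (size_t)g * K * Cout_g,
                     K, Cout_g, false, true);
        arma::mat gcol = Wg * Gmv.t(); // K x hw*nb
        for (int s = 0; s < nb; ++s) {
          arma::mat sub(gcol.colptr(s * hw), K, hw, false, true);
          col2im_group(sub, gx.begin() + (size_t)(n0 + s) * H * W * C, H,
                       W, C, g * Cg, Cg, kh, kw, pad, stride, Ho, Wo);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}


// Group normalisation, fused forward/backward. x is (H, W, C, N); groups
// divide C; statistics are over (H, W, C/groups) per sample.
// [[Rcpp::export(name = ".cpp_groupnorm_fw", rng = false)]]
List cpp_groupnorm_fw(NumericVector x, NumericVector gamma,
                      NumericVector beta, int groups, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cg = C / groups;
  size_t m = (size_t)H * W * Cg;
  int ncol = groups * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = xd;
  NumericVector xhat((R_xlen_t)H * W * C * N);
  NumericVector inv(ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  double* hp = xhat.begin();
  size_t hw = (size_t)H * W;
  for (int j = 0; j < ncol; ++j) {
    const double* xc = xp + (size_t)j * m;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    double mu = s / m;
    double va = s2 / m - mu * mu;
    double iv = 1.0 / std::sqrt(va > 0 ? va + eps : eps);
    inv[j] = iv;
    int g = j % groups;   // group index within sample
    double* oc = op + (size_t)j * m;
    double* hc = hp + (size_t)j * m;
    for (int c = 0; c < Cg; ++c) {
      double ga = gamma[g * Cg + c], be = beta[g * Cg + c];
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[c * hw + i] - mu) * iv;
        hc[c * hw + i] = xh;
        oc[c * hw + i] = xh * ga + be;
      }
    }
  }
  return List::create(_["y"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = ".cpp_groupnorm_bw", rng = false)]]
List cpp_groupnorm_bw(NumericVector g, NumericVector xhat,
                      NumericVector inv, NumericVector gamma, int groups) {
  IntegerVector xd = g.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cg = C / groups;
  size_t m = (size_t)H * W * Cg;
  size_t hw = (size_t)H * W;
  int ncol = groups * N;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  const double* gp = g.begin();
  const double* hp = xhat.begin();
  double* xp = gx.begin();
  for (int j = 0; j < ncol; ++j) {
    const double* gc = gp + (size_t)j * m;
    const double* hc = hp + (size_t)j * m;
    double* xc = xp + (size_t)j * m;
    int gi = j % groups;
    // per-channel affine grads + per-group means of dyhat and dyhat*xhat
    double m1 = 0, m2 = 0;
    for (int c = 0; c < Cg; ++c) {
      double ga = gamma[gi * Cg + c];
      double sg = 0, sgx = 0;
      for (size_t i = 0; i < hw; ++i) {
        double gv = gc[c * hw + i];
        double dyh = gv * ga;
        sg += gv;
        sgx += gv * hc[c * hw + i];
        m1 += dyh;
        m2 += dyh * hc[c * hw + i];
      }
      gbeta[gi * Cg + c] += sg;
      ggamma[gi * Cg + c] += sgx;
    }
    m1 /= m; m2 /= m;
    double iv = inv[j];
    for (int c = 0; c < Cg; ++c) {
      double ga = gamma[gi * Cg + c];
      for (size_t i = 0; i < hw; ++i) {
        xc[c * hw + i] =
            (gc[c * hw + i] * ga - m1 - hc[c * hw + i] * m2) * iv;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
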
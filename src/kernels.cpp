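// Low-level 3D tensor primitives used by the network and the resamplers.
// All 4-D feature maps are channels-last, column-major: dim (D, H, W, C),
// linear index d + D*(h + H*(w + W*c)).  Convolutions run as chunked
// im2col + GEMM so peak memory stays bounded on full-resolution volumes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// upper bound on the im2col buffer, in doubles (~64 MB)
static const size_t COL_BUDGET = 8000000;

static inline int chunk_depth(int D, int H, int W, int K) {
  size_t per_slice = (size_t)H * W * K;
  int cd = per_slice == 0 ? D : (int)std::max((size_t)1, COL_BUDGET / per_slice);
  return std::min(cd, D);
}

// Fill col (chunkV x K) for output depths [d0, d1); K = k^3 * Cin.
// Column j = ci*k^3 + (dz + k*(dy + k*dx)).  Depth runs are contiguous in
// both source and destination, so the inner loop is a bounded memcpy.
static void im2col_chunk(const double* x, int D, int H, int W, int Cin,
                         int k, int pad, int d0, int d1, arma::mat& col) {
  const int cd = d1 - d0;
  const int k3 = k * k * k;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)D * H * W * ci;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dz = 0; dz < k; ++dz) {
          const int j = ci * k3 + dz + k * (dy + k * dx);
          double* cj = col.colptr(j);
          const int dlo = std::max(d0, pad - dz);
          const int dhi = std::min(d1, D + pad - dz);
          for (int w = 0; w < W; ++w) {
            const int sx = w + dx - pad;
            const bool okx = sx >= 0 && sx < W;
            for (int h = 0; h < H; ++h) {
              double* dst = cj + (size_t)cd * (h + (size_t)H * w);
              const int sy = h + dy - pad;
              if (!okx || sy < 0 || sy >= H) {
                std::memset(dst, 0, sizeof(double) * cd);
                continue;
              }
              const size_t xoff = (size_t)D * (sy + (size_t)H * sx);
              if (dlo > d0)
                std::memset(dst, 0, sizeof(double) * (dlo - d0));
              if (dhi > dlo)
                std::memcpy(dst + (dlo - d0), xc + xoff + (dlo + dz - pad),
                            sizeof(double) * (dhi - dlo));
              if (d1 > dhi)
                std::memset(dst + std::max(dhi, d0) - d0, 0,
                            sizeof(double) * (d1 - std::max(dhi, d0)));
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col_chunk: accumulate col back into gx.
static void col2im_chunk(const arma::mat& col, double* gx, int D, int H, int W,
                         int Cin, int k, int pad, int d0, int d1) {
  const int cd = d1 - d0;
  const int k3 = k * k * k;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gx + (size_t)D * H * W * ci;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dz = 0; dz < k; ++dz) {
          const int j = ci * k3 + dz + k * (dy + k * dx);
          const double* cj = col.colptr(j);
          const int dlo = std::max(d0, pad - dz);
          const int dhi = std::min(d1, D + pad - dz);
          if (dhi <= dlo) continue;
          for (int w = 0; w < W; ++w) {
            const int sx = w + dx - pad;
            if (sx < 0 || sx >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sy = h + dy - pad;
              if (sy < 0 || sy >= H) continue;
              const size_t xoff = (size_t)D * (sy + (size_t)H * sx);
              const double* src = cj + (size_t)cd * (h + (size_t)H * w);
              double* dst = gc + xoff + (dlo + dz - pad);
              const double* s = src + (dlo - d0);
              for (int d = 0; d < dhi - dlo; ++d) dst[d] += s[d];
            }
          }
        }
      }
    }
  }
}

// Same-resolution 3D convolution (stride 1, pad = (k-1)/2).
// W is (k^3*Cin) x Cout, bias length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix Wm, NumericVector bias,
                             int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const int K = k * k * k * Cin, Cout = Wm.ncol();
  if (Wm.nrow() != K) stop("conv weight rows mismatch");
  NumericVector out((size_t)D * H * W * Cout);
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  const arma::mat Wmat(Wm.begin(), K, Cout, false);
  const int cdmax = chunk_depth(D, H, W, K);
  arma::mat col(cdmax * (size_t)H * W, K);
  for (int d0 = 0; d0 < D; d0 += cdmax) {
    const int d1 = std::min(D, d0 + cdmax);
    const int cd = d1 - d0;
    const size_t cv = (size_t)cd * H * W;
    arma::mat colv(col.memptr(), cv, K, false, true);
    im2col_chunk(x.begin(), D, H, W, Cin, k, pad, d0, d1, colv);
    arma::mat oc = colv * Wmat;  // cv x Cout
    for (int co = 0; co < Cout; ++co) {
      const double b = bias[co];
      const double* src = oc.colptr(co);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double* dst = out.begin() + d0 +
            (size_t)D * (h + (size_t)H * (w + (size_t)W * co));
          const double* s = src + (size_t)cd * (h + (size_t)H * w);
          for (int d = 0; d < cd; ++d) dst[d] = s[d] + b;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector gout, int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const int K = k * k * k * Cin, Cout = Wm.ncol();
  const arma::mat Wmat(Wm.begin(), K, Cout, false);
  NumericVector gx((size_t)D * H * W * Cin);
  gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  arma::mat gW(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  const int cdmax = chunk_depth(D, H, W, K);
  arma::mat col(cdmax * (size_t)H * W, K);
  arma::mat gchunk(cdmax * (size_t)H * W, Cout);
  for (int d0 = 0; d0 < D; d0 += cdmax) {
    const int d1 = std::min(D, d0 + cdmax);
    const int cd = d1 - d0;
    const size_t cv = (size_t)cd * H * W;
    arma::mat colv(col.memptr(), cv, K, false, true);
    arma::mat gv(gchunk.memptr(), cv, Cout, false, true);
    for (int co = 0; co < Cout; ++co) {
      double* dst = gv.colptr(co);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* src = gout.begin() + d0 +
            (size_t)D * (h + (size_t)H * (w + (size_t)W * co));
          double* s = dst + (size_t)cd * (h + (size_t)H * w);
          for (int d = 0; d < cd; ++d) s[d] = src[d];
        }
      gb[co] += arma::accu(gv.col(co));
    }
    im2col_chunk(x.begin(), D, H, W, Cin, k, pad, d0, d1, colv);
    gW += colv.t() * gv;
    arma::mat gcol = gv * Wmat.t();  // cv x K
    col2im_chunk(gcol, gx.begin(), D, H, W, Cin, k, pad, d0, d1);
  }
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// Transposed convolution, kernel 2^3, stride 2 (doubles each spatial dim).
// W is Cin x (Cout*8); column co*8 + (dz + 2*(dy + 2*dx)).
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix Wm, NumericVector bias) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const int Cout = Wm.ncol() / 8;
  const size_t V = (size_t)D * H * W;
  const arma::mat X(x.begin(), V, Cin, false);
  const arma::mat Wmat(Wm.begin(), Cin, (size_t)Cout * 8, false);
  arma::mat colm = X * Wmat;  // V x Cout*8
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector out((size_t)D2 * H2 * W2 * Cout);
  out.attr("dim") = IntegerVector::create(D2, H2, W2, Cout);
  for (int co = 0; co < Cout; ++co) {
    const double b = bias[co];
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
        for (int dz = 0; dz < 2; ++dz) {
          const double* src = colm.colptr(co * 8 + dz + 2 * (dy + 2 * dx));
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h) {
              const double* s = src + (size_t)D * (h + (size_t)H * w);
              double* dst = out.begin() + (size_t)(2 * 0 + dz) +
                (size_t)D2 * ((2 * h + dy) +
                (size_t)H2 * ((2 * w + dx) + (size_t)W2 * co));
              for (int d = 0; d < D; ++d) dst[2 * d] = s[d] + b;
            }
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector gout) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const int Cout = Wm.ncol() / 8;
  const size_t V = (size_t)D * H * W;
  const arma::mat X(x.begin(), V, Cin, false);
  const arma::mat Wmat(Wm.begin(), Cin, (size_t)Cout * 8, false);
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  arma::mat gcol(V, (size_t)Cout * 8);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
        for (int dz = 0; dz < 2; ++dz) {
          double* dst = gcol.colptr(co * 8 + dz + 2 * (dy + 2 * dx));
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h) {
              double* s = dst + (size_t)D * (h + (size_t)H * w);
              const double* src = gout.begin() + (size_t)dz +
                (size_t)D2 * ((2 * h + dy) +
                (size_t)H2 * ((2 * w + dx) + (size_t)W2 * co));
              for (int d = 0; d < D; ++d) { s[d] = src[2 * d]; acc += src[2 * d]; }
            }
        }
    gb[co] = acc;
  }
  arma::mat gW = X.t() * gcol;          // Cin x Cout*8
  arma::mat gX = gcol * Wmat.t();       // V x Cin
  NumericVector gx(wrap(arma::vectorise(gX)));
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// Max pooling, kernel = stride = k; spatial dims must divide by k.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  if (D % k || H % k || W % k) stop("pooling requires divisible dims");
  const int Do = D / k, Ho = H / k, Wo = W / k;
  const size_t Vo = (size_t)Do * Ho * Wo * C;
  NumericVector out(Vo);
  IntegerVector amax(Vo);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -INFINITY; size_t bi = 0;
          for (int dx = 0; dx < k; ++dx)
            for (int dy = 0; dy < k; ++dy)
              for (int dz = 0; dz < k; ++dz) {
                const size_t ix = (size_t)(k * d + dz) +
                  (size_t)D * ((k * h + dy) +
                  (size_t)H * ((k * w + dx) + (size_t)W * c));
                if (x[ix] > best) { best = x[ix]; bi = ix; }
              }
          const size_t io = (size_t)d +
            (size_t)Do * (h + (size_t)Ho * (w + (size_t)Wo * c));
          out[io] = best;
          amax[io] = (int)bi;
        }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector amax,
                              IntegerVector in_dims) {
  NumericVector gx((size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3]);
  gx.attr("dim") = in_dims;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[amax[i]] += gout[i];
  return gx;
}

struct AxisMap { std::vector<int> i0, i1; std::vector<double> w1; };

// half-pixel-centre coordinate mapping; exact identity when n_out == n_in
static AxisMap axis_map(int n_in, int n_out) {
  AxisMap m; m.i0.resize(n_out); m.i1.resize(n_out); m.w1.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int lo = (int)std::floor(s);
    if (lo > n_in - 2) lo = std::max(0, n_in - 2);
    m.i0[i] = lo;
    m.i1[i] = std::min(lo + 1, n_in - 1);
    m.w1[i] = s - lo;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_resize3_lin(NumericVector x, IntegerVector in_dhw,
                              IntegerVector out_dhw, int C) {
  const int D = in_dhw[0], H = in_dhw[1], W = in_dhw[2];
  const int Do = out_dhw[0], Ho = out_dhw[1], Wo = out_dhw[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector out((size_t)Do * Ho * Wo * C);
  if (C > 1) out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  else out.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)D * H * W * c;
    double* oc = out.begin() + (size_t)Do * Ho * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      const int x0 = mw.i0[w], x1 = mw.i1[w]; const double fx = mw.w1[w];
      for (int h = 0; h < Ho; ++h) {
        const int y0 = mh.i0[h], y1 = mh.i1[h]; const double fy = mh.w1[h];
        const size_t o00 = (size_t)D * (y0 + (size_t)H * x0);
        const size_t o01 = (size_t)D * (y0 + (size_t)H * x1);
        const size_t o10 = (size_t)D * (y1 + (size_t)H * x0);
        const size_t o11 = (size_t)D * (y1 + (size_t)H * x1);
        double* dst = oc + (size_t)Do * (h + (size_t)Ho * w);
        for (int d = 0; d < Do; ++d) {
          const int z0 = md.i0[d], z1 = md.i1[d]; const double fz = md.w1[d];
          const double v00 = xc[z0 + o00] * (1 - fz) + xc[z1 + o00] * fz;
          const double v01 = xc[z0 + o01] * (1 - fz) + xc[z1 + o01] * fz;
          const double v10 = xc[z0 + o10] * (1 - fz) + xc[z1 + o10] * fz;
          const double v11 = xc[z0 + o11] * (1 - fz) + xc[z1 + o11] * fz;
          dst[d] = (v00 * (1 - fy) + v10 * fy) * (1 - fx)
                 + (v01 * (1 - fy) + v11 * fy) * fx;
        }
      }
    }
  }
  return out;
}

// adjoint of cpp_resize3_lin (scatter-add of the interpolation weights)
// [[Rcpp::export]]
NumericVector cpp_resize3_lin_adj(NumericVector gout, IntegerVector in_dhw,
                                  IntegerVector out_dhw, int C) {
  const int D = in_dhw[0], H = in_dhw[1], W = in_dhw[2];
  const int Do = out_dhw[0], Ho = out_dhw[1], Wo = out_dhw[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector gx((size_t)D * H * W * C);
  if (C > 1) gx.attr("dim") = IntegerVector::create(D, H, W, C);
  else gx.attr("dim") = IntegerVector::create(D, H, W);
  for (int c = 0; c < C; ++c) {
    double* xc = gx.begin() + (size_t)D * H * W * c;
    const double* oc = gout.begin() + (size_t)Do * Ho * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      const int x0 = mw.i0[w], x1 = mw.i1[w]; const double fx = mw.w1[w];
      for (int h = 0; h < Ho; ++h) {
        const int y0 = mh.i0[h], y1 = mh.i1[h]; const double fy = mh.w1[h];
        const double* src = oc + (size_t)Do * (h + (size_t)Ho * w);
        for (int d = 0; d < Do; ++d) {
          const int z0 = md.i0[d], z1 = md.i1[d]; const double fz = md.w1[d];
          const double g = src[d];
          const double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
          const double w01 = (1 - fy) * fx, w11 = fy * fx;
          xc[z0 + (size_t)D * (y0 + (size_t)H * x0)] += g * w00 * (1 - fz);
          xc[z1 + (size_t)D * (y0 + (size_t)H * x0)] += g * w00 * fz;
          xc[z0 + (size_t)D * (y1 + (size_t)H * x0)] += g * w10 * (1 - fz);
          xc[z1 + (size_t)D * (y1 + (size_t)H * x0)] += g * w10 * fz;
          xc[z0 + (size_t)D * (y0 + (size_t)H * x1)] += g * w01 * (1 - fz);
          xc[z1 + (size_t)D * (y0 + (size_t)H * x1)] += g * w01 * fz;
          xc[z0 + (size_t)D * (y1 + (size_t)H * x1)] += g * w11 * (1 - fz);
          xc[z1 + (size_t)D * (y1 + (size_t)H * x1)] += g * w11 * fz;
        }
      }
    }
  }
  return gx;
}

// nearest-neighbour resize of one 3-D volume (labels)
// [[Rcpp::export]]
NumericVector cpp_resize3_nn(NumericVector x, IntegerVector in_dhw,
                             IntegerVector out_dhw) {
  const int D = in_dhw[0], H = in_dhw[1], W = in_dhw[2];
  const int Do = out_dhw[0], Ho = out_dhw[1], Wo = out_dhw[2];
  std::vector<int> zi(Do), yi(Ho), xi(Wo);
  auto nn = [](int n_in, int n_out, std::vector<int>& v) {
    const double scale = (double)n_in / n_out;
    for (int i = 0; i < n_out; ++i) {
      int s = (int)std::lround((i + 0.5) * scale - 0.5);
      v[i] = std::min(std::max(s, 0), n_in - 1);
    }
  };
  nn(D, Do, zi); nn(H, Ho, yi); nn(W, Wo, xi);
  NumericVector out((size_t)Do * Ho * Wo);
  out.attr("dim") = out_dhw;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h) {
      const size_t off = (size_t)D * (yi[h] + (size_t)H * xi[w]);
      double* dst = out.begin() + (size_t)Do * (h + (size_t)Ho * w);
      for (int d = 0; d < Do; ++d) dst[d] = x[zi[d] + off];
    }
  return out;
}

// Affine warp of a 3-D volume: source = A %*% (v - centre) + centre,
// with A the inverse (output-to-input) map.  interp 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_warp3(NumericVector x, IntegerVector dhw, NumericMatrix A,
                        int interp, double fill) {
  const int D = dhw[0], H = dhw[1], W = dhw[2];
  const double cz = (D - 1) / 2.0, cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericVector out((size_t)D * H * W);
  out.attr("dim") = dhw;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const double vz = d - cz, vy = h - cy, vx = w - cx;
        const double sz = A(0, 0) * vz + A(0, 1) * vy + A(0, 2) * vx + cz;
        const double sy = A(1, 0) * vz + A(1, 1) * vy + A(1, 2) * vx + cy;
        const double sx = A(2, 0) * vz + A(2, 1) * vy + A(2, 2) * vx + cx;
        double val = fill;
        if (interp == 0) {
          const int iz = (int)std::lround(sz), iy = (int)std::lround(sy),
                    ix = (int)std::lround(sx);
          if (iz >= 0 && iz < D && iy >= 0 && iy < H && ix >= 0 && ix < W)
            val = x[(size_t)iz + (size_t)D * (iy + (size_t)H * ix)];
        } else if (sz >= 0 && sz <= D - 1 && sy >= 0 && sy <= H - 1 &&
                   sx >= 0 && sx <= W - 1) {
          int z0 = (int)std::floor(sz), y0 = (int)std::floor(sy),
              x0 = (int)std::floor(sx);
          if (z0 > D - 2) z0 = std::max(0, D - 2);
          if (y0 > H - 2) y0 = std::max(0, H - 2);
          if (x0 > W - 2) x0 = std::max(0, W - 2);
          const int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1),
                    x1 = std::min(x0 + 1, W - 1);
          const double fz = sz - z0, fy = sy - y0, fx = sx - x0;
          auto at = [&](int z, int y, int xx) {
            return x[(size_t)z + (size_t)D * (y + (size_t)H * xx)];
          };
          val = ((at(z0, y0, x0) * (1 - fz) + at(z1, y0, x0) * fz) * (1 - fy) +
                 (at(z0, y1, x0) * (1 - fz) + at(z1, y1, x0) * fz) * fy) * (1 - fx) +
                ((at(z0, y0, x1) * (1 - fz) + at(z1, y0, x1) * fz) * (1 - fy) +
                 (at(z0, y1, x1) * (1 - fz) + at(z1, y1, x1) * fz) * fy) * fx;
        }
        out[(size_t)d + (size_t)D * (h + (size_t)H * w)] = val;
      }
  return out;
}
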
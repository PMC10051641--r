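// Low-level numerical kernels for the neural-network engine and image ops.
// Layout conventions: feature maps are H x W x C x N arrays (column-major,
// as produced by base R), weights for a k x k convolution are k x k x Cin x Cout.
// Convolutions use "same" zero padding and stride 1; pooling is 2 x 2 stride 2.
// Arithmetic is single precision internally (BLAS sgemm via Armadillo).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold one sample (H x W x C float cube) into an (H*W) x (k*k*C) matrix so a
// same-padded k x k convolution becomes a single GEMM. Column ordering matches
// the column-major flattening of a k x k x C R array.
static arma::fmat im2col(const arma::fcube &x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = k / 2;
  arma::fmat col(H * (arma::uword)W, (arma::uword)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::fmat &xs = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword cc = (arma::uword)c * k * k + kj * k + ki;
        const int di = ki - r, dj = kj - r;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          float *dst = col.colptr(cc) + (arma::uword)j * H;
          const float *src = xs.colptr(j + dj) + di;
          for (int i = i0; i < i1; ++i) dst[i] = src[i];
        }
      }
    }
  }
  return col;
}

// Scatter-add inverse of im2col.
static void col2im(const arma::fmat &col, int k, arma::fcube &gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices, r = k / 2;
  for (int c = 0; c < C; ++c) {
    arma::fmat &xs = gx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword cc = (arma::uword)c * k * k + kj * k + ki;
        const int di = ki - r, dj = kj - r;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          float *dst = xs.colptr(j + dj) + di;
          const float *src = col.colptr(cc) + (arma::uword)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static arma::fcube sample_cube(const NumericVector &x, int H, int W, int C, int n) {
  arma::fcube out(H, W, C);
  const double *p = x.begin() + (R_xlen_t)n * H * W * C;
  std::copy(p, p + (R_xlen_t)H * W * C, out.memptr());
  return out;
}

// [[Rcpp::export]]
NumericVector conv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and weights");
  arma::fmat Wm((arma::uword)k * k * C, Cout);
  std::copy(w.begin(), w.end(), Wm.memptr());
  arma::frowvec bv(Cout);
  for (int i = 0; i < Cout; ++i) bv[i] = (float)b[i];
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::fcube xc = sample_cube(x, H, W, C, n);
    arma::fmat yn = im2col(xc, k) * Wm;
    yn.each_row() += bv;
    double *dst = y.begin() + (R_xlen_t)n * H * W * Cout;
    std::copy(yn.begin(), yn.end(), dst);
  }
  return y;
}

// [[Rcpp::export]]
List conv_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  arma::fmat Wm((arma::uword)k * k * C, Cout);
  std::copy(w.begin(), w.end(), Wm.memptr());
  arma::fmat gW((arma::uword)k * k * C, Cout, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    arma::fcube xc = sample_cube(x, H, W, C, n);
    arma::fmat col = im2col(xc, k);
    arma::fmat gyn(H * (arma::uword)W, Cout);
    std::copy(gy.begin() + (R_xlen_t)n * H * W * Cout,
              gy.begin() + (R_xlen_t)(n + 1) * H * W * Cout, gyn.memptr());
    gW += col.t() * gyn;
    gb += arma::sum(gyn, 0).t();
    arma::fmat gcol = gyn * Wm.t();
    arma::fcube gxc(H, W, C, arma::fill::zeros);
    col2im(gcol, k, gxc);
    std::copy(gxc.begin(), gxc.end(), gx.begin() + (R_xlen_t)n * H * W * C);
  }
  NumericVector gwv((R_xlen_t)k * k * C * Cout);
  gwv.attr("dim") = wd;
  std::copy(gW.begin(), gW.end(), gwv.begin());
  NumericVector gbv(Cout);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N); // 0..3: (di,dj) = (idx%2, idx/2)
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          int best = 0;
          double bv = xs[(R_xlen_t)(2 * j) * H + 2 * i];
          for (int q = 1; q < 4; ++q) {
            double v = xs[(R_xlen_t)(2 * j + q / 2) * H + 2 * i + q % 2];
            if (v > bv) { bv = v; best = q; }
          }
          y[o] = bv; idx[o] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *gs = gx.begin() + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          int q = idx[o];
          gs[(R_xlen_t)(2 * j + q / 2) * H + 2 * i + q % 2] += gy[o];
        }
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector avgpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o)
          y[o] = 0.25 * (xs[(R_xlen_t)(2 * j) * H + 2 * i] +
                         xs[(R_xlen_t)(2 * j) * H + 2 * i + 1] +
                         xs[(R_xlen_t)(2 * j + 1) * H + 2 * i] +
                         xs[(R_xlen_t)(2 * j + 1) * H + 2 * i + 1]);
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bw(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *gs = gx.begin() + ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          const double g = 0.25 * gy[o];
          gs[(R_xlen_t)(2 * j) * H + 2 * i] += g;
          gs[(R_xlen_t)(2 * j) * H + 2 * i + 1] += g;
          gs[(R_xlen_t)(2 * j + 1) * H + 2 * i] += g;
          gs[(R_xlen_t)(2 * j + 1) * H + 2 * i + 1] += g;
        }
    }
  return gx;
}

// Inverse-mapping affine warp on an H x W matrix in row/col coordinates.
// For output pixel p (0-based row/col), the source location is A %*% p + t.
// filter 0 = nearest neighbour (binary-preserving), 1 = bilinear.
// Out-of-frame samples take value `fill`.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericMatrix A, NumericVector t,
                              int filter, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const double t1 = t[0], t2 = t[1];
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double sr = a11 * i + a12 * j + t1;
      const double sc = a21 * i + a22 * j + t2;
      double v = fill;
      if (filter == 0) {
        const int ri = (int)std::lround(sr), ci = (int)std::lround(sc);
        if (ri >= 0 && ri < H && ci >= 0 && ci < W) v = img(ri, ci);
      } else {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        if (r0 >= 0 && r0 + 1 < H && c0 >= 0 && c0 + 1 < W) {
          const double fr = sr - r0, fc = sc - c0;
          v = (1 - fr) * (1 - fc) * img(r0, c0) + fr * (1 - fc) * img(r0 + 1, c0) +
              (1 - fr) * fc * img(r0, c0 + 1) + fr * fc * img(r0 + 1, c0 + 1);
        } else if (r0 >= -1 && r0 < H && c0 >= -1 && c0 < W) {
          // border: clamp the out-of-frame corners to fill
          const double fr = sr - r0, fc = sc - c0;
          auto at = [&](int r, int c) {
            return (r >= 0 && r < H && c >= 0 && c < W) ? img(r, c) : fill;
          };
          v = (1 - fr) * (1 - fc) * at(r0, c0) + fr * (1 - fc) * at(r0 + 1, c0) +
              (1 - fr) * fc * at(r0, c0 + 1) + fr * fc * at(r0 + 1, c0 + 1);
        }
      }
      out(i, j) = v;
    }
  return out;
}

// Patch-based non-local means denoising of an 8-bit grayscale matrix.
// h: filter strength (Gaussian weighting of patch distances),
// patch_r / search_r: patch and search-window radii.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double h, int patch_r, int search_r) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double h2 = h * h;
  const int parea = (2 * patch_r + 1) * (2 * patch_r + 1);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double wsum = 0.0, vsum = 0.0;
      for (int dj = -search_r; dj <= search_r; ++dj)
        for (int di = -search_r; di <= search_r; ++di) {
          const int ci = i + di, cj = j + dj;
          if (ci < 0 || ci >= H || cj < 0 || cj >= W) continue;
          double d2 = 0.0;
          for (int pj = -patch_r; pj <= patch_r; ++pj)
            for (int pi = -patch_r; pi <= patch_r; ++pi) {
              const int r1 = std::min(std::max(i + pi, 0), H - 1);
              const int c1 = std::min(std::max(j + pj, 0), W - 1);
              const int r2 = std::min(std::max(ci + pi, 0), H - 1);
              const int c2 = std::min(std::max(cj + pj, 0), W - 1);
              const double d = img(r1, c1) - img(r2, c2);
              d2 += d * d;
            }
          const double w = std::exp(-d2 / (parea * h2));
          wsum += w;
          vsum += w * img(ci, cj);
        }
      out(i, j) = vsum / wsum;
    }
  return out;
}

// Distance-to-segment rasterisation: marks pixels within `radius` of the
// segment (r0,c0)-(r1,c1) in the logical mask (updated in place via copy).
// [[Rcpp::export]]
LogicalMatrix raster_segments_cpp(int H, int W, NumericMatrix seg) {
  // seg columns: r0, c0, r1, c1, radius
  LogicalMatrix mask(H, W);
  for (int s = 0; s < seg.nrow(); ++s) {
    const double r0 = seg(s, 0), c0 = seg(s, 1), r1 = seg(s, 2), c1 = seg(s, 3);
    const double rad = seg(s, 4);
    const int ilo = std::max(0, (int)std::floor(std::min(r0, r1) - rad - 1));
    const int ihi = std::min(H - 1, (int)std::ceil(std::max(r0, r1) + rad + 1));
    const int jlo = std::max(0, (int)std::floor(std::min(c0, c1) - rad - 1));
    const int jhi = std::min(W - 1, (int)std::ceil(std::max(c0, c1) + rad + 1));
    const double vr = r1 - r0, vc = c1 - c0;
    const double L2 = vr * vr + vc * vc;
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i) {
        double tt = L2 > 0 ? ((i - r0) * vr + (j - c0) * vc) / L2 : 0.0;
        tt = std::min(1.0, std::max(0.0, tt));
        const double dr = i - (r0 + tt * vr), dc = j - (c0 + tt * vc);
        if (dr * dr + dc * dc <= rad * rad) mask(i, j) = true;
      }
  }
  return mask;
}

// Minimum radius-normalised distance (d / radius) from each pixel to any
// segment centreline, capped at `cap`. Used to build the smooth vein
// intensity profile: depth = contrast * exp(-a * (d/radius)^2).
// [[Rcpp::export]]
NumericMatrix segment_distance_cpp(int H, int W, NumericMatrix seg, double cap) {
  NumericMatrix dist(H, W);
  std::fill(dist.begin(), dist.end(), cap);
  for (int s = 0; s < seg.nrow(); ++s) {
    const double r0 = seg(s, 0), c0 = seg(s, 1), r1 = seg(s, 2), c1 = seg(s, 3);
    const double rad = seg(s, 4), win = cap * rad;
    const int ilo = std::max(0, (int)std::floor(std::min(r0, r1) - win - 1));
    const int ihi = std::min(H - 1, (int)std::ceil(std::max(r0, r1) + win + 1));
    const int jlo = std::max(0, (int)std::floor(std::min(c0, c1) - win - 1));
    const int jhi = std::min(W - 1, (int)std::ceil(std::max(c0, c1) + win + 1));
    const double vr = r1 - r0, vc = c1 - c0;
    const double L2 = vr * vr + vc * vc;
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i) {
        double tt = L2 > 0 ? ((i - r0) * vr + (j - c0) * vc) / L2 : 0.0;
        tt = std::min(1.0, std::max(0.0, tt));
        const double dr = i - (r0 + tt * vr), dc = j - (c0 + tt * vc);
        const double d = std::sqrt(dr * dr + dc * dc) / rad;
        if (d < dist(i, j)) dist(i, j) = d;
      }
  }
  return dist;
}

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y(clone(x));
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector y, NumericVector gy) {
  NumericVector gx(clone(gy));
  for (R_xlen_t i = 0; i < gx.size(); ++i) if (y[i] <= 0) gx[i] = 0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Inverted dropout with a counter-based generator: one integer drawn from the
// R RNG stream seeds the whole mask, so results stay reproducible under
// set.seed while avoiding millions of R-level draws.
// [[Rcpp::export]]
List dropout_fw_cpp(NumericVector x, double rate, int seed) {
  NumericVector y(clone(x));
  LogicalVector keep(x.size());
  uint64_t s = (uint64_t)(uint32_t)seed * 0x2545F4914F6CDD1DULL + 1442695040888963407ULL;
  const double scale = 1.0 / (1.0 - rate);
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    const double u = (splitmix64(s) >> 11) * 0x1.0p-53;
    if (u < rate) { y[i] = 0; keep[i] = false; }
    else { y[i] *= scale; keep[i] = true; }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["keep"] = keep);
}

// [[Rcpp::export]]
NumericVector dropout_bw_cpp(NumericVector gy, LogicalVector keep, double rate) {
  NumericVector gx(clone(gy));
  const double scale = 1.0 / (1.0 - rate);
  for (R_xlen_t i = 0; i < gx.size(); ++i) gx[i] = keep[i] ? gx[i] * scale : 0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// ---- channel-wise helpers for batch normalisation over H x W x C x N ----

static inline void chan_dims(const NumericVector &x, R_xlen_t &hw, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  hw = (R_xlen_t)d[0] * d[1];
  C = d[2];
  N = d[3];
}

// [[Rcpp::export]]
List chan_moments_cpp(NumericVector x) {
  R_xlen_t hw; int C, N;
  chan_dims(x, hw, C, N);
  NumericVector mu(C), msq(C);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < hw; ++i, ++p) { s += *p; s2 += *p * *p; }
      mu[c] += s; msq[c] += s2;
    }
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) { mu[c] /= m; msq[c] /= m; }
  return List::create(_["mean"] = mu, _["meansq"] = msq);
}

// y = a[c] * x + b[c], optionally clamped at zero (fused ReLU)
// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector a, NumericVector b) {
  R_xlen_t hw; int C, N;
  chan_dims(x, hw, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *p = x.begin(); double *q = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double aa = a[c], bb = b[c];
      for (R_xlen_t i = 0; i < hw; ++i, ++p, ++q) *q = aa * *p + bb;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector chan_sum_cpp(NumericVector x) {
  R_xlen_t hw; int C, N;
  chan_dims(x, hw, C, N);
  NumericVector out(C);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (R_xlen_t i = 0; i < hw; ++i, ++p) s += *p;
      out[c] += s;
    }
  return out;
}

// per-channel sum of x * y
// [[Rcpp::export]]
NumericVector chan_dot_cpp(NumericVector x, NumericVector y) {
  R_xlen_t hw; int C, N;
  chan_dims(x, hw, C, N);
  NumericVector out(C);
  const double *p = x.begin(), *q = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (R_xlen_t i = 0; i < hw; ++i, ++p, ++q) s += *p * *q;
      out[c] += s;
    }
  return out;
}

// gx = (gxhat * m - s1[c] - xhat * s2[c]) * istd[c] / m
// [[Rcpp::export]]
NumericVector bn_bw_combine_cpp(NumericVector gxhat, NumericVector xhat,
                                NumericVector s1, NumericVector s2,
                                NumericVector istd) {
  R_xlen_t hw; int C, N;
  chan_dims(gxhat, hw, C, N);
  const double m = (double)hw * N;
  NumericVector gx(gxhat.size());
  gx.attr("dim") = gxhat.attr("dim");
  const double *pg = gxhat.begin(), *px = xhat.begin();
  double *q = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = s1[c], b = s2[c], f = istd[c] / m;
      for (R_xlen_t i = 0; i < hw; ++i, ++pg, ++px, ++q)
        *q = (*pg * m - a - *px * b) * f;
    }
  return gx;
}
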
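// Convolutional layer primitives (forward + backward) for the segmentation
// networks.  Feature maps are column-major (H*W) x C matrices; spatial index
// r = i + j*H with 0-based row i, column j.  Weights for a k x k convolution
// are (k*k*cin) x cout with row index c*k*k + kj*k + ki.  All arithmetic is
// single precision; the R interface converts from/to doubles at the boundary.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

typedef arma::fmat MT;

static MT dn(const arma::mat& m) { return arma::conv_to<MT>::from(m); }
static arma::mat up(const MT& m) { return arma::conv_to<arma::mat>::from(m); }

static void out_dims(int H, int W, int k, int stride, int dil,
                     int& pad, int& Ho, int& Wo) {
  pad = dil * (k - 1) / 2;           // 'same' padding for odd k
  Ho = (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  Wo = (W + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Patch matrix layout: (Ho*Wo) x (k*k*C); writes run down output rows so both
// source and destination access is sequential for stride 1.
static void im2col(const MT& xs, int H, int W, int k, int stride, int dil,
                   MT& col, int& Ho, int& Wo) {
  int C = xs.n_cols, pad;
  out_dims(H, W, k, stride, dil, pad, Ho, Wo);
  col.zeros((size_t)Ho * Wo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const float* xc = xs.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        float* cc = col.colptr((size_t)c * k * k + kj * k + ki);
        int di = ki * dil - pad, dj = kj * dil - pad;
        for (int oj = 0; oj < Wo; ++oj) {
          int ij = oj * stride + dj;
          if (ij < 0 || ij >= W) continue;
          const float* src = xc + (size_t)ij * H;
          float* dst = cc + (size_t)oj * Ho;
          int i0 = 0, i1 = Ho - 1;
          while (i0 <= i1 && i0 * stride + di < 0) ++i0;
          while (i1 >= i0 && i1 * stride + di >= H) --i1;
          if (i0 > i1) continue;
          if (stride == 1) {
            memcpy(dst + i0, src + i0 + di, (size_t)(i1 - i0 + 1) * sizeof(float));
          } else {
            for (int oi = i0; oi <= i1; ++oi) dst[oi] = src[oi * stride + di];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
static void col2im(const MT& dcol, int H, int W, int C, int k, int stride,
                   int dil, MT& dx) {
  int pad, Ho, Wo;
  out_dims(H, W, k, stride, dil, pad, Ho, Wo);
  dx.zeros((size_t)H * W, C);
  for (int c = 0; c < C; ++c) {
    float* xc = dx.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const float* cc = dcol.colptr((size_t)c * k * k + kj * k + ki);
        int di = ki * dil - pad, dj = kj * dil - pad;
        for (int oj = 0; oj < Wo; ++oj) {
          int ij = oj * stride + dj;
          if (ij < 0 || ij >= W) continue;
          float* dst = xc + (size_t)ij * H;
          const float* src = cc + (size_t)oj * Ho;
          int i0 = 0, i1 = Ho - 1;
          while (i0 <= i1 && i0 * stride + di < 0) ++i0;
          while (i1 >= i0 && i1 * stride + di >= H) --i1;
          for (int oi = i0; oi <= i1; ++oi) dst[oi * stride + di] += src[oi];
        }
      }
    }
  }
}

// Zero-pad a feature map by p pixels on each side.
static void pad_map(const MT& x, int H, int W, int p, MT& xp, int& Hp, int& Np) {
  int C = x.n_cols;
  Hp = H + 2 * p;
  int Wp = W + 2 * p;
  Np = Hp * Wp;
  xp.zeros(Np, C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* dst = xp.colptr(c);
    for (int j = 0; j < W; ++j)
      memcpy(dst + (size_t)(j + p) * Hp + p, src + (size_t)j * H,
             (size_t)H * sizeof(float));
  }
}

static void unpad_map(const MT& xp, int H, int W, int p, MT& x) {
  int C = xp.n_cols, Hp = H + 2 * p;
  x.set_size((size_t)H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* src = xp.colptr(c);
    float* dst = x.colptr(c);
    for (int j = 0; j < W; ++j)
      memcpy(dst + (size_t)j * H, src + (size_t)(j + p) * Hp + p,
             (size_t)H * sizeof(float));
  }
}

// A k=3, stride-1 'same' convolution as 9 shifted GEMMs on a padded buffer:
// in padded coordinates y[r] += x[r + di + dj*Hp] * W_(di,dj), so each tap
// is one GEMM over a contiguous row range.  Cheaper than im2col unless the
// dilation-driven padding dwarfs the map.
static bool use_shift(int H, int W, int k, int stride, int dil) {
  if (k != 3 || stride != 1) return false;
  double blow = (double)(H + 2 * dil) * (W + 2 * dil) / ((double)H * W);
  return blow <= 2.0;
}

// [[Rcpp::export]]
List nn_conv_fwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                 const arma::vec& b, int k, int stride, int dil) {
  MT x = dn(xs), wf = dn(w);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b);
  MT y;
  int Ho = H, Wo = W;
  if (k == 1 && stride == 1) {
    y = x * wf;
  } else if (use_shift(H, W, k, stride, dil)) {
    int C = x.n_cols, cout = wf.n_cols, p = dil, Hp, Np;
    MT xp;
    pad_map(x, H, W, p, xp, Hp, Np);
    MT yp(Np, cout, fill::zeros);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        int s = (ki - 1) * dil + (kj - 1) * dil * Hp;
        int a = std::max(0, -s), bnd = Np - 1 - std::max(0, s);
        // rows of wf for tap (ki,kj): c*9 + kj*3 + ki over channels
        MT wk(C, cout);
        for (int c = 0; c < C; ++c) wk.row(c) = wf.row(c * 9 + kj * 3 + ki);
        yp.rows(a, bnd) += xp.rows(a + s, bnd + s) * wk;
      }
    unpad_map(yp, H, W, p, y);
  } else {
    MT col;
    im2col(x, H, W, k, stride, dil, col, Ho, Wo);
    y = col * wf;
  }
  y.each_row() += bf;
  return List::create(Named("y") = up(y), Named("H") = Ho, Named("W") = Wo);
}

// [[Rcpp::export]]
List nn_conv_bwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                 const arma::mat& dy, int k, int stride, int dil) {
  MT x = dn(xs), wf = dn(w), g = dn(dy);
  MT dw, dx;
  if (k == 1 && stride == 1) {
    dw = x.t() * g;
    dx = g * wf.t();
  } else if (use_shift(H, W, k, stride, dil)) {
    int C = x.n_cols, cout = wf.n_cols, p = dil, Hp, Np;
    MT xp, gp;
    pad_map(x, H, W, p, xp, Hp, Np);
    pad_map(g, H, W, p, gp, Hp, Np);
    MT dxp(Np, C, fill::zeros);
    dw.set_size(wf.n_rows, cout);
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        int s = (ki - 1) * dil + (kj - 1) * dil * Hp;
        int a = std::max(0, -s), bnd = Np - 1 - std::max(0, s);
        MT wk(C, cout);
        for (int c = 0; c < C; ++c) wk.row(c) = wf.row(c * 9 + kj * 3 + ki);
        MT dwk = xp.rows(a + s, bnd + s).t() * gp.rows(a, bnd);
        for (int c = 0; c < C; ++c) dw.row(c * 9 + kj * 3 + ki) = dwk.row(c);
        dxp.rows(a + s, bnd + s) += gp.rows(a, bnd) * wk.t();
      }
    unpad_map(dxp, H, W, p, dx);
  } else {
    MT col;
    int Ho, Wo;
    im2col(x, H, W, k, stride, dil, col, Ho, Wo);
    dw = col.t() * g;
    MT dcol = g * wf.t();
    col2im(dcol, H, W, x.n_cols, k, stride, dil, dx);
  }
  arma::fvec db = arma::sum(g, 0).t();
  return List::create(Named("dx") = up(dx), Named("dw") = up(dw),
                      Named("db") = up(arma::fmat(db)));
}

// Depthwise k x k convolution, stride 1, 'same' padding: w is (k*k) x C,
// one kernel per channel.  Direct tap-wise accumulation (memory bound; no
// patch matrix is worth building for a single kernel per channel).
// [[Rcpp::export]]
List nn_dwconv_fwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                   const arma::vec& b, int k, int dil) {
  MT x = dn(xs), wf = dn(w);
  int C = x.n_cols, pad = dil * (k - 1) / 2;
  MT y((size_t)H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    float* yc = y.colptr(c);
    float bc = (float)b(c);
    for (size_t r = 0; r < (size_t)H * W; ++r) yc[r] = bc;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        float wv = wf(kj * k + ki, c);
        int di = ki * dil - pad, dj = kj * dil - pad;
        int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        if (j0 > j1 || i0 > i1) continue;
        for (int j = j0; j <= j1; ++j) {
          float* dst = yc + (size_t)j * H;
          const float* src = xc + (size_t)(j + dj) * H + di;
          for (int i = i0; i <= i1; ++i) dst[i] += wv * src[i];
        }
      }
  }
  return List::create(Named("y") = up(y), Named("H") = H, Named("W") = W);
}

// [[Rcpp::export]]
List nn_dwconv_bwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                   const arma::mat& dy, int k, int dil) {
  MT x = dn(xs), wf = dn(w), g = dn(dy);
  int C = x.n_cols, pad = dil * (k - 1) / 2;
  MT dw((size_t)k * k, C, fill::zeros), dx((size_t)H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    const float* gc = g.colptr(c);
    float* dxc = dx.colptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        float wv = wf(kj * k + ki, c);
        double acc = 0.0;
        int di = ki * dil - pad, dj = kj * dil - pad;
        int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        if (j0 > j1 || i0 > i1) { dw(kj * k + ki, c) = 0; continue; }
        for (int j = j0; j <= j1; ++j) {
          const float* gj = gc + (size_t)j * H;
          const float* xj = xc + (size_t)(j + dj) * H + di;
          float* dxj = dxc + (size_t)(j + dj) * H + di;
          for (int i = i0; i <= i1; ++i) {
            acc += (double)gj[i] * xj[i];
            dxj[i] += wv * gj[i];
          }
        }
        dw(kj * k + ki, c) = (float)acc;
      }
  }
  arma::fvec db = arma::sum(g, 0).t();
  return List::create(Named("dx") = up(dx), Named("dw") = up(dw),
                      Named("db") = up(arma::fmat(db)));
}

// 2x2 max pooling, stride 2; H and W must be even.  idx holds the 1-based
// within-channel linear index of each selected element.
// [[Rcpp::export]]
List nn_maxpool_fwd(const arma::mat& xs, int H, int W) {
  MT x = dn(xs);
  int C = x.n_cols, Ho = H / 2, Wo = W / 2;
  MT y((size_t)Ho * Wo, C);
  arma::imat idx((size_t)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    float* yc = y.colptr(c);
    arma::sword* ic = idx.colptr(c);
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        int i = 2 * oi, j = 2 * oj;
        size_t p00 = (size_t)j * H + i;
        size_t cand[4] = { p00, p00 + 1, p00 + H, p00 + H + 1 };
        size_t best = cand[0];
        for (int q = 1; q < 4; ++q) if (xc[cand[q]] > xc[best]) best = cand[q];
        yc[(size_t)oj * Ho + oi] = xc[best];
        ic[(size_t)oj * Ho + oi] = (arma::sword)best + 1;
      }
    }
  }
  return List::create(Named("y") = up(y), Named("idx") = idx,
                      Named("H") = Ho, Named("W") = Wo);
}

// [[Rcpp::export]]
arma::mat nn_maxpool_bwd(const arma::mat& dy, const arma::imat& idx,
                         int H, int W) {
  MT g = dn(dy);
  int C = g.n_cols;
  MT dx((size_t)H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* gc = g.colptr(c);
    const arma::sword* ic = idx.colptr(c);
    float* xc = dx.colptr(c);
    for (size_t r = 0; r < g.n_rows; ++r) xc[ic[r] - 1] += gc[r];
  }
  return up(dx);
}

// Transposed 2x2 convolution with stride 2 ("up-convolution"): every input
// pixel paints a disjoint 2x2 output block.  w is cin x (4*cout), the four
// column blocks ordered (di,dj) = (0,0),(1,0),(0,1),(1,1).
// [[Rcpp::export]]
List nn_convt_fwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                  const arma::vec& b) {
  MT x = dn(xs), wf = dn(w);
  int cout = wf.n_cols / 4, H2 = 2 * H, W2 = 2 * W;
  MT y((size_t)H2 * W2, cout);
  for (int dd = 0; dd < 4; ++dd) {
    int di = dd % 2, dj = dd / 2;
    MT t = x * wf.cols((size_t)dd * cout, (size_t)dd * cout + cout - 1);
    for (int c = 0; c < cout; ++c) {
      const float* tc = t.colptr(c);
      float* yc = y.colptr(c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          yc[(size_t)(2 * j + dj) * H2 + 2 * i + di] = tc[(size_t)j * H + i];
    }
  }
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b);
  y.each_row() += bf;
  return List::create(Named("y") = up(y), Named("H") = H2, Named("W") = W2);
}

// [[Rcpp::export]]
List nn_convt_bwd(const arma::mat& xs, int H, int W, const arma::mat& w,
                  const arma::mat& dy) {
  MT x = dn(xs), wf = dn(w), g = dn(dy);
  int cout = wf.n_cols / 4, H2 = 2 * H;
  MT dw(x.n_cols, (size_t)4 * cout), dx((size_t)H * W, x.n_cols, fill::zeros);
  MT sub((size_t)H * W, cout);
  for (int dd = 0; dd < 4; ++dd) {
    int di = dd % 2, dj = dd / 2;
    for (int c = 0; c < cout; ++c) {
      const float* gc = g.colptr(c);
      float* sc = sub.colptr(c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          sc[(size_t)j * H + i] = gc[(size_t)(2 * j + dj) * H2 + 2 * i + di];
    }
    dw.cols((size_t)dd * cout, (size_t)dd * cout + cout - 1) = x.t() * sub;
    dx += sub * wf.cols((size_t)dd * cout, (size_t)dd * cout + cout - 1).t();
  }
  arma::fvec db = arma::sum(g, 0).t();
  return List::create(Named("dx") = up(dx), Named("dw") = up(dw),
                      Named("db") = up(arma::fmat(db)));
}

// Nearest-neighbour upsampling to (th, tw); source pixel floor(o*S/T).
// [[Rcpp::export]]
arma::mat nn_upsample_fwd(const arma::mat& xs, int H, int W, int th, int tw) {
  MT x = dn(xs);
  int C = x.n_cols;
  MT y((size_t)th * tw, C);
  std::vector<int> mi(th), mj(tw);
  for (int i = 0; i < th; ++i) mi[i] = std::min((int)((long long)i * H / th), H - 1);
  for (int j = 0; j < tw; ++j) mj[j] = std::min((int)((long long)j * W / tw), W - 1);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.colptr(c);
    float* yc = y.colptr(c);
    for (int j = 0; j < tw; ++j) {
      const float* src = xc + (size_t)mj[j] * H;
      float* dst = yc + (size_t)j * th;
      for (int i = 0; i < th; ++i) dst[i] = src[mi[i]];
    }
  }
  return up(y);
}

// [[Rcpp::export]]
arma::mat nn_upsample_bwd(const arma::mat& dy, int H, int W, int th, int tw) {
  MT g = dn(dy);
  int C = g.n_cols;
  MT dx((size_t)H * W, C, fill::zeros);
  std::vector<int> mi(th), mj(tw);
  for (int i = 0; i < th; ++i) mi[i] = std::min((int)((long long)i * H / th), H - 1);
  for (int j = 0; j < tw; ++j) mj[j] = std::min((int)((long long)j * W / tw), W - 1);
  for (int c = 0; c < C; ++c) {
    const float* gc = g.colptr(c);
    float* xc = dx.colptr(c);
    for (int j = 0; j < tw; ++j) {
      float* dst = xc + (size_t)mj[j] * H;
      const float* src = gc + (size_t)j * th;
      for (int i = 0; i < th; ++i) dst[mi[i]] += src[i];
    }
  }
  return up(dx);
}
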
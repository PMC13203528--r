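// Numerical kernels for the four-branch depthwise-separable / TCN classifier.
// Activations are arma::cube with layout (channels x time x batch).
// Forward and backward for one training step run in a single call so the
// layer caches never cross the R/C++ boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;

static mat getM(const List& p, const char* nm) { return as<mat>(p[nm]); }
static vec getV(const List& p, const char* nm) { return as<vec>(p[nm]); }

// ---------------- depthwise temporal convolution (no bias) ----------------

static cube dw_fwd(const cube& x, const mat& W, int d, int pl, int pr) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices, k = W.n_cols;
  const int Tp = T + pl + pr;
  cube xp(C, Tp, B, arma::fill::zeros);
  xp.cols(pl, pl + T - 1) = x;
  cube y(C, T, B, arma::fill::zeros);
  const double* xpm = xp.memptr();
  const double* wm = W.memptr();
  double* ym = y.memptr();
  for (int b = 0; b < B; ++b) {
    const double* xb = xpm + (size_t)b * C * Tp;
    double* yb = ym + (size_t)b * C * T;
    for (int j = 0; j < k; ++j) {
      const double* wj = wm + (size_t)j * C;
      const double* xs = xb + (size_t)j * d * C;
      for (int t = 0; t < T; ++t) {
        const double* xc = xs + (size_t)t * C;
        double* yc = yb + (size_t)t * C;
        for (int c = 0; c < C; ++c) yc[c] += wj[c] * xc[c];
      }
    }
  }
  return y;
}

static void dw_bwd(const cube& x, const mat& W, int d, int pl, int pr,
                   const cube& dy, cube& dx, mat& dW) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices, k = W.n_cols;
  const int Tp = T + pl + pr;
  cube xp(C, Tp, B, arma::fill::zeros);
  xp.cols(pl, pl + T - 1) = x;
  cube dxp(C, Tp, B, arma::fill::zeros);
  dW.zeros(C, k);
  const double* xpm = xp.memptr();
  const double* wm = W.memptr();
  const double* dym = dy.memptr();
  double* dxpm = dxp.memptr();
  double* dwm = dW.memptr();
  for (int b = 0; b < B; ++b) {
    const double* xb = xpm + (size_t)b * C * Tp;
    const double* dyb = dym + (size_t)b * C * T;
    double* dxb = dxpm + (size_t)b * C * Tp;
    for (int j = 0; j < k; ++j) {
      const double* wj = wm + (size_t)j * C;
      const double* xs = xb + (size_t)j * d * C;
      double* dxs = dxb + (size_t)j * d * C;
      double* dwj = dwm + (size_t)j * C;
      for (int t = 0; t < T; ++t) {
        const double* xc = xs + (size_t)t * C;
        const double* dyc = dyb + (size_t)t * C;
        double* dxc = dxs + (size_t)t * C;
        for (int c = 0; c < C; ++c) {
          dwj[c] += dyc[c] * xc[c];
          dxc[c] += wj[c] * dyc[c];
        }
      }
    }
  }
  dx = dxp.cols(pl, pl + T - 1);
}

// ---------------- pointwise (1x1) convolution (no bias) ----------------

// the (C, T, B) cube is contiguous column-major, so it aliases a C x (T*B)
// matrix without copying; pointwise convolution is then a single GEMM
static mat flat_alias(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows,
             (size_t)x.n_cols * x.n_slices, false, true);
}

static cube pw_fwd(const cube& x, const mat& W) {
  cube y(W.n_rows, x.n_cols, x.n_slices);
  mat ya = flat_alias(y);
  ya = W * flat_alias(x);
  return y;
}

static void pw_bwd(const cube& x, const mat& W, const cube& dy, cube& dx, mat& dW) {
  mat xa = flat_alias(x), dya = flat_alias(dy);
  dW = dya * xa.t();
  dx.set_size(x.n_rows, x.n_cols, x.n_slices);
  mat dxa = flat_alias(dx);
  dxa = W.t() * dya;
}

// ---------------- batch normalization over (time, batch) ----------------

struct BNCache { cube xhat; vec invstd; };

static cube bn_fwd(const cube& x, const vec& g, const vec& bb,
                   vec& rm, vec& rv, bool train, double momentum, BNCache& cc) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const double N = double(T) * double(B);
  mat xa = flat_alias(x);
  vec m(C), v(C);
  if (train) {
    m = arma::mean(xa, 1);
    v = arma::mean(arma::square(xa), 1) - arma::square(m);
    v.transform([](double u) { return u > 0 ? u : 0.0; });
    double corr = N > 1.5 ? N / (N - 1.0) : 1.0;
    rm = (1.0 - momentum) * rm + momentum * m;
    rv = (1.0 - momentum) * rv + momentum * v * corr;
  } else {
    m = rm; v = rv;
  }
  vec invstd = 1.0 / arma::sqrt(v + BN_EPS);
  cube xhat(C, T, B), y(C, T, B);
  mat xha = flat_alias(xhat), ya = flat_alias(y);
  xha = xa;
  xha.each_col() -= m;
  xha.each_col() %= invstd;
  ya = xha;
  ya.each_col() %= g;
  ya.each_col() += bb;
  cc.xhat = xhat; cc.invstd = invstd;
  return y;
}

static void bn_bwd(const cube& dy, const vec& g, const BNCache& cc,
                   cube& dx, vec& dg, vec& db) {
  const int C = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
  const double N = double(T) * double(B);
  mat dya = flat_alias(dy), xha = flat_alias(cc.xhat);
  dg = arma::sum(dya % xha, 1);
  db = arma::sum(dya, 1);
  vec s1 = db % g;  // sum of dxhat per channel
  vec s2 = dg % g;  // sum of dxhat*xhat per channel
  dx.set_size(C, T, B);
  mat dxa = flat_alias(dx);
  dxa = dya;
  dxa.each_col() %= g;
  dxa.each_col() -= s1 / N;
  mat t2 = xha;
  t2.each_col() %= (s2 / N);
  dxa -= t2;
  dxa.each_col() %= cc.invstd;
}

// ---------------- SiLU ----------------

static cube silu_fwd(const cube& x, cube& s) {
  s = 1.0 / (1.0 + arma::exp(-x));
  return x % s;
}

static cube silu_bwd(const cube& x, const cube& s, const cube& dy) {
  return dy % (s % (1.0 + x % (1.0 - s)));
}

static mat silu_fwd_m(const mat& x) { return x % (1.0 / (1.0 + arma::exp(-x))); }

static mat silu_bwd_m(const mat& x, const mat& dy) {
  mat s = 1.0 / (1.0 + arma::exp(-x));
  return dy % (s % (1.0 + x % (1.0 - s)));
}

// ---------------- squeeze-and-excitation ----------------

struct SECache { cube x; mat z, h, s; };

static cube se_fwd(const cube& x, const mat& W1, const vec& b1,
                   const mat& W2, const vec& b2, SECache& cc) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  mat z(C, B);
  const double* xm = x.memptr();
  for (int b = 0; b < B; ++b) {
    double* zc = z.colptr(b);
    const double* xb = xm + (size_t)b * C * T;
    for (int c = 0; c < C; ++c) zc[c] = 0.0;
    for (int t = 0; t < T; ++t) {
      const double* xc = xb + (size_t)t * C;
      for (int c = 0; c < C; ++c) zc[c] += xc[c];
    }
    for (int c = 0; c < C; ++c) zc[c] /= double(T);
  }
  mat h = W1 * z;
  h.each_col() += b1;
  h.elem(arma::find(h < 0)).zeros();        // ReLU
  mat s = W2 * h;
  s.each_col() += b2;
  s = 1.0 / (1.0 + arma::exp(-s));          // sigmoid
  cube y(C, T, B);
  double* ym = y.memptr();
  const double* sm = s.memptr();
  for (int b = 0; b < B; ++b) {
    const double* sc = sm + (size_t)b * C;
    const double* xb = xm + (size_t)b * C * T;
    double* yb = ym + (size_t)b * C * T;
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c)
        yb[(size_t)t * C + c] = xb[(size_t)t * C + c] * sc[c];
  }
  cc.x = x; cc.z = z; cc.h = h; cc.s = s;
  return y;
}

static void se_bwd(const cube& dy, const mat& W1, const mat& W2, const SECache& cc,
                   cube& dx, mat& dW1, vec& db1, mat& dW2, vec& db2) {
  const int C = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
  dx.set_size(C, T, B);
  mat ds(C, B, arma::fill::zeros);
  const double* dym = dy.memptr();
  const double* xm = cc.x.memptr();
  const double* sm = cc.s.memptr();
  double* dxm = dx.memptr();
  for (int b = 0; b < B; ++b) {
    const double* sc = sm + (size_t)b * C;
    const double* dyb = dym + (size_t)b * C * T;
    const double* xb = xm + (size_t)b * C * T;
    double* dxb = dxm + (size_t)b * C * T;
    double* dsc = ds.colptr(b);
    for (int t = 0; t < T; ++t) {
      const size_t off = (size_t)t * C;
      for (int c = 0; c < C; ++c) {
        dxb[off + c] = dyb[off + c] * sc[c];
        dsc[c] += dyb[off + c] * xb[off + c];
      }
    }
  }
  mat dspre = ds % cc.s % (1.0 - cc.s);
  dW2 = dspre * cc.h.t();
  db2 = arma::sum(dspre, 1);
  mat dh = W2.t() * dspre;
  dh.elem(arma::find(cc.h <= 0)).zeros();
  dW1 = dh * cc.z.t();
  db1 = arma::sum(dh, 1);
  mat dz = W1.t() * dh;
  for (int b = 0; b < B; ++b) {
    const double* dzc = dz.colptr(b);
    double* dxb = dxm + (size_t)b * C * T;
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c)
        dxb[(size_t)t * C + c] += dzc[c] / double(T);
  }
}

// ---------------- max pooling (kernel 2, stride 2, floor) ----------------

static cube pool_fwd(const cube& x, cube& mask) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices, To = T / 2;
  cube y(C, To, B);
  mask.set_size(C, To, B);
  const double* xm = x.memptr();
  double* ym = y.memptr();
  double* mm = mask.memptr();
  for (int b = 0; b < B; ++b) {
    const double* xb = xm + (size_t)b * C * T;
    double* yb = ym + (size_t)b * C * To;
    double* mb = mm + (size_t)b * C * To;
    for (int t = 0; t < To; ++t) {
      const double* xa = xb + (size_t)(2 * t) * C;
      const double* xc = xa + C;
      for (int c = 0; c < C; ++c) {
        const bool second = xc[c] > xa[c];
        yb[(size_t)t * C + c] = second ? xc[c] : xa[c];
        mb[(size_t)t * C + c] = second ? 1.0 : 0.0;
      }
    }
  }
  return y;
}

static cube pool_bwd(const cube& dy, const cube& mask, int T_in) {
  const int C = dy.n_rows, To = dy.n_cols, B = dy.n_slices;
  cube dx(C, T_in, B, arma::fill::zeros);
  const double* dym = dy.memptr();
  const double* mm = mask.memptr();
  double* dxm = dx.memptr();
  for (int b = 0; b < B; ++b) {
    const double* dyb = dym + (size_t)b * C * To;
    const double* mb = mm + (size_t)b * C * To;
    double* dxb = dxm + (size_t)b * C * T_in;
    for (int t = 0; t < To; ++t) {
      for (int c = 0; c < C; ++c) {
        const double g = dyb[(size_t)t * C + c];
        if (mb[(size_t)t * C + c] > 0.5) dxb[(size_t)(2 * t + 1) * C + c] += g;
        else dxb[(size_t)(2 * t) * C + c] += g;
      }
    }
  }
  return dx;
}

// ---------------- dropout (inverted, R RNG for determinism) ----------------

static cube drop_fwd(const cube& x, double p, bool train, cube& mask) {
  if (!train || p <= 0.0) { mask.reset(); return x; }
  const double keep = 1.0 - p;
  mask.set_size(arma::size(x));
  for (arma::uword i = 0; i < mask.n_elem; ++i)
    mask(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return x % mask;
}

static cube drop_bwd(const cube& dy, const cube& mask) {
  if (mask.n_elem == 0) return dy;
  return dy % mask;
}

// ---------------- group normalization (per sample, per group) ----------------

struct GNCache { cube xhat; mat invstd; };

static cube gn_fwd(const cube& x, const vec& g, const vec& bb, int G, GNCache& cc) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices, cg = C / G;
  const double N = double(cg) * double(T);
  cube xhat(C, T, B), y(C, T, B);
  cc.invstd.set_size(G, B);
  for (int b = 0; b < B; ++b) {
    for (int gi = 0; gi < G; ++gi) {
      int r0 = gi * cg, r1 = (gi + 1) * cg - 1;
      mat sub = x.slice(b).rows(r0, r1);
      double m = arma::accu(sub) / N;
      double v = arma::accu(arma::square(sub - m)) / N;
      double is = 1.0 / std::sqrt(v + BN_EPS);
      xhat.slice(b).rows(r0, r1) = (sub - m) * is;
      cc.invstd(gi, b) = is;
    }
    mat t1 = xhat.slice(b);
    t1.each_col() %= g;
    t1.each_col() += bb;
    y.slice(b) = t1;
  }
  cc.xhat = xhat;
  return y;
}

static void gn_bwd(const cube& dy, const vec& g, int G, const GNCache& cc,
                   cube& dx, vec& dg, vec& db) {
  const int C = dy.n_rows, T = dy.n_cols, B = dy.n_slices, cg = C / G;
  const double N = double(cg) * double(T);
  dg.zeros(C); db.zeros(C);
  dx.set_size(C, T, B);
  for (int b = 0; b < B; ++b) {
    dg += arma::sum(dy.slice(b) % cc.xhat.slice(b), 1);
    db += arma::sum(dy.slice(b), 1);
    for (int gi = 0; gi < G; ++gi) {
      int r0 = gi * cg, r1 = (gi + 1) * cg - 1;
      mat dxhat = dy.slice(b).rows(r0, r1);
      dxhat.each_col() %= g.subvec(r0, r1);
      mat xh = cc.xhat.slice(b).rows(r0, r1);
      double s1 = arma::accu(dxhat), s2 = arma::accu(dxhat % xh);
      dx.slice(b).rows(r0, r1) =
        cc.invstd(gi, b) * (dxhat - s1 / N - xh * (s2 / N));
    }
  }
}

// ---------------- DS-SE block ----------------

struct DSSECache {
  cube x, adw;        // conv inputs
  BNCache bn;
  cube silu_in, silu_s;
  SECache se;
  bool has_bias;
};

static cube dsse_fwd(const List& p, List& st, const std::string& pre, const cube& x,
                     bool train, double momentum, DSSECache& cc) {
  mat Wdw = getM(p, (pre + "_dw").c_str());
  mat Wpw = getM(p, (pre + "_pw").c_str());
  int k = Wdw.n_cols, pad = (k - 1) / 2;
  cc.x = x;
  cc.adw = dw_fwd(x, Wdw, 1, pad, pad);
  cube a = pw_fwd(cc.adw, Wpw);
  vec rm = getV(st, (pre + "_rm").c_str());
  vec rv = getV(st, (pre + "_rv").c_str());
  cube b = bn_fwd(a, getV(p, (pre + "_bng").c_str()), getV(p, (pre + "_bnb").c_str()),
                  rm, rv, train, momentum, cc.bn);
  if (train) { st[pre + "_rm"] = rm; st[pre + "_rv"] = rv; }
  cc.silu_in = b;
  cube c = silu_fwd(b, cc.silu_s);
  cc.has_bias = p.containsElementNamed((pre + "_se_b1").c_str());
  mat W1 = getM(p, (pre + "_se_W1").c_str());
  mat W2 = getM(p, (pre + "_se_W2").c_str());
  vec b1 = cc.has_bias ? getV(p, (pre + "_se_b1").c_str()) : vec(W1.n_rows, arma::fill::zeros);
  vec b2 = cc.has_bias ? getV(p, (pre + "_se_b2").c_str()) : vec(W2.n_rows, arma::fill::zeros);
  return se_fwd(c, W1, b1, W2, b2, cc.se);
}

static cube dsse_bwd(const List& p, const std::string& pre, const DSSECache& cc,
                     const cube& dy, List& grads) {
  mat W1 = getM(p, (pre + "_se_W1").c_str());
  mat W2 = getM(p, (pre + "_se_W2").c_str());
  cube dc; mat dW1, dW2; vec db1, db2;
  se_bwd(dy, W1, W2, cc.se, dc, dW1, db1, dW2, db2);
  grads[pre + "_se_W1"] = dW1;
  grads[pre + "_se_W2"] = dW2;
  if (cc.has_bias) { grads[pre + "_se_b1"] = db1; grads[pre + "_se_b2"] = db2; }
  cube db_cube = silu_bwd(cc.silu_in, cc.silu_s, dc);
  cube da; vec dg, dbb;
  bn_bwd(db_cube, getV(p, (pre + "_bng").c_str()), cc.bn, da, dg, dbb);
  grads[pre + "_bng"] = dg;
  grads[pre + "_bnb"] = dbb;
  mat Wpw = getM(p, (pre + "_pw").c_str());
  cube dadw; mat dWpw;
  pw_bwd(cc.adw, Wpw, da, dadw, dWpw);
  grads[pre + "_pw"] = dWpw;
  mat Wdw = getM(p, (pre + "_dw").c_str());
  int k = Wdw.n_cols, pad = (k - 1) / 2;
  cube dx; mat dWdw;
  dw_bwd(cc.x, Wdw, 1, pad, pad, dadw, dx, dWdw);
  grads[pre + "_dw"] = dWdw;
  return dx;
}

// ---------------- lightweight temporal block (two causal DS convs) ----------------

struct LTBCache {
  cube y0;
  cube c1in, c1dw; BNCache bn1; cube silu1_in, silu1_s, mask1, o1;
  cube c2in, c2dw; BNCache bn2; cube silu2_in, silu2_s, mask2;
  cube pre, pre_s;
};

static cube ltb_fwd(const List& p, List& st, const std::string& pre, const cube& y0,
                    int d, bool train, double p_drop, double momentum, LTBCache& cc) {
  cc.y0 = y0;
  mat Wdw1 = getM(p, (pre + "_dw1").c_str());
  int k = Wdw1.n_cols, pl = (k - 1) * d;
  cc.c1in = y0;
  cc.c1dw = dw_fwd(y0, Wdw1, d, pl, 0);
  cube a = pw_fwd(cc.c1dw, getM(p, (pre + "_pw1").c_str()));
  vec rm1 = getV(st, (pre + "_bn1_rm").c_str());
  vec rv1 = getV(st, (pre + "_bn1_rv").c_str());
  cube b = bn_fwd(a, getV(p, (pre + "_bn1g").c_str()), getV(p, (pre + "_bn1b").c_str()),
                  rm1, rv1, train, momentum, cc.bn1);
  if (train) { st[pre + "_bn1_rm"] = rm1; st[pre + "_bn1_rv"] = rv1; }
  cc.silu1_in = b;
  cube c = silu_fwd(b, cc.silu1_s);
  cc.o1 = drop_fwd(c, p_drop, train, cc.mask1);

  mat Wdw2 = getM(p, (pre + "_dw2").c_str());
  cc.c2in = cc.o1;
  cc.c2dw = dw_fwd(cc.o1, Wdw2, d, pl, 0);
  cube a2 = pw_fwd(cc.c2dw, getM(p, (pre + "_pw2").c_str()));
  vec rm2 = getV(st, (pre + "_bn2_rm").c_str());
  vec rv2 = getV(st, (pre + "_bn2_rv").c_str());
  cube b2 = bn_fwd(a2, getV(p, (pre + "_bn2g").c_str()), getV(p, (pre + "_bn2b").c_str()),
                   rm2, rv2, train, momentum, cc.bn2);
  if (train) { st[pre + "_bn2_rm"] = rm2; st[pre + "_bn2_rv"] = rv2; }
  cc.silu2_in = b2;
  cube c2 = silu_fwd(b2, cc.silu2_s);
  cube o2 = drop_fwd(c2, p_drop, train, cc.mask2);

  cc.pre = o2 + y0;           // identity residual (channels match by construction)
  return silu_fwd(cc.pre, cc.pre_s);
}

static cube ltb_bwd(const List& p, const std::string& pre, int d, const LTBCache& cc,
                    const cube& dy, List& grads) {
  cube dpre = silu_bwd(cc.pre, cc.pre_s, dy);
  // residual: gradient flows to both o2 path and y0
  cube do2 = dpre;
  cube dc2 = drop_bwd(do2, cc.mask2);
  cube db2 = silu_bwd(cc.silu2_in, cc.silu2_s, dc2);
  cube da2; vec dg2, dbb2;
  bn_bwd(db2, getV(p, (pre + "_bn2g").c_str()), cc.bn2, da2, dg2, dbb2);
  grads[pre + "_bn2g"] = dg2;
  grads[pre + "_bn2b"] = dbb2;
  cube dc2dw; mat dWpw2;
  pw_bwd(cc.c2dw, getM(p, (pre + "_pw2").c_str()), da2, dc2dw, dWpw2);
  grads[pre + "_pw2"] = dWpw2;
  mat Wdw2 = getM(p, (pre + "_dw2").c_str());
  int k = Wdw2.n_cols, pl = (k - 1) * d;
  cube do1; mat dWdw2;
  dw_bwd(cc.c2in, Wdw2, d, pl, 0, dc2dw, do1, dWdw2);
  grads[pre + "_dw2"] = dWdw2;

  cube dc1 = drop_bwd(do1, cc.mask1);
  cube db1 = silu_bwd(cc.silu1_in, cc.silu1_s, dc1);
  cube da1; vec dg1, dbb1;
  bn_bwd(db1, getV(p, (pre + "_bn1g").c_str()), cc.bn1, da1, dg1, dbb1);
  grads[pre + "_bn1g"] = dg1;
  grads[pre + "_bn1b"] = dbb1;
  cube dc1dw; mat dWpw1;
  pw_bwd(cc.c1dw, getM(p, (pre + "_pw1").c_str()), da1, dc1dw, dWpw1);
  grads[pre + "_pw1"] = dWpw1;
  mat Wdw1 = getM(p, (pre + "_dw1").c_str());
  cube dy0; mat dWdw1;
  dw_bwd(cc.c1in, Wdw1, d, pl, 0, dc1dw, dy0, dWdw1);
  grads[pre + "_dw1"] = dWdw1;

  return dy0 + dpre;  // conv path + residual path
}

// ---------------- full branch ----------------

struct BranchCache {
  DSSECache d1, d2;
  cube pool_mask;
  int pool_Tin;
  cube h1, pooled, h2;
  LTBCache l1, l2;
  cube tcn_out;
  GNCache gn;
  cube gn_out;
  int T2;
};

static mat branch_fwd(const List& p, List& st, const cube& x, bool train,
                      double p_drop, int gn_groups, double momentum, BranchCache& cc) {
  cc.h1 = dsse_fwd(p, st, "d1", x, train, momentum, cc.d1);
  cc.pool_Tin = cc.h1.n_cols;
  cc.pooled = pool_fwd(cc.h1, cc.pool_mask);
  cc.h2 = dsse_fwd(p, st, "d2", cc.pooled, train, momentum, cc.d2);
  cube t1 = ltb_fwd(p, st, "l1", cc.h2, 1, train, p_drop, momentum, cc.l1);
  cc.tcn_out = ltb_fwd(p, st, "l2", t1, 2, train, p_drop, momentum, cc.l2);
  cc.gn_out = gn_fwd(cc.tcn_out, getV(p, "gn_g"), getV(p, "gn_b"), gn_groups, cc.gn);
  cc.T2 = cc.gn_out.n_cols;
  const int C = cc.gn_out.n_rows, B = cc.gn_out.n_slices;
  mat f(C, B);
  for (int b = 0; b < B; ++b) f.col(b) = arma::mean(cc.gn_out.slice(b), 1);
  return f;
}

static void branch_bwd(const List& p, const BranchCache& cc, const mat& df,
                       int gn_groups, List& grads) {
  const int C = df.n_rows, B = df.n_cols, T = cc.T2;
  cube dgn(C, T, B);
  for (int b = 0; b < B; ++b) {
    mat add(C, T);
    add.each_col() = df.col(b) / double(T);
    dgn.slice(b) = add;
  }
  cube dtcn; vec dgg, dgb;
  gn_bwd(dgn, getV(p, "gn_g"), gn_groups, cc.gn, dtcn, dgg, dgb);
  grads["gn_g"] = dgg;
  grads["gn_b"] = dgb;
  cube dt1 = ltb_bwd(p, "l2", 2, cc.l2, dtcn, grads);
  cube dh2 = ltb_bwd(p, "l1", 1, cc.l1, dt1, grads);
  cube dpooled = dsse_bwd(p, "d2", cc.d2, dh2, grads);
  cube dh1 = pool_bwd(dpooled, cc.pool_mask, cc.pool_Tin);
  dsse_bwd(p, "d1", cc.d1, dh1, grads);  // input gradient discarded
}

// ---------------- classifier head ----------------

struct HeadCache {
  mat f, z1;
  mat bn_xhat; vec bn_invstd;
  mat silu_in, mask, h;
};

static mat bnm_fwd(const mat& x, const vec& g, const vec& bb, vec& rm, vec& rv,
                   bool train, double momentum, mat& xhat, vec& invstd) {
  const int B = x.n_cols;
  const double N = double(B);
  vec m, v;
  if (train) {
    m = arma::mean(x, 1);
    mat cen = x; cen.each_col() -= m;
    v = arma::sum(arma::square(cen), 1) / N;
    double corr = N > 1.5 ? N / (N - 1.0) : 1.0;
    rm = (1.0 - momentum) * rm + momentum * m;
    rv = (1.0 - momentum) * rv + momentum * v * corr;
  } else { m = rm; v = rv; }
  invstd = 1.0 / arma::sqrt(v + BN_EPS);
  xhat = x;
  xhat.each_col() -= m;
  xhat.each_col() %= invstd;
  mat y = xhat;
  y.each_col() %= g;
  y.each_col() += bb;
  return y;
}

static void bnm_bwd(const mat& dy, const vec& g, const mat& xhat, const vec& invstd,
                    mat& dx, vec& dg, vec& db) {
  const double N = double(dy.n_cols);
  dg = arma::sum(dy % xhat, 1);
  db = arma::sum(dy, 1);
  vec s1 = db % g, s2 = dg % g;
  dx = dy;
  dx.each_col() %= g;
  dx.each_col() -= s1 / N;
  mat t2 = xhat;
  t2.each_col() %= (s2 / N);
  dx -= t2;
  dx.each_col() %= invstd;
}

static mat head_fwd(const List& hp, List& hst, const mat& f, bool train,
                    double p_fc, double momentum, HeadCache& cc) {
  cc.f = f;
  mat z1 = getM(hp, "fc1_W") * f;
  z1.each_col() += getV(hp, "fc1_b");
  cc.z1 = z1;
  vec rm = getV(hst, "bn_rm"), rv = getV(hst, "bn_rv");
  mat zb = bnm_fwd(z1, getV(hp, "bn_g"), getV(hp, "bn_b"), rm, rv, train, momentum,
                   cc.bn_xhat, cc.bn_invstd);
  if (train) { hst["bn_rm"] = rm; hst["bn_rv"] = rv; }
  cc.silu_in = zb;
  mat h = silu_fwd_m(zb);
  if (train && p_fc > 0) {
    const double keep = 1.0 - p_fc;
    cc.mask.set_size(arma::size(h));
    for (arma::uword i = 0; i < cc.mask.n_elem; ++i)
      cc.mask(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    h %= cc.mask;
  } else cc.mask.reset();
  cc.h = h;
  mat logits = getM(hp, "fc2_W") * h;
  logits.each_col() += getV(hp, "fc2_b");
  return logits;
}

static mat head_bwd(const List& hp, const HeadCache& cc, const mat& dlogits, List& grads) {
  grads["fc2_W"] = mat(dlogits * cc.h.t());
  grads["fc2_b"] = vec(arma::sum(dlogits, 1));
  mat dh = getM(hp, "fc2_W").t() * dlogits;
  if (cc.mask.n_elem > 0) dh %= cc.mask;
  mat dzb = silu_bwd_m(cc.silu_in, dh);
  mat dz1; vec dg, db;
  bnm_bwd(dzb, getV(hp, "bn_g"), cc.bn_xhat, cc.bn_invstd, dz1, dg, db);
  grads["bn_g"] = dg;
  grads["bn_b"] = db;
  grads["fc1_W"] = mat(dz1 * cc.f.t());
  grads["fc1_b"] = vec(arma::sum(dz1, 1));
  return getM(hp, "fc1_W").t() * dz1;
}

static mat softmax_cols(const mat& logits) {
  mat p = logits;
  for (arma::uword b = 0; b < p.n_cols; ++b) {
    vec c = p.col(b);
    c -= c.max();
    c = arma::exp(c);
    p.col(b) = c / arma::accu(c);
  }
  return p;
}

// ---------------- exported entry points ----------------

// One full training step: forward, loss, backward. Returns loss, gradients
// (mirroring the trainable parameter lists), updated normalization state and
// the fall probabilities of the batch.
// [[Rcpp::export]]
List cpp_fallnet_loss_grad(List params, List state, List xs, IntegerVector y,
                           NumericVector class_w, double smoothing,
                           double p_tcn, double p_fc, int gn_groups,
                           double momentum) {
  List bparams = params["branches"], hparams = params["head"];
  List bstate = clone(as<List>(state["branches"]));
  List hstate = clone(as<List>(state["head"]));
  const int nb = bparams.size();
  const int B = y.size();

  std::vector<BranchCache> caches(nb);
  mat f;
  for (int i = 0; i < nb; ++i) {
    List bp = bparams[i];
    List bs = bstate[i];
    cube x = as<cube>(xs[i]);
    mat fi = branch_fwd(bp, bs, x, true, p_tcn, gn_groups, momentum, caches[i]);
    bstate[i] = bs;
    f = (i == 0) ? fi : arma::join_cols(f, fi);
  }
  HeadCache hc;
  mat logits = head_fwd(hparams, hstate, f, true, p_fc, momentum, hc);
  mat p = softmax_cols(logits);

  double loss = 0.0, sumw = 0.0;
  mat dlogits(2, B);
  for (int b = 0; b < B; ++b) {
    int yi = y[b];
    double wb = class_w[yi];
    vec t(2);
    t[0] = smoothing / 2.0 + (yi == 0 ? 1.0 - smoothing : 0.0);
    t[1] = smoothing / 2.0 + (yi == 1 ? 1.0 - smoothing : 0.0);
    loss += wb * (-arma::accu(t % arma::log(p.col(b) + 1e-12)));
    dlogits.col(b) = wb * (p.col(b) - t);
    sumw += wb;
  }
  loss /= sumw;
  dlogits /= sumw;

  List hgrads;
  mat df = head_bwd(hparams, hc, dlogits, hgrads);
  List bgrads(nb);
  const int Cf = f.n_rows / nb;
  for (int i = 0; i < nb; ++i) {
    List bp = bparams[i];
    List gi;
    mat dfi = df.rows(i * Cf, (i + 1) * Cf - 1);
    branch_bwd(bp, caches[i], dfi, gn_groups, gi);
    bgrads[i] = gi;
  }
  return List::create(_["loss"] = loss,
                      _["grads"] = List::create(_["branches"] = bgrads, _["head"] = hgrads),
                      _["state"] = List::create(_["branches"] = bstate, _["head"] = hstate),
                      _["prob_fall"] = NumericVector(p.row(1).begin(), p.row(1).end()));
}

// Inference-mode forward pass; returns the (2 x B) class-probability matrix.
// [[Rcpp::export]]
arma::mat cpp_fallnet_forward(List params, List state, List xs, int gn_groups) {
  List bparams = params["branches"], hparams = params["head"];
  List bstate = state["branches"];
  List hstate = state["head"];
  const int nb = bparams.size();
  mat f;
  for (int i = 0; i < nb; ++i) {
    List bp = bparams[i];
    List bs = bstate[i];
    cube x = as<cube>(xs[i]);
    BranchCache cc;
    mat fi = branch_fwd(bp, bs, x, false, 0.0, gn_groups, 0.0, cc);
    f = (i == 0) ? fi : arma::join_cols(f, fi);
  }
  HeadCache hc;
  mat logits = head_fwd(hparams, hstate, f, false, 0.0, 0.0, hc);
  return softmax_cols(logits);
}

// Inference-mode forward of a single branch, returning the intermediate
// activations (used for shape tracing and diagnostics).
// [[Rcpp::export]]
List cpp_branch_trace(List bparams, List bstate, arma::cube x, int gn_groups) {
  BranchCache cc;
  List bs = bstate;
  mat f = branch_fwd(bparams, bs, x, false, 0.0, gn_groups, 0.0, cc);
  return List::create(_["h1"] = cc.h1, _["pooled"] = cc.pooled, _["h2"] = cc.h2,
                      _["tcn"] = cc.tcn_out, _["gn"] = cc.gn_out, _["feat"] = f);
}

// Inference-mode forward of the DS-TCN alone (the two stacked temporal
// blocks), used for empirical receptive-field probing.
// [[Rcpp::export]]
arma::cube cpp_dstcn_forward(List bparams, List bstate, arma::cube x) {
  LTBCache c1, c2;
  List bs = bstate;
  cube t1 = ltb_fwd(bparams, bs, "l1", x, 1, false, 0.0, 0.0, c1);
  return ltb_fwd(bparams, bs, "l2", t1, 2, false, 0.0, 0.0, c2);
}
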
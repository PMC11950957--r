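// Compact CNN engine for the 2D U-net dose-prediction model.
//
// The network is an encoder-decoder with skip concatenations, residual
// convolution blocks, batch normalization, dropout, strided-convolution
// downsampling and transposed-convolution upsampling. Forward, backward
// and Adam updates are implemented here in single precision; the training
// loop runs entirely in C++ for speed, with all randomness drawn from one
// mt19937_64 generator so runs are reproducible from a single seed.
//
// Tensor layout: a batch of N slices of C channels is one arma::fmat of
// shape (N*H*W, C); sample n occupies rows [n*HW, (n+1)*HW) and the
// flattened spatial index is p = q*H + r (r = row, fastest-varying,
// matching R's column-major slice flattening). With channels as columns,
// every convolution is a single BLAS sgemm on an im2col matrix, batch
// normalization is column-wise, and skip concatenation is join_rows.

#include <RcppArmadillo.h>
#include <random>
#include <string>
#include <vector>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

// Single-precision training drives many activations and gradients into
// the denormal range (notably in near-zero dose regions), where x86
// arithmetic is orders of magnitude slower. Flush denormals to zero for
// the numerical work in this unit; the ~1e-38 truncation is far below
// anything the optimizer can use.
static inline void set_flush_denormals() {
#if defined(__SSE2__) || defined(__x86_64__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

typedef std::mt19937_64 RNG;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.9f;

// ---------------------------------------------------------------- helpers

struct AdamState {
  fmat m, v;
  void init(const fmat &p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
};

struct AdamHyper {
  float lr, b1, b2, eps;
  long t; // shared step counter
};

static void adam_update(fmat &p, const fmat &g, AdamState &s,
                        const AdamHyper &h) {
  s.m = h.b1 * s.m + (1.0f - h.b1) * g;
  s.v = h.b2 * s.v + (1.0f - h.b2) * (g % g);
  float c1 = 1.0f - std::pow(h.b1, (float)h.t);
  float c2 = 1.0f - std::pow(h.b2, (float)h.t);
  p -= h.lr * (s.m / c1) / (arma::sqrt(s.v / c2) + h.eps);
}

static void he_init(fmat &W, int fan_in, RNG &rng) {
  std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
}

// Spatial geometry of a batch at one resolution level.
struct Geom {
  int N, H, W;
  int HW() const { return H * W; }
  long rows() const { return (long)N * H * W; }
};

// ----------------------------------------------------------------- layers

// 3x3 "same" convolution.
struct Conv3x3 {
  int Cin, Cout;
  fmat W; // (9*Cin) x Cout
  frowvec b;
  fmat gW;
  frowvec gb;
  AdamState aW, ab_;
  fmat col; // cache (N*HW, 9*Cin)
  Geom g_;

  void build(int cin, int cout) {
    Cin = cin;
    Cout = cout;
    W.set_size(9 * Cin, Cout);
    b.zeros(Cout);
  }
  void init(RNG &rng) { he_init(W, 9 * Cin, rng); b.zeros(); }

  void im2col(const fmat &X, fmat &C, const Geom &g) const {
    C.zeros();
    const int H = g.H, Wd = g.W, HW = g.HW();
    for (int n = 0; n < g.N; ++n) {
      const long base = (long)n * HW;
      int o = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr, ++o) {
          int qlo = std::max(0, -dc), qhi = std::min(Wd - 1, Wd - 1 - dc);
          int rlo = std::max(0, -dr), rhi = std::min(H - 1, H - 1 - dr);
          if (qlo > qhi || rlo > rhi) continue;
          for (int q = qlo; q <= qhi; ++q) {
            long p0 = base + (long)q * H + rlo;
            long s0 = base + (long)(q + dc) * H + rlo + dr;
            C.submat(p0, o * Cin, p0 + (rhi - rlo), (o + 1) * Cin - 1) =
                X.submat(s0, 0, s0 + (rhi - rlo), Cin - 1);
          }
        }
    }
  }
  void col2im(const fmat &dC, fmat &dX, const Geom &g) const {
    const int H = g.H, Wd = g.W, HW = g.HW();
    for (int n = 0; n < g.N; ++n) {
      const long base = (long)n * HW;
      int o = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr, ++o) {
          int qlo = std::max(0, -dc), qhi = std::min(Wd - 1, Wd - 1 - dc);
          int rlo = std::max(0, -dr), rhi = std::min(H - 1, H - 1 - dr);
          if (qlo > qhi || rlo > rhi) continue;
          for (int q = qlo; q <= qhi; ++q) {
            long p0 = base + (long)q * H + rlo;
            long s0 = base + (long)(q + dc) * H + rlo + dr;
            dX.submat(s0, 0, s0 + (rhi - rlo), Cin - 1) +=
                dC.submat(p0, o * Cin, p0 + (rhi - rlo), (o + 1) * Cin - 1);
          }
        }
    }
  }

  fmat fwd(const fmat &X, const Geom &g, bool keep) {
    g_ = g;
    fmat Ctmp;
    fmat &C = keep ? col : Ctmp;
    C.set_size(g.rows(), 9 * Cin);
    im2col(X, C, g);
    fmat Y = C * W;
    Y.each_row() += b;
    if (!keep) col.reset();
    return Y;
  }
  fmat bwd(const fmat &dY) {
    gW = col.t() * dY;
    gb = arma::sum(dY, 0);
    fmat dC = dY * W.t();
    fmat dX(g_.rows(), Cin, arma::fill::zeros);
    col2im(dC, dX, g_);
    col.reset();
    return dX;
  }
};

// 1x1 convolution (residual projection and output head).
struct Conv1x1 {
  int Cin, Cout;
  fmat W; // Cin x Cout
  frowvec b;
  fmat gW;
  frowvec gb;
  AdamState aW, ab_;
  fmat Xc;

  void build(int cin, int cout) {
    Cin = cin;
    Cout = cout;
    W.set_size(Cin, Cout);
    b.zeros(Cout);
  }
  void init(RNG &rng) { he_init(W, Cin, rng); b.zeros(); }
  fmat fwd(const fmat &X, bool keep) {
    fmat Y = X * W;
    Y.each_row() += b;
    if (keep) Xc = X;
    return Y;
  }
  fmat bwd(const fmat &dY) {
    gW = Xc.t() * dY;
    gb = arma::sum(dY, 0);
    fmat dX = dY * W.t();
    Xc.reset();
    return dX;
  }
};

// 2x2 stride-2 convolution (learned downsampling).
struct ConvDown {
  int Cin, Cout;
  fmat W; // 4*Cin x Cout
  frowvec b;
  fmat gW;
  frowvec gb;
  AdamState aW, ab_;
  fmat col;
  Geom g_;

  void build(int cin, int cout) {
    Cin = cin;
    Cout = cout;
    W.set_size(4 * Cin, Cout);
    b.zeros(Cout);
  }
  void init(RNG &rng) { he_init(W, 4 * Cin, rng); b.zeros(); }

  fmat fwd(const fmat &X, const Geom &g, bool keep) {
    g_ = g;
    const int H = g.H, Ho = g.H / 2, Wo = g.W / 2, HWo = Ho * Wo;
    fmat Ctmp;
    fmat &C = keep ? col : Ctmp;
    C.set_size((long)g.N * HWo, 4 * Cin);
    for (int n = 0; n < g.N; ++n) {
      const long bi = (long)n * g.HW(), bo = (long)n * HWo;
      int o = 0;
      for (int dc = 0; dc <= 1; ++dc)
        for (int dr = 0; dr <= 1; ++dr, ++o)
          for (int c = 0; c < Cin; ++c) {
            const float *src = X.colptr(c) + bi;
            float *dst = C.colptr(o * Cin + c) + bo;
            for (int q = 0; q < Wo; ++q)
              for (int r = 0; r < Ho; ++r)
                dst[q * Ho + r] = src[(2 * q + dc) * H + 2 * r + dr];
          }
    }
    fmat Y = C * W;
    Y.each_row() += b;
    if (!keep) col.reset();
    return Y;
  }
  fmat bwd(const fmat &dY) {
    gW = col.t() * dY;
    gb = arma::sum(dY, 0);
    fmat dC = dY * W.t();
    const int H = g_.H, Ho = g_.H / 2, Wo = g_.W / 2, HWo = Ho * Wo;
    fmat dX(g_.rows(), Cin, arma::fill::zeros);
    for (int n = 0; n < g_.N; ++n) {
      const long bi = (long)n * g_.HW(), bo = (long)n * HWo;
      int o = 0;
      for (int dc = 0; dc <= 1; ++dc)
        for (int dr = 0; dr <= 1; ++dr, ++o)
          for (int c = 0; c < Cin; ++c) {
            float *dst = dX.colptr(c) + bi;
            const float *src = dC.colptr(o * Cin + c) + bo;
            for (int q = 0; q < Wo; ++q)
              for (int r = 0; r < Ho; ++r)
                dst[(2 * q + dc) * H + 2 * r + dr] += src[q * Ho + r];
          }
    }
    col.reset();
    return dX;
  }
};

// 2x2 stride-2 transposed convolution (learned upsampling).
struct ConvUp {
  int Cin, Cout;
  fmat W; // Cin x 4*Cout (one Cin x Cout block per output sub-position)
  frowvec b; // Cout
  fmat gW;
  frowvec gb;
  AdamState aW, ab_;
  fmat Xc;
  Geom g_; // input geometry

  void build(int cin, int cout) {
    Cin = cin;
    Cout = cout;
    W.set_size(Cin, 4 * Cout);
    b.zeros(Cout);
  }
  void init(RNG &rng) { he_init(W, Cin, rng); b.zeros(); }

  fmat fwd(const fmat &X, const Geom &g, bool keep) {
    g_ = g;
    const int H = g.H, Wd = g.W, H2 = 2 * H, HW2 = 4 * g.HW();
    fmat Yo = X * W; // (N*HW, 4*Cout)
    fmat Y((long)g.N * HW2, Cout);
    for (int n = 0; n < g.N; ++n) {
      const long bi = (long)n * g.HW(), bo = (long)n * HW2;
      int o = 0;
      for (int dc = 0; dc <= 1; ++dc)
        for (int dr = 0; dr <= 1; ++dr, ++o)
          for (int c = 0; c < Cout; ++c) {
            const float *src = Yo.colptr(o * Cout + c) + bi;
            float *dst = Y.colptr(c) + bo;
            for (int q = 0; q < Wd; ++q)
              for (int r = 0; r < H; ++r)
                dst[(2 * q + dc) * H2 + 2 * r + dr] = src[q * H + r];
          }
    }
    Y.each_row() += b;
    if (keep) Xc = X;
    return Y;
  }
  fmat bwd(const fmat &dY) {
    const int H = g_.H, Wd = g_.W, H2 = 2 * H, HW2 = 4 * g_.HW();
    gb = arma::sum(dY, 0);
    fmat dYo(g_.rows(), 4 * Cout);
    for (int n = 0; n < g_.N; ++n) {
      const long bi = (long)n * g_.HW(), bo = (long)n * HW2;
      int o = 0;
      for (int dc = 0; dc <= 1; ++dc)
        for (int dr = 0; dr <= 1; ++dr, ++o)
          for (int c = 0; c < Cout; ++c) {
            float *dst = dYo.colptr(o * Cout + c) + bi;
            const float *src = dY.colptr(c) + bo;
            for (int q = 0; q < Wd; ++q)
              for (int r = 0; r < H; ++r)
                dst[q * H + r] = src[(2 * q + dc) * H2 + 2 * r + dr];
          }
    }
    gW = Xc.t() * dYo;
    fmat dX = dYo * W.t();
    Xc.reset();
    return dX;
  }
};

// Batch normalization over batch x spatial positions, per channel
// (channels are columns of the tall batch matrix).
struct BatchNorm {
  int C;
  fvec g, be, rm, rv;
  fvec gg, gbe;
  AdamState ag, abe;
  fmat xhat;
  frowvec invstd;

  void build(int c) {
    C = c;
    g.ones(C);
    be.zeros(C);
    rm.zeros(C);
    rv.ones(C);
  }
  void init(RNG &) { g.ones(); be.zeros(); rm.zeros(); rv.ones(); }

  fmat fwd(const fmat &X, bool train, bool keep) {
    fmat Y;
    if (train) {
      frowvec mu = arma::mean(X, 0);
      frowvec var = arma::mean(arma::square(X), 0) - arma::square(mu);
      var.transform([](float v) { return v > 0 ? v : 0.0f; });
      invstd = 1.0f / arma::sqrt(var + BN_EPS);
      Y = X;
      Y.each_row() -= mu;
      Y.each_row() %= invstd;
      if (keep) xhat = Y;
      Y.each_row() %= g.t();
      Y.each_row() += be.t();
      rm = BN_MOM * rm + (1.0f - BN_MOM) * mu.t();
      rv = BN_MOM * rv + (1.0f - BN_MOM) * var.t();
    } else {
      frowvec is = (1.0f / arma::sqrt(rv + BN_EPS)).t();
      Y = X;
      Y.each_row() -= rm.t();
      Y.each_row() %= is;
      Y.each_row() %= g.t();
      Y.each_row() += be.t();
    }
    return Y;
  }
  fmat bwd(const fmat &dY) {
    const float cnt = (float)dY.n_rows;
    gbe = arma::sum(dY, 0).t();
    gg = arma::sum(dY % xhat, 0).t();
    fmat dX = dY;
    dX.each_row() -= (gbe / cnt).t();
    dX -= xhat % arma::repmat((gg / cnt).t(), dY.n_rows, 1);
    dX.each_row() %= (g % invstd.t()).t();
    xhat.reset();
    return dX;
  }
};

struct ReLU {
  fmat mask;
  fmat fwd(const fmat &X, bool keep) {
    fmat Y = X;
    Y.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (keep) {
      mask = X;
      mask.transform([](float v) { return v > 0 ? 1.0f : 0.0f; });
    }
    return Y;
  }
  fmat bwd(const fmat &dY) {
    fmat dX = dY % mask;
    mask.reset();
    return dX;
  }
};

struct Dropout {
  float p;
  fmat mask;
  fmat fwd(const fmat &X, bool train, RNG &rng, bool keep) {
    if (!train || p <= 0.0f) return X;
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    mask.set_size(X.n_rows, X.n_cols);
    float scale = 1.0f / (1.0f - p);
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask(i) = (ud(rng) >= p) ? scale : 0.0f;
    fmat Y = X % mask;
    if (!keep) mask.reset();
    return Y;
  }
  fmat bwd(const fmat &dY) {
    fmat dX = dY % mask;
    mask.reset();
    return dX;
  }
};

// Residual convolution block:
// conv3x3 -> BN -> ReLU -> conv3x3 -> BN -> dropout -> (+ shortcut) -> ReLU
// The shortcut is the identity when channel counts match, else a 1x1
// projection. Dropout follows every second batch-normalization layer.
struct Block {
  int Cin, Cout;
  Conv3x3 conv1, conv2;
  BatchNorm bn1, bn2;
  ReLU relu1, relu2;
  Dropout drop;
  Conv1x1 proj;
  bool has_proj;

  void build(int cin, int cout, float dropout) {
    Cin = cin;
    Cout = cout;
    conv1.build(cin, cout);
    bn1.build(cout);
    conv2.build(cout, cout);
    bn2.build(cout);
    drop.p = dropout;
    has_proj = (cin != cout);
    if (has_proj) proj.build(cin, cout);
  }
  void init(RNG &rng) {
    conv1.init(rng);
    bn1.init(rng);
    conv2.init(rng);
    bn2.init(rng);
    if (has_proj) proj.init(rng);
  }
  fmat fwd(const fmat &X, const Geom &g, bool train, RNG &rng, bool keep) {
    fmat a = conv1.fwd(X, g, keep);
    a = bn1.fwd(a, train, keep);
    a = relu1.fwd(a, keep);
    a = conv2.fwd(a, g, keep);
    a = bn2.fwd(a, train, keep);
    a = drop.fwd(a, train, rng, keep);
    if (has_proj)
      a += proj.fwd(X, keep);
    else
      a += X;
    return relu2.fwd(a, keep);
  }
  // returns dX; requires keep=true caches from fwd
  fmat bwd(const fmat &dY) {
    fmat d = relu2.bwd(dY);
    fmat dshort = d; // gradient into the shortcut branch
    if (drop.p > 0.0f && drop.mask.n_elem > 0) d = drop.bwd(d);
    d = bn2.bwd(d);
    d = conv2.bwd(d);
    d = relu1.bwd(d);
    d = bn1.bwd(d);
    fmat dX = conv1.bwd(d);
    if (has_proj)
      dX += proj.bwd(dshort);
    else
      dX += dshort;
    return dX;
  }
};

// ------------------------------------------------------------------- net

struct Net {
  int in_ch, base, depth;
  float dropout;
  std::vector<Block> enc, dec;
  Block bott;
  std::vector<ConvDown> down;
  std::vector<ConvUp> up;
  Conv1x1 head;

  void build(int in_ch_, int base_, int depth_, float dropout_) {
    in_ch = in_ch_;
    base = base_;
    depth = depth_;
    dropout = dropout_;
    enc.resize(depth);
    dec.resize(depth);
    down.resize(depth);
    up.resize(depth);
    for (int l = 0; l < depth; ++l) {
      int cl = base << l, cn = base << (l + 1);
      enc[l].build(l == 0 ? in_ch : cl, cl, dropout);
      down[l].build(cl, cn);
      up[l].build(cn, cl);
      dec[l].build(2 * cl, cl, dropout);
    }
    bott.build(base << depth, base << depth, dropout);
    head.build(base, 1);
  }
  void init(RNG &rng) {
    for (int l = 0; l < depth; ++l) {
      enc[l].init(rng);
      down[l].init(rng);
      up[l].init(rng);
      dec[l].init(rng);
    }
    bott.init(rng);
    head.init(rng);
  }

  fmat fwd(const fmat &X, Geom g, bool train, RNG &rng, bool keep) {
    if (g.H % (1 << depth) || g.W % (1 << depth))
      stop("spatial size must be divisible by 2^depth");
    std::vector<fmat> skips(depth);
    fmat cur = X;
    for (int l = 0; l < depth; ++l) {
      skips[l] = enc[l].fwd(cur, g, train, rng, keep);
      cur = down[l].fwd(skips[l], g, keep);
      g.H /= 2;
      g.W /= 2;
    }
    cur = bott.fwd(cur, g, train, rng, keep);
    for (int l = depth - 1; l >= 0; --l) {
      fmat u = up[l].fwd(cur, g, keep);
      g.H *= 2;
      g.W *= 2;
      cur = dec[l].fwd(arma::join_rows(u, skips[l]), g, train, rng, keep);
      skips[l].reset();
    }
    return head.fwd(cur, keep);
  }

  // Backward through the whole net; fwd must have been run with keep=true.
  void bwd(const fmat &dOut) {
    fmat d = head.bwd(dOut);
    std::vector<fmat> dskip(depth);
    for (int l = 0; l < depth; ++l) {
      fmat dcat = dec[l].bwd(d);
      int cl = base << l;
      dskip[l] = dcat.cols(cl, 2 * cl - 1);
      d = up[l].bwd(dcat.cols(0, cl - 1));
    }
    d = bott.bwd(d);
    for (int l = depth - 1; l >= 0; --l) {
      fmat de = down[l].bwd(d);
      de += dskip[l];
      dskip[l].reset();
      d = enc[l].bwd(de);
    }
  }

  // each_param callback signature:
  //   f(name, fmat& value, fmat* grad, AdamState*, trainable)
  // frowvec/fvec parameters are exposed through 1-row / 1-col fmat copies.
  template <typename F>
  void rowvec_param(const std::string &nm, frowvec &v, frowvec *g,
                    AdamState *a, F f) {
    fmat vm(v), gm;
    bool has_g = g && g->n_elem == v.n_elem;
    if (has_g) gm = fmat(*g);
    f(nm, vm, has_g ? &gm : nullptr, a, true);
    v = vm.row(0);
    if (has_g) *g = gm.row(0);
  }
  template <typename F>
  void colvec_param(const std::string &nm, fvec &v, fvec *g, AdamState *a,
                    bool train, F f) {
    fmat vm(v), gm;
    bool has_g = g && g->n_elem == v.n_elem;
    if (has_g) gm = fmat(*g);
    f(nm, vm, has_g ? &gm : nullptr, a, train);
    v = vm.col(0);
    if (has_g) *g = gm.col(0);
  }
  template <typename F>
  void block_params(Block &blk, const std::string &p, F f) {
    f(p + ".conv1.W", blk.conv1.W, &blk.conv1.gW, &blk.conv1.aW, true);
    rowvec_param(p + ".conv1.b", blk.conv1.b, &blk.conv1.gb,
                 &blk.conv1.ab_, f);
    colvec_param(p + ".bn1.g", blk.bn1.g, &blk.bn1.gg, &blk.bn1.ag, true, f);
    colvec_param(p + ".bn1.b", blk.bn1.be, &blk.bn1.gbe, &blk.bn1.abe, true,
                 f);
    colvec_param(p + ".bn1.rm", blk.bn1.rm, nullptr, nullptr, false, f);
    colvec_param(p + ".bn1.rv", blk.bn1.rv, nullptr, nullptr, false, f);
    f(p + ".conv2.W", blk.conv2.W, &blk.conv2.gW, &blk.conv2.aW, true);
    rowvec_param(p + ".conv2.b", blk.conv2.b, &blk.conv2.gb,
                 &blk.conv2.ab_, f);
    colvec_param(p + ".bn2.g", blk.bn2.g, &blk.bn2.gg, &blk.bn2.ag, true, f);
    colvec_param(p + ".bn2.b", blk.bn2.be, &blk.bn2.gbe, &blk.bn2.abe, true,
                 f);
    colvec_param(p + ".bn2.rm", blk.bn2.rm, nullptr, nullptr, false, f);
    colvec_param(p + ".bn2.rv", blk.bn2.rv, nullptr, nullptr, false, f);
    if (blk.has_proj) {
      f(p + ".proj.W", blk.proj.W, &blk.proj.gW, &blk.proj.aW, true);
      rowvec_param(p + ".proj.b", blk.proj.b, &blk.proj.gb, &blk.proj.ab_,
                   f);
    }
  }
  template <typename F> void each_param(F f) {
    for (int l = 0; l < depth; ++l) {
      block_params(enc[l], "enc" + std::to_string(l), f);
      f("down" + std::to_string(l) + ".W", down[l].W, &down[l].gW,
        &down[l].aW, true);
      rowvec_param("down" + std::to_string(l) + ".b", down[l].b,
                   &down[l].gb, &down[l].ab_, f);
      f("up" + std::to_string(l) + ".W", up[l].W, &up[l].gW, &up[l].aW,
        true);
      rowvec_param("up" + std::to_string(l) + ".b", up[l].b, &up[l].gb,
                   &up[l].ab_, f);
      block_params(dec[l], "dec" + std::to_string(l), f);
    }
    block_params(bott, "bott", f);
    f("head.W", head.W, &head.gW, &head.aW, true);
    rowvec_param("head.b", head.b, &head.gb, &head.ab_, f);
  }

  List save() {
    std::vector<SEXP> vals;
    std::vector<std::string> names;
    each_param([&](const std::string &nm, fmat &v, fmat *, AdamState *,
                   bool) {
      NumericMatrix m(v.n_rows, v.n_cols);
      for (arma::uword i = 0; i < v.n_elem; ++i) m[i] = v(i);
      names.push_back(nm);
      vals.push_back(m);
    });
    List res(vals.size());
    CharacterVector rn(vals.size());
    for (size_t i = 0; i < vals.size(); ++i) {
      res[i] = vals[i];
      rn[i] = names[i];
    }
    res.attr("names") = rn;
    return res;
  }
  void load(const List &params) {
    each_param([&](const std::string &nm, fmat &v, fmat *, AdamState *,
                   bool) {
      if (!params.containsElementNamed(nm.c_str()))
        stop("missing parameter '%s'", nm.c_str());
      NumericMatrix m = params[nm];
      if ((arma::uword)m.nrow() != v.n_rows ||
          (arma::uword)m.ncol() != v.n_cols)
        stop("parameter '%s' has wrong shape", nm.c_str());
      for (arma::uword i = 0; i < v.n_elem; ++i) v(i) = (float)m[i];
    });
  }
  void adam_init() {
    each_param([&](const std::string &, fmat &v, fmat *, AdamState *a,
                   bool train) {
      if (train && a) a->init(v);
    });
  }
  void adam_step(AdamHyper &h) {
    each_param([&](const std::string &, fmat &v, fmat *g, AdamState *a,
                   bool train) {
      if (train && g && a && g->n_elem == v.n_elem)
        adam_update(v, *g, *a, h);
    });
  }
};

static Net make_net(const List &cfg) {
  Net net;
  net.build(as<int>(cfg["in_channels"]), as<int>(cfg["base_features"]),
            as<int>(cfg["depth"]), (float)as<double>(cfg["dropout"]));
  return net;
}

// Copy slices idx (0-based) of the (HW, C, Ntot) array x into a tall
// (n*HW, C) float matrix.
static fmat gather_batch(const double *x, long HW, int C, long Ntot,
                         const std::vector<int> &idx) {
  fmat X((long)idx.size() * HW, C);
  for (size_t i = 0; i < idx.size(); ++i) {
    const double *src = x + (long)idx[i] * HW * C;
    for (int c = 0; c < C; ++c) {
      float *dst = X.colptr(c) + (long)i * HW;
      const double *s = src + (long)c * HW;
      for (long p = 0; p < HW; ++p) dst[p] = (float)s[p];
    }
  }
  return X;
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export(name = ".unet_init")]]
List unet_init_cpp(List cfg, int seed) {
  set_flush_denormals();
  Net net = make_net(cfg);
  RNG rng((uint64_t)seed);
  net.init(rng);
  return net.save();
}

// [[Rcpp::export(name = ".unet_predict")]]
NumericMatrix unet_predict_cpp(List params, List cfg, NumericVector x,
                               int H, int W, int C, int N) {
  set_flush_denormals();
  Net net = make_net(cfg);
  net.load(params);
  RNG rng(0);
  long HW = (long)H * W;
  std::vector<int> all(N);
  for (int i = 0; i < N; ++i) all[i] = i;
  Geom g;
  g.N = N;
  g.H = H;
  g.W = W;
  fmat X = gather_batch(x.begin(), HW, C, N, all);
  fmat Y = net.fwd(X, g, false, rng, false);
  NumericMatrix out(HW, N);
  for (int n = 0; n < N; ++n)
    for (long p = 0; p < HW; ++p) out(p, n) = Y((long)n * HW + p, 0);
  return out;
}

// Training loop: mini-batch Adam on MSE, per-epoch mean training-batch loss
// and eval-mode validation loss. Indices are 0-based into the slice axis.
// [[Rcpp::export(name = ".unet_train")]]
List unet_train_cpp(List params, List cfg, NumericVector x, NumericMatrix y,
                    int H, int W, int C, int N, IntegerVector train_idx,
                    IntegerVector val_idx, int epochs, int batch_size,
                    double lr, double beta1, double beta2, int seed) {
  set_flush_denormals();
  Net net = make_net(cfg);
  net.load(params);
  net.adam_init();
  RNG rng((uint64_t)seed);
  long HW = (long)H * W;

  AdamHyper hyper;
  hyper.lr = (float)lr;
  hyper.b1 = (float)beta1;
  hyper.b2 = (float)beta2;
  hyper.eps = 1e-8f;
  hyper.t = 0;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  NumericVector train_loss(epochs), val_loss(epochs);

  auto target_batch = [&](const std::vector<int> &idx, size_t from,
                          size_t nb) {
    fmat T(nb * HW, 1);
    for (size_t i = 0; i < nb; ++i) {
      const double *s = &y(0, idx[from + i]);
      float *dst = T.colptr(0) + (long)i * HW;
      for (long p = 0; p < HW; ++p) dst[p] = (float)s[p];
    }
    return T;
  };

  auto eval_mse = [&](const std::vector<int> &idx) -> double {
    if (idx.empty()) return NA_REAL;
    double se = 0;
    size_t done = 0;
    while (done < idx.size()) {
      size_t nb = std::min((size_t)batch_size, idx.size() - done);
      std::vector<int> sub(idx.begin() + done, idx.begin() + done + nb);
      Geom g;
      g.N = nb;
      g.H = H;
      g.W = W;
      fmat Xb = gather_batch(x.begin(), HW, C, N, sub);
      fmat Yb = net.fwd(Xb, g, false, rng, false);
      fmat Tb = target_batch(idx, done, nb);
      fmat diff = Yb - Tb;
      se += arma::dot(diff, diff);
      done += nb;
    }
    return se / ((double)idx.size() * HW);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0;
    int nb_count = 0;
    size_t done = 0;
    while (done < tr.size()) {
      size_t nb = std::min((size_t)batch_size, tr.size() - done);
      std::vector<int> sub(tr.begin() + done, tr.begin() + done + nb);
      Geom g;
      g.N = nb;
      g.H = H;
      g.W = W;
      fmat Xb = gather_batch(x.begin(), HW, C, N, sub);
      fmat Tb = target_batch(tr, done, nb);
      fmat Yb = net.fwd(Xb, g, true, rng, true);
      fmat diff = Yb - Tb;
      double se = arma::dot(diff, diff);
      fmat dY = (2.0f / (float)diff.n_rows) * diff;
      net.bwd(dY);
      ++hyper.t;
      net.adam_step(hyper);
      ep_loss += se / (double)diff.n_rows;
      ++nb_count;
      done += nb;
      Rcpp::checkUserInterrupt();
    }
    train_loss[ep] = ep_loss / std::max(nb_count, 1);
    val_loss[ep] = eval_mse(va);
  }

  return List::create(_["params"] = net.save(),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss);
}

// Loss and analytic gradients for one batch (gradient-check support).
// BN uses batch statistics; dropout is disabled.
// [[Rcpp::export(name = ".unet_loss_grads")]]
List unet_loss_grads_cpp(List params, List cfg, NumericVector x,
                         NumericMatrix y, int H, int W, int C, int N) {
  set_flush_denormals();
  List cfg2 = clone(cfg);
  cfg2["dropout"] = 0.0;
  Net net = make_net(cfg2);
  net.load(params);
  RNG rng(0);
  long HW = (long)H * W;
  std::vector<int> all(N);
  for (int i = 0; i < N; ++i) all[i] = i;
  Geom g;
  g.N = N;
  g.H = H;
  g.W = W;
  fmat X = gather_batch(x.begin(), HW, C, N, all);
  fmat T(HW * (long)N, 1);
  for (int n = 0; n < N; ++n)
    for (long p = 0; p < HW; ++p) T((long)n * HW + p, 0) = (float)y(p, n);
  fmat Y = net.fwd(X, g, true, rng, true);
  fmat diff = Y - T;
  double se = arma::dot(diff, diff);
  fmat dY = (2.0f / (float)diff.n_rows) * diff;
  net.bwd(dY);
  std::vector<std::string> names;
  std::vector<NumericMatrix> grads;
  net.each_param([&](const std::string &nm, fmat &v, fmat *gr, AdamState *,
                     bool train) {
    if (!train || !gr || gr->n_elem != v.n_elem) return;
    NumericMatrix m(gr->n_rows, gr->n_cols);
    for (arma::uword i = 0; i < gr->n_elem; ++i) m[i] = (*gr)(i);
    names.push_back(nm);
    grads.push_back(m);
  });
  List gl(grads.size());
  CharacterVector gn(grads.size());
  for (size_t i = 0; i < grads.size(); ++i) {
    gl[i] = grads[i];
    gn[i] = names[i];
  }
  gl.attr("names") = gn;
  return List::create(_["loss"] = se / (double)diff.n_rows,
                      _["grads"] = gl);
}
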
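// Self-contained float32 CNN engine for FAZ segmentation:
// im2col/GEMM convolutions, batch normalization, 2x2 max pooling,
// bilinear 2x upsampling, the feature-location attention block (FLAB),
// joint Dice + cross-entropy loss, manual backprop and Adam.
//
// Layout conventions:
//   - An image tensor is an arma::fcube (H, W, C); a batch is a vector of
//     cubes. R-side 4-D arrays are (N, C, H, W) double, converted at the
//     boundary.
//   - Conv weights are stored as fmat (Cin*k*k, Cout) with row index
//     ci*k*k + kr*k + kc; the R-facing layout is (Cout, Cin, kh, kw).
//
// Performance notes: convolutions run through chunked im2col + BLAS sgemm;
// the gradient w.r.t. the input is computed as a same-size convolution of
// the output gradient with the flipped kernel (better GEMM shapes, no
// scatter). Everything that is not a GEMM runs through small pointer
// kernels cloned for x86-64-v3 (AVX2/FMA) with a generic fallback, so one
// binary stays portable while using wide vectors where available.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <memory>
#include <vector>
#include <string>
#include <cstring>
#include <cmath>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

typedef std::vector<fcube> Batch;
typedef std::shared_ptr<Batch> BatchP;

#if defined(__GLIBC__)
#include <malloc.h>
// Training allocates and frees large activation buffers every step; keep
// them in the heap instead of round-tripping through mmap/munmap (page
// faults dominate otherwise on repeated steps).
static struct MallocTuning {
  MallocTuning() {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
  }
} malloc_tuning_;
#endif

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT __attribute__((target_clones("arch=x86-64-v4", "arch=x86-64-v3", "default")))
#else
#define HOT
#endif

// ------------------------------------------------------ profiling ----
// cheap wall-clock buckets, exposed through .nn_prof_report for tuning
static struct Prof {
  std::map<std::string, double> t;
} prof_;
struct ProfScope {
  const char* key;
  arma::wall_clock clk;
  explicit ProfScope(const char* k) : key(k) { clk.tic(); }
  ~ProfScope() { prof_.t[key] += clk.toc(); }
};

// ------------------------------------------------------- hot kernels ----
HOT static void k_axpy(int n, float a, const float* x, float* y) {
  for (int i = 0; i < n; ++i) y[i] += a * x[i];
}
HOT static void k_scale_add2(int n, float a, const float* x, float b,
                             const float* y, float* out) {
  for (int i = 0; i < n; ++i) out[i] = a * x[i] + b * y[i];
}
HOT static float k_dot(int n, const float* x, const float* y) {
  float acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int i = 0;
  for (; i + 8 <= n; i += 8)
    for (int j = 0; j < 8; ++j) acc[j] += x[i + j] * y[i + j];
  float s = 0;
  for (int j = 0; j < 8; ++j) s += acc[j];
  for (; i < n; ++i) s += x[i] * y[i];
  return s;
}
HOT static void k_add(int n, const float* x, float* y) {
  for (int i = 0; i < n; ++i) y[i] += x[i];
}
HOT static void k_relu(int n, float* x) {
  for (int i = 0; i < n; ++i) x[i] = x[i] > 0 ? x[i] : 0.0f;
}
HOT static void k_relu_bwd(int n, const float* y, float* d) {
  for (int i = 0; i < n; ++i) if (y[i] <= 0) d[i] = 0;
}
HOT static void k_sum_sumsq(int n, const float* x, double* s, double* s2) {
  double a0 = 0, a1 = 0;
  for (int i = 0; i < n; ++i) { a0 += x[i]; a1 += (double)x[i] * x[i]; }
  *s += a0; *s2 += a1;
}
HOT static double k_sumd(int n, const float* x) {
  double a = 0;
  for (int i = 0; i < n; ++i) a += x[i];
  return a;
}
HOT static void k_bn_apply(int n, const float* x, float mu, float is, float g,
                           float b, float* xhat, float* y) {
  for (int i = 0; i < n; ++i) {
    const float h = (x[i] - mu) * is;
    xhat[i] = h;
    y[i] = g * h + b;
  }
}
HOT static void k_bn_eval(int n, const float* x, float mu, float is, float g,
                          float b, float* y) {
  for (int i = 0; i < n; ++i) y[i] = g * (x[i] - mu) * is + b;
}
HOT static void k_bn_bwd_sums(int n, const float* d, const float* h,
                              double* sd, double* sdh) {
  double a0 = 0, a1 = 0;
  for (int i = 0; i < n; ++i) { a0 += d[i]; a1 += (double)d[i] * h[i]; }
  *sd += a0; *sdh += a1;
}
HOT static void k_bn_bwd_apply(int n, const float* d, const float* h, float a,
                               float m, float sd, float sdh, float* out) {
  for (int i = 0; i < n; ++i) out[i] = a * (m * d[i] - sd - h[i] * sdh);
}

// fast expf via 2^z with a degree-5 minimax polynomial; |rel err| ~ 3e-7,
// clamped to the finite float range. Deterministic pure arithmetic.
HOT static void k_sigmoid(int n, const float* x, float* out) {
  for (int i = 0; i < n; ++i) {
    float z = -x[i] * 1.44269504088896341f;
    if (z > 126.0f) z = 126.0f;
    if (z < -126.0f) z = -126.0f;
    const float fl = std::floor(z);
    const float f = z - fl;
    float p = 1.8775767e-3f;
    p = p * f + 8.9893397e-3f;
    p = p * f + 5.5826318e-2f;
    p = p * f + 2.4015361e-1f;
    p = p * f + 6.9315308e-1f;
    p = p * f + 9.9999994e-1f;
    union { uint32_t u; float fv; } sc;
    sc.u = (uint32_t)((int)fl + 127) << 23;
    const float e = sc.fv * p;     // exp(-x)
    out[i] = 1.0f / (1.0f + e);
  }
}

// ------------------------------------------------------------- params ----
struct PTensor {
  fmat w, g, m, v;
  std::string name;
  void init(int nr, int nc, const std::string& nm) {
    w.zeros(nr, nc); g.zeros(nr, nc); m.zeros(nr, nc); v.zeros(nr, nc);
    name = nm;
  }
};

// ---------------------------------------------------------------- RNG ----
// mt19937 + polar Box-Muller; self-contained so that initialization is
// bit-reproducible regardless of the C++ stdlib.
struct XRng {
  std::mt19937 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit XRng(uint32_t seed) : gen(seed) {}
  double unif() { return (double(gen()) + 0.5) / 4294967296.0; }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// -------------------------------------------------- conv2d primitives ----
// Stride-1, zero-padded, square-kernel cross-correlation.

static int conv_chunk_cols(int H, int CiKK, int W) {
  long budget = 16L * 1024 * 1024;       // 64 MB of floats
  long nc = budget / (long(CiKK) * H);
  if (nc < 1) nc = 1;
  if (nc > W) nc = W;
  return (int)nc;
}

// Fill colsT (H*ncols x CiKK) for output columns [c0, c0+ncols).
static void im2col_chunk(const fcube& x, int k, int c0, int ncols, fmat& colsT) {
  ProfScope ps_("im2col");
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices, p = (k - 1) / 2;
  colsT.set_size((size_t)H * ncols, (size_t)Ci * k * k);
  for (int ci = 0; ci < Ci; ++ci) {
    for (int kr = 0; kr < k; ++kr) {
      const int r0 = std::max(0, p - kr);
      const int r1 = std::min(H, H + p - kr);
      for (int kc = 0; kc < k; ++kc) {
        float* dst = colsT.colptr((size_t)ci * k * k + (size_t)kr * k + kc);
        for (int c = c0; c < c0 + ncols; ++c) {
          float* seg = dst + (size_t)(c - c0) * H;
          const int ic = c + kc - p;
          if (ic < 0 || ic >= W) {
            std::memset(seg, 0, sizeof(float) * H);
            continue;
          }
          if (r0 > 0) std::memset(seg, 0, sizeof(float) * r0);
          if (r1 < H) std::memset(seg + r1, 0, sizeof(float) * (H - r1));
          if (r1 > r0)
            std::memcpy(seg + r0, x.slice_colptr(ci, ic) + r0 + kr - p,
                        sizeof(float) * (r1 - r0));
        }
      }
    }
  }
}

static void conv_fwd(const fcube& x, const fmat& W, const fmat& b, int k,
                     fcube& out, bool add_bias = true) {
  ProfScope ps_("conv_fwd");
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  const int Co = W.n_cols;
  out.set_size(H, Wd, Co);
  if (k == 1) {
    const fmat Xm(const_cast<float*>(x.memptr()), (size_t)H * Wd, Ci, false, true);
    fmat Om(out.memptr(), (size_t)H * Wd, Co, false, true);
    Om = Xm * W;
    if (add_bias) Om.each_row() += b.t();
    return;
  }
  const int step = conv_chunk_cols(H, Ci * k * k, Wd);
  fmat colsT;
  for (int c0 = 0; c0 < Wd; c0 += step) {
    const int nc = std::min(step, Wd - c0);
    im2col_chunk(x, k, c0, nc, colsT);
    fmat oc = colsT * W;               // (H*nc, Co)
    if (add_bias) oc.each_row() += b.t();
    for (int co = 0; co < Co; ++co)
      std::memcpy(out.slice_colptr(co, c0), oc.colptr(co),
                  sizeof(float) * (size_t)H * nc);
  }
}

// weight gradient + bias gradient from input and output gradient
static void conv_bwd_w(const fcube& x, int k, const fcube& dout, fmat& dW,
                       fmat& db) {
  ProfScope ps_("conv_bwd_w");
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  const int Co = dout.n_slices;
  for (int co = 0; co < Co; ++co)
    db(co) += (float)k_sumd((int)((size_t)H * Wd), dout.slice_memptr(co));
  if (k == 1) {
    const fmat Xm(const_cast<float*>(x.memptr()), (size_t)H * Wd, Ci, false, true);
    const fmat Dm(const_cast<float*>(dout.memptr()), (size_t)H * Wd, Co, false, true);
    dW += Xm.t() * Dm;
    return;
  }
  const int step = conv_chunk_cols(H, Ci * k * k, Wd);
  fmat colsT, doc;
  for (int c0 = 0; c0 < Wd; c0 += step) {
    const int nc = std::min(step, Wd - c0);
    im2col_chunk(x, k, c0, nc, colsT);
    doc.set_size((size_t)H * nc, Co);
    for (int co = 0; co < Co; ++co)
      std::memcpy(doc.colptr(co), dout.slice_colptr(co, c0),
                  sizeof(float) * (size_t)H * nc);
    dW += colsT.t() * doc;
  }
}

// input gradient as a same-size convolution of dout with the flipped
// kernel: dx (H,W,Ci) = conv(dout, Wflip), Wflip (Co*k*k, Ci)
static void conv_bwd_x(const fmat& W, int k, int Ci, const fcube& dout,
                       fcube& dx) {
  ProfScope ps_("conv_bwd_x");
  const int Co = dout.n_slices;
  if (k == 1) {
    const int H = dout.n_rows, Wd = dout.n_cols;
    dx.set_size(H, Wd, Ci);
    const fmat Dm(const_cast<float*>(dout.memptr()), (size_t)H * Wd, Co, false, true);
    fmat DxM(dx.memptr(), (size_t)H * Wd, Ci, false, true);
    DxM = Dm * W.t();
    return;
  }
  fmat Wf((size_t)Co * k * k, Ci);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc)
          Wf((size_t)co * k * k + (size_t)(k - 1 - kr) * k + (k - 1 - kc), ci) =
            W((size_t)ci * k * k + (size_t)kr * k + kc, co);
  fmat zb(Ci, 1, arma::fill::zeros);
  conv_fwd(dout, Wf, zb, k, dx, false);
}

// ------------------------------------- separable stride-1 pooling pair ----
// Sliding-window average and max with edge replication (clamped indices),
// output size == input size. Separable passes: columns then rows. The
// arg-max linear index (within the H x W map) is recorded during the
// forward pass so the backward pass is a plain scatter.
static void pool_pair_fwd(const fmat& x, int k, float* avg, float* mx,
                          int* arg, fmat& tS, fmat& tM,
                          std::vector<short>& argc) {
  ProfScope ps_("pool_fwd");
  const int H = x.n_rows, W = x.n_cols, p = (k - 1) / 2;
  tS.set_size(H, W); tM.set_size(H, W);
  argc.resize((size_t)H * W);
  for (int c = 0; c < W; ++c) {
    const int cc0 = c - p < 0 ? 0 : c - p;
    float* ps = tS.colptr(c);
    float* pm = tM.colptr(c);
    short* ac = argc.data() + (size_t)c * H;
    std::memcpy(ps, x.colptr(cc0), sizeof(float) * H);
    std::memcpy(pm, x.colptr(cc0), sizeof(float) * H);
    for (int r = 0; r < H; ++r) ac[r] = (short)cc0;
    for (int dc = -p; dc <= p; ++dc) {
      if (dc == -p) continue;                  // provided by the memcpy
      int cc = c + dc; cc = cc < 0 ? 0 : (cc >= W ? W - 1 : cc);
      k_add(H, x.colptr(cc), ps);
      const float* xc = x.colptr(cc);
      for (int r = 0; r < H; ++r)
        if (xc[r] > pm[r]) { pm[r] = xc[r]; ac[r] = (short)cc; }
    }
  }
  const float inv = 1.0f / (k * k);
  for (int c = 0; c < W; ++c) {
    const float* ps = tS.colptr(c);
    const float* pm = tM.colptr(c);
    const short* ac = argc.data() + (size_t)c * H;
    float* oa = avg + (size_t)c * H;
    float* om = mx + (size_t)c * H;
    int* oi = arg + (size_t)c * H;
    const int rlo = std::min(p, H), rhi = std::max(rlo, H - p);
    // clamped border rows
    for (int r = 0; r < H; ++r) {
      if (r == rlo && rhi > rlo) r = rhi;          // skip interior
      float sv = 0;
      int br = r - p < 0 ? 0 : r - p;
      float m = pm[br];
      for (int dr = -p; dr <= p; ++dr) {
        int rr = r + dr; rr = rr < 0 ? 0 : (rr >= H ? H - 1 : rr);
        sv += ps[rr];
        if (pm[rr] > m) { m = pm[rr]; br = rr; }
      }
      oa[r] = sv * inv;
      om[r] = m;
      oi[r] = br + H * (int)ac[br];
    }
    // branch-light interior
    for (int r = rlo; r < rhi; ++r) {
      float sv = ps[r - p];
      int br = r - p;
      float m = pm[r - p];
      for (int dr = -p + 1; dr <= p; ++dr) {
        sv += ps[r + dr];
        if (pm[r + dr] > m) { m = pm[r + dr]; br = r + dr; }
      }
      oa[r] = sv * inv;
      om[r] = m;
      oi[r] = br + H * (int)ac[br];
    }
  }
}

// davg spreads uniformly over the (clamped) window; dmax flows to the
// recorded arg-max position.
static void pool_pair_bwd(int k, const fmat& davg, const fmat& dmx,
                          const int* arg, fmat& dx, fmat& tS) {
  ProfScope ps_("pool_bwd");
  const int H = davg.n_rows, W = davg.n_cols, p = (k - 1) / 2;
  const float inv = 1.0f / (k * k);
  // vertical transpose-scatter: dtmp = sum_dr shift(davg) with edge pileup
  tS.zeros(H, W);
  for (int c = 0; c < W; ++c) {
    const float* d = davg.colptr(c);
    float* t = tS.colptr(c);
    for (int dr = -p; dr <= p; ++dr) {
      const int r0 = dr < 0 ? -dr : 0;
      const int r1 = dr > 0 ? H - dr : H;
      if (r1 > r0) k_add(r1 - r0, d + r0, t + r0 + dr);
      for (int r = 0; r < r0; ++r) t[0] += d[r];
      for (int r = r1; r < H; ++r) t[H - 1] += d[r];
    }
  }
  // horizontal transpose-scatter with the 1/k^2 factor folded in
  for (int c = 0; c < W; ++c)
    for (int dc = -p; dc <= p; ++dc) {
      int cc = c + dc; cc = cc < 0 ? 0 : (cc >= W ? W - 1 : cc);
      k_axpy(H, inv, tS.colptr(c), dx.colptr(cc));
    }
  // max part: direct scatter to recorded argmax
  const float* dm = dmx.memptr();
  float* px = dx.memptr();
  const int np = H * W;
  for (int q = 0; q < np; ++q) px[arg[q]] += dm[q];
}

// ------------------------------------------- direct small convolution ----
// 7x7 (or any odd k) zero-padded conv of one input map into ONE output
// map, as shifted column AXPYs: out += w[t] * shift(x). Used by the
// location-aware branch where im2col overhead would dominate.
static void conv1out_accum(const fmat& x, const float* w, int k, fmat& out) {
  ProfScope ps_("loc_fwd");
  const int H = x.n_rows, W = x.n_cols, p = (k - 1) / 2;
  for (int kr = 0; kr < k; ++kr) {
    const int dr = kr - p;
    const int r0 = dr < 0 ? -dr : 0;          // output row start
    const int r1 = dr > 0 ? H - dr : H;       // output row end
    if (r1 <= r0) continue;
    for (int kc = 0; kc < k; ++kc) {
      const float wv = w[(size_t)kr * k + kc];
      const int dc = kc - p;
      const int c0 = dc < 0 ? -dc : 0;
      const int c1 = dc > 0 ? W - dc : W;
      for (int c = c0; c < c1; ++c)
        k_axpy(r1 - r0, wv, x.colptr(c + dc) + r0 + dr, out.colptr(c) + r0);
    }
  }
}

// gradient of the kernel: dw[t] += sum(dout * shift(x))
static void conv1out_dw(const fmat& x, const fmat& dout, int k, float* dw) {
  ProfScope ps_("loc_dw");
  const int H = x.n_rows, W = x.n_cols, p = (k - 1) / 2;
  for (int kr = 0; kr < k; ++kr) {
    const int dr = kr - p;
    const int r0 = dr < 0 ? -dr : 0;
    const int r1 = dr > 0 ? H - dr : H;
    if (r1 <= r0) continue;
    for (int kc = 0; kc < k; ++kc) {
      const int dc = kc - p;
      const int c0 = dc < 0 ? -dc : 0;
      const int c1 = dc > 0 ? W - dc : W;
      float acc = 0;
      for (int c = c0; c < c1; ++c)
        acc += k_dot(r1 - r0, dout.colptr(c) + r0, x.colptr(c + dc) + r0 + dr);
      dw[(size_t)kr * k + kc] += acc;
    }
  }
}

// gradient of the input: dx += w[t] * shift^T(dout)
static void conv1out_dx(const fmat& dout, const float* w, int k, fmat& dx) {
  ProfScope ps_("loc_dx");
  const int H = dout.n_rows, W = dout.n_cols, p = (k - 1) / 2;
  for (int kr = 0; kr < k; ++kr) {
    const int dr = kr - p;
    const int r0 = dr < 0 ? -dr : 0;
    const int r1 = dr > 0 ? H - dr : H;
    if (r1 <= r0) continue;
    for (int kc = 0; kc < k; ++kc) {
      const float wv = w[(size_t)kr * k + kc];
      const int dc = kc - p;
      const int c0 = dc < 0 ? -dc : 0;
      const int c1 = dc > 0 ? W - dc : W;
      for (int c = c0; c < c1; ++c)
        k_axpy(r1 - r0, wv, dout.colptr(c) + r0, dx.colptr(c + dc) + r0 + dr);
    }
  }
}

// -------------------------------------------------------- conv layers ----
struct Conv2d {
  PTensor W, b;
  int k = 3, ci = 0, co = 0;
  void build(int ci_, int co_, int k_, const std::string& nm, XRng& rng) {
    ci = ci_; co = co_; k = k_;
    W.init(ci * k * k, co, nm + "_w");
    b.init(co, 1, nm + "_b");
    const double sd = std::sqrt(2.0 / (ci * k * k));
    for (arma::uword i = 0; i < W.w.n_elem; ++i)
      W.w(i) = (float)(rng.gauss() * sd);
  }
  void forward(const Batch& x, Batch& out) const {
    out.resize(x.size());
    for (size_t n = 0; n < x.size(); ++n)
      conv_fwd(x[n], W.w, b.w, k, out[n]);
  }
  void backward(const Batch& x, const Batch& dout, Batch& dx,
                bool need_dx = true) {
    dx.resize(x.size());
    for (size_t n = 0; n < x.size(); ++n) {
      conv_bwd_w(x[n], k, dout[n], W.g, b.g);
      if (need_dx) conv_bwd_x(W.w, k, ci, dout[n], dx[n]);
    }
  }
};

struct BatchNorm {
  PTensor gamma, beta;
  fvec rmean, rvar;
  float momentum = 0.1f, eps = 1e-5f;
  Batch xhat;                        // train cache
  fvec invstd;
  double mcount = 0;
  void build(int C, const std::string& nm) {
    gamma.init(C, 1, nm + "_gamma");
    beta.init(C, 1, nm + "_beta");
    gamma.w.ones();
    rmean.zeros(C); rvar.ones(C);
  }
  void forward(const Batch& x, Batch& out, bool train) {
    ProfScope ps_("bn");
    const int C = x[0].n_slices;
    out.resize(x.size());
    for (size_t n = 0; n < x.size(); ++n)
      out[n].set_size(x[n].n_rows, x[n].n_cols, C);
    if (train) {
      xhat.resize(x.size());
      for (size_t n = 0; n < x.size(); ++n)
        xhat[n].set_size(x[n].n_rows, x[n].n_cols, C);
      invstd.set_size(C);
      double m = 0;
      for (size_t n = 0; n < x.size(); ++n) m += x[n].n_rows * x[n].n_cols;
      mcount = m;
      for (int c = 0; c < C; ++c) {
        double s = 0, s2 = 0;
        for (size_t n = 0; n < x.size(); ++n)
          k_sum_sumsq((int)(x[n].n_rows * x[n].n_cols), x[n].slice_memptr(c),
                      &s, &s2);
        const double mu = s / m;
        double var = s2 / m - mu * mu;
        if (var < 0) var = 0;
        const float is = (float)(1.0 / std::sqrt(var + eps));
        invstd(c) = is;
        rmean(c) = (1 - momentum) * rmean(c) + momentum * (float)mu;
        const double varu = m > 1 ? var * m / (m - 1) : var;
        rvar(c) = (1 - momentum) * rvar(c) + momentum * (float)varu;
        for (size_t n = 0; n < x.size(); ++n)
          k_bn_apply((int)(x[n].n_rows * x[n].n_cols), x[n].slice_memptr(c),
                     (float)mu, is, gamma.w(c), beta.w(c),
                     xhat[n].slice_memptr(c), out[n].slice_memptr(c));
      }
    } else {
      for (int c = 0; c < C; ++c) {
        const float is = 1.0f / std::sqrt(rvar(c) + eps);
        for (size_t n = 0; n < x.size(); ++n)
          k_bn_eval((int)(x[n].n_rows * x[n].n_cols), x[n].slice_memptr(c),
                    rmean(c), is, gamma.w(c), beta.w(c),
                    out[n].slice_memptr(c));
      }
    }
  }
  void backward(const Batch& dout, Batch& dx) {
    ProfScope ps_("bn");
    const int C = dout[0].n_slices;
    dx.resize(dout.size());
    for (size_t n = 0; n < dout.size(); ++n)
      dx[n].set_size(dout[n].n_rows, dout[n].n_cols, C);
    const double m = mcount;
    for (int c = 0; c < C; ++c) {
      double sd = 0, sdh = 0;
      for (size_t n = 0; n < dout.size(); ++n)
        k_bn_bwd_sums((int)(dout[n].n_rows * dout[n].n_cols),
                      dout[n].slice_memptr(c), xhat[n].slice_memptr(c),
                      &sd, &sdh);
      gamma.g(c) += (float)sdh;
      beta.g(c) += (float)sd;
      const float a = gamma.w(c) * invstd(c) / (float)m;
      for (size_t n = 0; n < dout.size(); ++n)
        k_bn_bwd_apply((int)(dout[n].n_rows * dout[n].n_cols),
                       dout[n].slice_memptr(c), xhat[n].slice_memptr(c), a,
                       (float)m, (float)sd, (float)sdh,
                       dx[n].slice_memptr(c));
    }
    xhat.clear();
  }
};

// conv 3x3 -> BN -> ReLU
struct ConvBlock {
  Conv2d conv;
  BatchNorm bn;
  BatchP in_x, out_y;
  void build(int ci, int co, const std::string& nm, XRng& rng) {
    conv.build(ci, co, 3, nm + "_conv", rng);
    bn.build(co, nm + "_bn");
  }
  BatchP forward(const BatchP& x, bool train) {
    Batch z, y;
    conv.forward(*x, z);
    bn.forward(z, y, train);
    for (size_t n = 0; n < y.size(); ++n)
      k_relu((int)y[n].n_elem, y[n].memptr());
    BatchP out = std::make_shared<Batch>(std::move(y));
    if (train) { in_x = x; out_y = out; }
    return out;
  }
  void backward(Batch& dout, Batch& dx, bool need_dx = true) {
    for (size_t n = 0; n < dout.size(); ++n)
      k_relu_bwd((int)dout[n].n_elem, (*out_y)[n].memptr(), dout[n].memptr());
    Batch dz;
    bn.backward(dout, dz);
    conv.backward(*in_x, dz, dx, need_dx);
    in_x.reset(); out_y.reset();
  }
};

struct MaxPool2 {
  BatchP in_x;
  BatchP forward(const BatchP& x, bool train) {
    Batch out(x->size());
    for (size_t n = 0; n < x->size(); ++n) {
      const fcube& xs = (*x)[n];
      const int H = xs.n_rows / 2, W = xs.n_cols / 2, C = xs.n_slices;
      out[n].set_size(H, W, C);
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W; ++j) {
          const float* c0 = xs.slice_colptr(c, 2 * j);
          const float* c1 = xs.slice_colptr(c, 2 * j + 1);
          float* o = out[n].slice_colptr(c, j);
          for (int i = 0; i < H; ++i) {
            const float a = std::max(c0[2 * i], c0[2 * i + 1]);
            const float b = std::max(c1[2 * i], c1[2 * i + 1]);
            o[i] = std::max(a, b);
          }
        }
    }
    if (train) in_x = x;
    return std::make_shared<Batch>(std::move(out));
  }
  void backward(const Batch& dout, Batch& dx) {
    dx.resize(dout.size());
    for (size_t n = 0; n < dout.size(); ++n) {
      const fcube& xs = (*in_x)[n];
      dx[n].zeros(xs.n_rows, xs.n_cols, xs.n_slices);
      const int H = dout[n].n_rows, W = dout[n].n_cols, C = dout[n].n_slices;
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W; ++j) {
          const float* c0 = xs.slice_colptr(c, 2 * j);
          const float* c1 = xs.slice_colptr(c, 2 * j + 1);
          float* d0 = dx[n].slice_colptr(c, 2 * j);
          float* d1 = dx[n].slice_colptr(c, 2 * j + 1);
          const float* dz = dout[n].slice_colptr(c, j);
          for (int i = 0; i < H; ++i) {
            // first max in scan order (rows within column, then next col)
            float m = c0[2 * i]; int which = 0;
            if (c0[2 * i + 1] > m) { m = c0[2 * i + 1]; which = 1; }
            if (c1[2 * i] > m) { m = c1[2 * i]; which = 2; }
            if (c1[2 * i + 1] > m) { which = 3; }
            switch (which) {
              case 0: d0[2 * i] += dz[i]; break;
              case 1: d0[2 * i + 1] += dz[i]; break;
              case 2: d1[2 * i] += dz[i]; break;
              default: d1[2 * i + 1] += dz[i];
            }
          }
        }
    }
    in_x.reset();
  }
};

// bilinear 2x upsampling, align_corners = false.
// Output columns 2m/2m+1 mix input columns m and m-1/m+1 with weights
// 0.75/0.25; the same pattern applies along rows; borders replicate.
struct Upsample2 {
  int inH = 0, inW = 0;
  BatchP forward(const BatchP& x) {
    ProfScope ps_("upsample");
    inH = (*x)[0].n_rows; inW = (*x)[0].n_cols;
    const int W2 = inW * 2;
    Batch out(x->size());
    fvec ucol(inH);
    for (size_t n = 0; n < x->size(); ++n) {
      const fcube& xs = (*x)[n];
      const int C = xs.n_slices;
      out[n].set_size(inH * 2, W2, C);
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W2; ++j) {
          const int i0 = j / 2;
          const int jm = (j % 2 == 0) ? std::max(0, i0 - 1)
                                      : std::min(inW - 1, i0 + 1);
          k_scale_add2(inH, 0.75f, xs.slice_colptr(c, i0), 0.25f,
                       xs.slice_colptr(c, jm), ucol.memptr());
          const float* u = ucol.memptr();
          float* o = out[n].slice_colptr(c, j);
          o[0] = u[0];
          for (int i = 1; i < inH; ++i) {
            o[2 * i - 1] = 0.75f * u[i - 1] + 0.25f * u[i];
            o[2 * i] = 0.25f * u[i - 1] + 0.75f * u[i];
          }
          o[2 * inH - 1] = u[inH - 1];
        }
    }
    return std::make_shared<Batch>(std::move(out));
  }
  void backward(const Batch& dout, Batch& dx) {
    ProfScope ps_("upsample");
    const int W2 = inW * 2;
    dx.resize(dout.size());
    fvec dcol(inH);
    for (size_t n = 0; n < dout.size(); ++n) {
      const int C = dout[n].n_slices;
      dx[n].zeros(inH, inW, C);
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < W2; ++j) {
          const float* d = dout[n].slice_colptr(c, j);
          float* u = dcol.memptr();
          std::memset(u, 0, sizeof(float) * inH);
          u[0] += d[0];
          for (int i = 1; i < inH; ++i) {
            u[i - 1] += 0.75f * d[2 * i - 1] + 0.25f * d[2 * i];
            u[i] += 0.25f * d[2 * i - 1] + 0.75f * d[2 * i];
          }
          u[inH - 1] += d[2 * inH - 1];
          const int i0 = j / 2;
          const int jm = (j % 2 == 0) ? std::max(0, i0 - 1)
                                      : std::min(inW - 1, i0 + 1);
          k_axpy(inH, 0.75f, u, dx[n].slice_colptr(c, i0));
          k_axpy(inH, 0.25f, u, dx[n].slice_colptr(c, jm));
        }
    }
  }
};

// ---------------------------------------------------------------- FLAB ----
// Per-channel attention: parallel feature-aware (pool pair -> 1x1 conv ->
// ReLU -> 1x1 conv) and location-aware (pool pair -> 7x7 conv) branches,
// additive fusion, sigmoid gating, then a 3x3 conv halving the channels.
struct FlabBranch {
  PTensor f1w, f1b, f2w, f2b, locw, locb;
  void build(int r, const std::string& nm, XRng& rng) {
    f1w.init(r, 2, nm + "_f1_w");
    f1b.init(r, 1, nm + "_f1_b");
    f2w.init(r, 1, nm + "_f2_w");
    f2b.init(1, 1, nm + "_f2_b");
    locw.init(2 * 49, 1, nm + "_loc_w");
    locb.init(1, 1, nm + "_loc_b");
    const double s1 = 1.0, s2 = std::sqrt(2.0 / r);
    const double sl = std::sqrt(2.0 / 98.0);
    for (arma::uword i = 0; i < f1w.w.n_elem; ++i) f1w.w(i) = (float)(rng.gauss() * s1);
    for (arma::uword i = 0; i < f2w.w.n_elem; ++i) f2w.w(i) = (float)(rng.gauss() * s2);
    for (arma::uword i = 0; i < locw.w.n_elem; ++i) locw.w(i) = (float)(rng.gauss() * sl);
  }
};

struct Flab {
  int pool_k = 3, r = 2, C = 0;
  bool share = true;
  std::vector<FlabBranch> br;     // size 1 (shared) or C
  Conv2d proj;                    // 3x3, C -> C/2, plain conv + bias
  // caches (train mode): per-image cubes, one slice per channel
  BatchP in_x;
  std::vector<fcube> avgB, maxB, gateB;
  std::vector<arma::Cube<int>> argB;
  BatchP gatedB;

  void build(int C_, int pool_k_, int r_, bool share_, const std::string& nm,
             XRng& rng) {
    C = C_; pool_k = pool_k_; r = r_; share = share_;
    const int nb = share ? 1 : C;
    br.resize(nb);
    for (int i = 0; i < nb; ++i)
      br[i].build(r, share ? nm : nm + "_ch" + std::to_string(i + 1), rng);
    proj.build(C, C / 2, 3, nm + "_proj", rng);
  }

  BatchP forward(const BatchP& x, bool train) {
    ProfScope ps_("flab_fwd");
    const size_t N = x->size();
    const int H = (*x)[0].n_rows, W = (*x)[0].n_cols;
    const int np = H * W;
    Batch gated(N);
    if (train) {
      avgB.resize(N); maxB.resize(N); gateB.resize(N); argB.resize(N);
      for (size_t n = 0; n < N; ++n) {
        avgB[n].set_size(H, W, C); maxB[n].set_size(H, W, C);
        gateB[n].set_size(H, W, C); argB[n].set_size(H, W, C);
      }
    }
    fmat avg, mx, pre(H, W), t1, t2;
    arma::Mat<int> argtmp;
    std::vector<short> argc;
    if (!train) { avg.set_size(H, W); mx.set_size(H, W); argtmp.set_size(H, W); }
    for (size_t n = 0; n < N; ++n) {
      gated[n].set_size(H, W, C);
      for (int i = 0; i < C; ++i) {
        const fmat xs(const_cast<float*>((*x)[n].slice_memptr(i)), H, W, false, true);
        float* pa = train ? avgB[n].slice_memptr(i) : avg.memptr();
        float* pm = train ? maxB[n].slice_memptr(i) : mx.memptr();
        int* pi = train ? argB[n].slice_memptr(i) : argtmp.memptr();
        pool_pair_fwd(xs, pool_k, pa, pm, pi, t1, t2, argc);
        const FlabBranch& B = br[share ? 0 : i];
        // location branch into 'pre'
        pre.fill(B.locb.w(0));
        const fmat avgm(pa, H, W, false, true);
        const fmat maxm(pm, H, W, false, true);
        conv1out_accum(avgm, B.locw.w.memptr(), 7, pre);
        conv1out_accum(maxm, B.locw.w.memptr() + 49, 7, pre);
        // feature branch fused into the pre-activation
        float* pp = pre.memptr();
        for (int q = 0; q < np; ++q) {
          float fsum = B.f2b.w(0);
          for (int j = 0; j < r; ++j) {
            float h = B.f1w.w(j, 0) * pa[q] + B.f1w.w(j, 1) * pm[q] + B.f1b.w(j);
            if (h > 0) fsum += B.f2w.w(j) * h;
          }
          pp[q] += fsum;
        }
        float* pg = train ? gateB[n].slice_memptr(i) : pre.memptr();
        k_sigmoid(np, pp, pg);
        const float* px = xs.memptr();
        float* po = gated[n].slice_memptr(i);
        for (int q = 0; q < np; ++q) po[q] = pg[q] * px[q];
      }
    }
    BatchP gp = std::make_shared<Batch>(std::move(gated));
    Batch out;
    proj.forward(*gp, out);
    if (train) { in_x = x; gatedB = gp; }
    return std::make_shared<Batch>(std::move(out));
  }

  void backward(const Batch& dout, Batch& dx) {
    ProfScope ps_("flab_bwd");
    const size_t N = dout.size();
    Batch dgated;
    proj.backward(*gatedB, dout, dgated);
    const int H = dgated[0].n_rows, W = dgated[0].n_cols;
    const int np = H * W;
    dx.resize(N);
    fmat dpre(H, W), davg(H, W), dmx(H, W), t1;
    for (size_t n = 0; n < N; ++n) {
      dx[n].set_size(H, W, C);
      for (int i = 0; i < C; ++i) {
        FlabBranch& B = br[share ? 0 : i];
        const fmat xs(const_cast<float*>((*in_x)[n].slice_memptr(i)), H, W, false, true);
        const float* px = xs.memptr();
        const float* pg = gateB[n].slice_memptr(i);
        const float* pd = dgated[n].slice_memptr(i);
        const float* pa = avgB[n].slice_memptr(i);
        const float* pm = maxB[n].slice_memptr(i);
        float* pdx = dx[n].slice_memptr(i);
        float* pdp = dpre.memptr();
        float* pda = davg.memptr();
        float* pdm = dmx.memptr();
        // fused pointwise backward: gate, sigmoid, feature branch
        double acc_f2b = 0;
        std::vector<double> acc_f2w(r, 0), acc_f1b(r, 0),
            acc_f1a(r, 0), acc_f1m(r, 0);
        for (int q = 0; q < np; ++q) {
          const float g = pg[q];
          const float dgate = pd[q] * px[q];
          pdx[q] = pd[q] * g;
          const float dp = dgate * g * (1.0f - g);
          pdp[q] = dp;
          acc_f2b += dp;
          float da = 0, dm = 0;
          for (int j = 0; j < r; ++j) {
            const float h = B.f1w.w(j, 0) * pa[q] + B.f1w.w(j, 1) * pm[q] +
                            B.f1b.w(j);
            if (h > 0) {
              acc_f2w[j] += (double)dp * h;
              const float dh = dp * B.f2w.w(j);
              acc_f1a[j] += (double)dh * pa[q];
              acc_f1m[j] += (double)dh * pm[q];
              acc_f1b[j] += dh;
              da += dh * B.f1w.w(j, 0);
              dm += dh * B.f1w.w(j, 1);
            }
          }
          pda[q] = da;
          pdm[q] = dm;
        }
        B.f2b.g(0) += (float)acc_f2b;
        for (int j = 0; j < r; ++j) {
          B.f2w.g(j) += (float)acc_f2w[j];
          B.f1w.g(j, 0) += (float)acc_f1a[j];
          B.f1w.g(j, 1) += (float)acc_f1m[j];
          B.f1b.g(j) += (float)acc_f1b[j];
        }
        // location branch backward
        B.locb.g(0) += (float)k_sumd(np, pdp);
        const fmat avgm(const_cast<float*>(pa), H, W, false, true);
        const fmat maxm(const_cast<float*>(pm), H, W, false, true);
        conv1out_dw(avgm, dpre, 7, B.locw.g.memptr());
        conv1out_dw(maxm, dpre, 7, B.locw.g.memptr() + 49);
        conv1out_dx(dpre, B.locw.w.memptr(), 7, davg);
        conv1out_dx(dpre, B.locw.w.memptr() + 49, 7, dmx);
        // pooling backward into the input-channel gradient
        fmat dxi(pdx, H, W, false, true);
        pool_pair_bwd(pool_k, davg, dmx, argB[n].slice_memptr(i), dxi, t1);
      }
    }
    in_x.reset(); gatedB.reset();
  }
};

// ---------------------------------------------------------------- UNet ----
struct UNetConfig {
  int in_ch = 1, num_classes = 2, base = 64;
  bool use_flab = true;
  int pool_k = 3, hidden_r = 2;
  bool flab_share = true;
};

struct UNet {
  UNetConfig cfg;
  std::vector<ConvBlock> enc;   // 10: stage s blocks 2s, 2s+1
  std::vector<MaxPool2> pool;   // 4
  std::vector<Upsample2> up;    // 4
  std::vector<Flab> flab;       // 4 (if use_flab)
  std::vector<ConvBlock> dec;   // 8: level l blocks 2l, 2l+1
  Conv2d head;
  long adam_t = 0;
  std::vector<BatchP> feats;    // encoder stage outputs
  std::vector<int> cat_up_ch;
  BatchP head_in;

  int enc_ch(int s) const { return cfg.base << s; }          // s = 0..4
  int dec_ch(int l) const { return cfg.base << (3 - l); }    // l = 0..3
  int cat_ch(int l) const { return 3 * dec_ch(l); }

  void build(int seed) {
    XRng rng((uint32_t)seed);
    enc.resize(10); pool.resize(4); up.resize(4); dec.resize(8);
    if (cfg.use_flab) flab.resize(4);
    int ci = cfg.in_ch;
    for (int s = 0; s < 5; ++s) {
      const int co = enc_ch(s);
      enc[2 * s].build(ci, co, "enc" + std::to_string(s + 1) + "_block1", rng);
      enc[2 * s + 1].build(co, co, "enc" + std::to_string(s + 1) + "_block2", rng);
      ci = co;
    }
    for (int l = 0; l < 4; ++l) {
      const int cc = cat_ch(l);
      const int dc = dec_ch(l);
      const std::string nm = "dec" + std::to_string(l + 1);
      int bi = cc;
      if (cfg.use_flab) {
        flab[l].build(cc, cfg.pool_k, cfg.hidden_r, cfg.flab_share,
                      "flab" + std::to_string(l + 1), rng);
        bi = cc / 2;
      }
      dec[2 * l].build(bi, dc, nm + "_block1", rng);
      dec[2 * l + 1].build(dc, dc, nm + "_block2", rng);
    }
    head.build(cfg.base, cfg.num_classes, 1, "head", rng);
  }

  static BatchP concat(const Batch& a, const Batch& b) {
    Batch out(a.size());
    for (size_t n = 0; n < a.size(); ++n) {
      out[n].set_size(a[n].n_rows, a[n].n_cols, a[n].n_slices + b[n].n_slices);
      std::memcpy(out[n].memptr(), a[n].memptr(), sizeof(float) * a[n].n_elem);
      std::memcpy(out[n].memptr() + a[n].n_elem, b[n].memptr(),
                  sizeof(float) * b[n].n_elem);
    }
    return std::make_shared<Batch>(std::move(out));
  }

  BatchP encode(const BatchP& x, bool train) {
    feats.assign(5, nullptr);
    BatchP s = x;
    for (int st = 0; st < 5; ++st) {
      if (st > 0) s = pool[st - 1].forward(s, train);
      s = enc[2 * st].forward(s, train);
      s = enc[2 * st + 1].forward(s, train);
      feats[st] = s;
    }
    return feats[4];
  }

  // skips deepest-first: skips[0] pairs with the first (deepest) decoder
  BatchP decode(BatchP d, const std::vector<BatchP>& skips, bool train) {
    cat_up_ch.assign(4, 0);
    for (int l = 0; l < 4; ++l) {
      cat_up_ch[l] = (*d)[0].n_slices;
      BatchP u = up[l].forward(d);
      BatchP cat = concat(*u, *skips[l]);
      u.reset();
      BatchP m = cfg.use_flab ? flab[l].forward(cat, train) : cat;
      cat.reset();
      m = dec[2 * l].forward(m, train);
      d = dec[2 * l + 1].forward(m, train);
    }
    return d;
  }

  BatchP forward(const BatchP& x, bool train, Batch& logits) {
    BatchP bottom = encode(x, train);
    std::vector<BatchP> skips = {feats[3], feats[2], feats[1], feats[0]};
    BatchP d = decode(bottom, skips, train);
    head.forward(*d, logits);
    if (train) head_in = d;
    else feats.assign(5, nullptr);
    return d;
  }

  void backward(Batch& dlogits) {
    std::vector<Batch> pend(5);
    Batch dd;
    head.backward(*head_in, dlogits, dd);
    head_in.reset();
    auto add_into = [](Batch& acc, Batch& add) {
      if (acc.empty()) { acc = std::move(add); return; }
      for (size_t n = 0; n < acc.size(); ++n)
        k_add((int)acc[n].n_elem, add[n].memptr(), acc[n].memptr());
    };
    for (int l = 3; l >= 0; --l) {
      Batch dm, dcatb;
      dec[2 * l + 1].backward(dd, dm);
      dec[2 * l].backward(dm, dcatb);
      Batch dcat;
      if (cfg.use_flab) flab[l].backward(dcatb, dcat);
      else dcat = std::move(dcatb);
      const int cu = cat_up_ch[l];
      Batch dup(dcat.size()), dskip(dcat.size());
      for (size_t n = 0; n < dcat.size(); ++n) {
        const int H = dcat[n].n_rows, W = dcat[n].n_cols;
        const int cs = dcat[n].n_slices - cu;
        dup[n].set_size(H, W, cu);
        dskip[n].set_size(H, W, cs);
        std::memcpy(dup[n].memptr(), dcat[n].memptr(),
                    sizeof(float) * dup[n].n_elem);
        std::memcpy(dskip[n].memptr(), dcat[n].memptr() + dup[n].n_elem,
                    sizeof(float) * dskip[n].n_elem);
      }
      dcat.clear();
      add_into(pend[3 - l], dskip);
      up[l].backward(dup, dd);
    }
    add_into(pend[4], dd);
    for (int st = 4; st >= 0; --st) {
      Batch g = std::move(pend[st]), g1, g2;
      enc[2 * st + 1].backward(g, g1);
      enc[2 * st].backward(g1, g2, st > 0);  // no input grad for the image
      if (st > 0) {
        Batch gp;
        pool[st - 1].backward(g2, gp);
        add_into(pend[st - 1], gp);
      }
    }
    feats.assign(5, nullptr);
  }

  void collect(std::vector<PTensor*>& ps) {
    for (auto& b : enc) {
      ps.push_back(&b.conv.W); ps.push_back(&b.conv.b);
      ps.push_back(&b.bn.gamma); ps.push_back(&b.bn.beta);
    }
    for (auto& f : flab) {
      for (auto& B : f.br) {
        ps.push_back(&B.f1w); ps.push_back(&B.f1b);
        ps.push_back(&B.f2w); ps.push_back(&B.f2b);
        ps.push_back(&B.locw); ps.push_back(&B.locb);
      }
      ps.push_back(&f.proj.W); ps.push_back(&f.proj.b);
    }
    for (auto& b : dec) {
      ps.push_back(&b.conv.W); ps.push_back(&b.conv.b);
      ps.push_back(&b.bn.gamma); ps.push_back(&b.bn.beta);
    }
    ps.push_back(&head.W); ps.push_back(&head.b);
  }

  void zero_grads() {
    std::vector<PTensor*> ps;
    collect(ps);
    for (auto* p : ps) p->g.zeros();
  }

  void adam_step(double lr, double b1, double b2, double eps) {
    ProfScope ps_("adam");
    ++adam_t;
    std::vector<PTensor*> ps;
    collect(ps);
    const double bc1 = 1.0 - std::pow(b1, (double)adam_t);
    const double bc2 = 1.0 - std::pow(b2, (double)adam_t);
    for (auto* p : ps) {
      float* w = p->w.memptr();
      float* g = p->g.memptr();
      float* m = p->m.memptr();
      float* v = p->v.memptr();
      const size_t n = p->w.n_elem;
      for (size_t i = 0; i < n; ++i) {
        m[i] = (float)(b1 * m[i] + (1 - b1) * g[i]);
        v[i] = (float)(b2 * v[i] + (1 - b2) * (double)g[i] * g[i]);
        const double mh = m[i] / bc1, vh = v[i] / bc2;
        w[i] -= (float)(lr * mh / (std::sqrt(vh) + eps));
      }
    }
  }
};

// ------------------------------------------------------- loss (joint) ----
// CE: mean over all pixels of -log p_y (p clamped at 1e-7).
// Dice: soft, on the positive class, per image then averaged over images.
struct LossOut { double joint, dice, ce; };

// generic K-class path (rarely used; the 2-class head takes the fast path)
static LossOut joint_loss_grad(const Batch& probs,
                               const std::vector<arma::Mat<int>>& y,
                               double w1, double w2, double smooth,
                               Batch& dlogits) {
  const size_t N = probs.size();
  const int K = probs[0].n_slices;
  const double eps = 1e-7;
  double tot_px = 0;
  for (size_t n = 0; n < N; ++n) tot_px += probs[n].n_rows * probs[n].n_cols;
  double ce = 0, dice = 0;
  dlogits.resize(N);
  std::vector<double> gk(K);
  for (size_t n = 0; n < N; ++n) {
    const int H = probs[n].n_rows, W = probs[n].n_cols;
    const int np = H * W;
    dlogits[n].set_size(H, W, K);
    const int* yp = y[n].memptr();
    const float* p1 = probs[n].slice_memptr(1);
    double S1 = 0, S2 = 0, I = 0;
    for (int q = 0; q < np; ++q) {
      S1 += p1[q];
      if (yp[q] == 1) { S2 += 1; I += p1[q]; }
    }
    const double den = S1 + S2 + smooth;
    dice += 1.0 - (2.0 * I + smooth) / den;
    const double dice_c = (2.0 * I + smooth) / (den * den) / (double)N;
    const double dice_t = 2.0 / den / (double)N;
    for (int q = 0; q < np; ++q) {
      const int lab = yp[q];
      double dot = 0;
      for (int c = 0; c < K; ++c) {
        const double pc = *(probs[n].slice_memptr(c) + q);
        double g = 0;
        if (c == 1) g += w1 * (dice_c - (lab == 1 ? dice_t : 0.0));
        if (c == lab) {
          const double pl = std::max(pc, eps);
          ce += -std::log(pl);
          g += w2 * (-1.0 / pl) / tot_px;
        }
        gk[c] = g;
        dot += g * pc;
      }
      for (int c = 0; c < K; ++c) {
        const double pc = *(probs[n].slice_memptr(c) + q);
        *(dlogits[n].slice_memptr(c) + q) = (float)(pc * (gk[c] - dot));
      }
    }
  }
  ce /= tot_px;
  dice /= (double)N;
  LossOut out;
  out.ce = ce; out.dice = dice; out.joint = w1 * dice + w2 * ce;
  return out;
}

// fast path for the two-class head
static LossOut joint_loss_grad2(const Batch& probs,
                                const std::vector<arma::Mat<int>>& y,
                                double w1, double w2, double smooth,
                                Batch& dlogits) {
  ProfScope ps_("loss");
  const size_t N = probs.size();
  const double eps = 1e-7;
  double tot_px = 0;
  for (size_t n = 0; n < N; ++n) tot_px += probs[n].n_rows * probs[n].n_cols;
  double ce = 0, dice = 0;
  dlogits.resize(N);
  for (size_t n = 0; n < N; ++n) {
    const int np = (int)(probs[n].n_rows * probs[n].n_cols);
    dlogits[n].set_size(probs[n].n_rows, probs[n].n_cols, 2);
    const int* yp = y[n].memptr();
    const float* p0 = probs[n].slice_memptr(0);
    const float* p1 = probs[n].slice_memptr(1);
    double S1 = 0, S2 = 0, I = 0;
    for (int q = 0; q < np; ++q) {
      S1 += p1[q];
      if (yp[q] == 1) { S2 += 1; I += p1[q]; }
    }
    const double den = S1 + S2 + smooth;
    dice += 1.0 - (2.0 * I + smooth) / den;
    const double dice_c = (2.0 * I + smooth) / (den * den) / (double)N;
    const double dice_t = 2.0 / den / (double)N;
    float* dz0 = dlogits[n].slice_memptr(0);
    float* dz1 = dlogits[n].slice_memptr(1);
    for (int q = 0; q < np; ++q) {
      const int lab = yp[q];
      const double pl = std::max((double)(lab == 1 ? p1[q] : p0[q]), eps);
      ce += -std::log(pl);
      const double g_lab = w2 * (-1.0 / pl) / tot_px;
      double g0 = 0, g1 = w1 * (dice_c - (lab == 1 ? dice_t : 0.0));
      if (lab == 1) g1 += g_lab; else g0 += g_lab;
      const double dot = g0 * p0[q] + g1 * p1[q];
      dz0[q] = (float)(p0[q] * (g0 - dot));
      dz1[q] = (float)(p1[q] * (g1 - dot));
    }
  }
  ce /= tot_px;
  dice /= (double)N;
  LossOut out;
  out.ce = ce; out.dice = dice; out.joint = w1 * dice + w2 * ce;
  return out;
}

static void softmax_probs(const Batch& logits, Batch& probs) {
  ProfScope ps_("softmax");
  probs.resize(logits.size());
  for (size_t n = 0; n < logits.size(); ++n) {
    const int H = logits[n].n_rows, W = logits[n].n_cols, K = logits[n].n_slices;
    const int np = H * W;
    probs[n].set_size(H, W, K);
    if (K == 2) {
      const float* z0 = logits[n].slice_memptr(0);
      const float* z1 = logits[n].slice_memptr(1);
      float* p0 = probs[n].slice_memptr(0);
      float* p1 = probs[n].slice_memptr(1);
      for (int q = 0; q < np; ++q) {
        const double e = std::exp((double)z1[q] - z0[q]);
        const double v = e / (1.0 + e);
        p1[q] = (float)v;
        p0[q] = (float)(1.0 - v);
      }
      continue;
    }
    for (int q = 0; q < np; ++q) {
      float mx = *(logits[n].slice_memptr(0) + q);
      for (int c = 1; c < K; ++c)
        mx = std::max(mx, *(logits[n].slice_memptr(c) + q));
      double s = 0;
      for (int c = 0; c < K; ++c) {
        const double e = std::exp((double)*(logits[n].slice_memptr(c) + q) - mx);
        *(probs[n].slice_memptr(c) + q) = (float)e;
        s += e;
      }
      for (int c = 0; c < K; ++c)
        *(probs[n].slice_memptr(c) + q) =
          (float)(*(probs[n].slice_memptr(c) + q) / s);
    }
  }
}

// ------------------------------------------------- R <-> C++ adapters ----
static void check_dims4(const NumericVector& x) {
  if (Rf_isNull(x.attr("dim"))) stop("expected a 4-D (N, C, H, W) array");
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (N, C, H, W) array");
}

static BatchP r_to_batch(const NumericVector& x) {
  ProfScope ps_("convert");
  check_dims4(x);
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], H = d[2], W = d[3];
  BatchP out = std::make_shared<Batch>(N);
  const double* xp = REAL(x);
  for (int n = 0; n < N; ++n) {
    (*out)[n].set_size(H, W, C);
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        float* dst = (*out)[n].slice_colptr(c, w);
        const double* src = xp + n + (size_t)N * (c + (size_t)C * (size_t)H * w);
        for (int h = 0; h < H; ++h) dst[h] = (float)src[(size_t)N * C * h];
      }
  }
  return out;
}

static NumericVector batch_to_r(const Batch& b) {
  ProfScope ps_("convert");
  const int N = b.size(), C = b[0].n_slices, H = b[0].n_rows, W = b[0].n_cols;
  NumericVector out((R_xlen_t)N * C * H * W);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const float* src = b[n].slice_colptr(c, w);
        double* dst = op + n + (size_t)N * (c + (size_t)C * (size_t)H * w);
        for (int h = 0; h < H; ++h) dst[(size_t)N * C * h] = src[h];
      }
  out.attr("dim") = IntegerVector::create(N, C, H, W);
  return out;
}

static std::vector<arma::Mat<int>> r_to_masks(const IntegerVector& y) {
  if (Rf_isNull(y.attr("dim"))) stop("expected a 3-D (N, H, W) mask array");
  IntegerVector d = y.attr("dim");
  if (d.size() != 3) stop("expected a 3-D (N, H, W) mask array");
  const int N = d[0], H = d[1], W = d[2];
  std::vector<arma::Mat<int>> out(N);
  const int* yp = INTEGER(y);
  for (int n = 0; n < N; ++n) {
    out[n].set_size(H, W);
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        out[n](h, w) = yp[n + (size_t)N * (h + (size_t)H * w)];
  }
  return out;
}

static UNetConfig parse_cfg(const List& cfg) {
  UNetConfig c;
  c.in_ch = as<int>(cfg["in_channels"]);
  c.num_classes = as<int>(cfg["num_classes"]);
  c.base = as<int>(cfg["base_width"]);
  c.use_flab = as<bool>(cfg["use_flab"]);
  c.pool_k = as<int>(cfg["pool_kernel"]);
  c.hidden_r = as<int>(cfg["hidden_width"]);
  c.flab_share = as<bool>(cfg["share_across_channels"]);
  if (c.base < 2 || c.base % 2 != 0) stop("base_width must be an even integer >= 2");
  if (c.num_classes < 2) stop("num_classes must be >= 2");
  if (c.pool_k < 1 || c.pool_k % 2 == 0)
    stop("feature-location attention block: pool_kernel must be an odd positive integer");
  if (c.hidden_r < 1) stop("hidden_width must be >= 1");
  return c;
}

static void check_input(const UNet& net, const Batch& x) {
  const int H = x[0].n_rows, W = x[0].n_cols, C = x[0].n_slices;
  if (C != net.cfg.in_ch)
    stop("input has %d channels but the network expects in_channels = %d", C,
         net.cfg.in_ch);
  if (H % 16 != 0 || W % 16 != 0)
    stop("input spatial dims (%d x %d) must be divisible by 16 (four 2x poolings); use the resize/pad policy upstream", H, W);
}

// ------------------------------------------------------------ exports ----
static NumericVector convw_to_r(const fmat& W, int ci, int k);

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create_cpp(List cfg, int seed) {
  UNet* net = new UNet();
  net->cfg = parse_cfg(cfg);
  net->build(seed);
  XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export(name = ".unet_forward")]]
List unet_forward_cpp(SEXP ptr_, NumericVector x, bool want_stages = false) {
  XPtr<UNet> net(ptr_);
  BatchP xb = r_to_batch(x);
  check_input(*net, *xb);
  Batch logits;
  List stages;
  if (!want_stages) {
    net->forward(xb, false, logits);
  } else {
    BatchP bottom = net->encode(xb, false);
    List ef(5);
    for (int s = 0; s < 5; ++s) ef[s] = batch_to_r(*net->feats[s]);
    std::vector<BatchP> skips = {net->feats[3], net->feats[2], net->feats[1],
                                 net->feats[0]};
    List lev(4);
    BatchP d = bottom;
    for (int l = 0; l < 4; ++l) {
      BatchP u = net->up[l].forward(d);
      BatchP cat = UNet::concat(*u, *skips[l]);
      List li;
      li["upsampled"] = batch_to_r(*u);
      li["concat"] = batch_to_r(*cat);
      BatchP m = cat;
      if (net->cfg.use_flab) {
        m = net->flab[l].forward(cat, false);
        li["flab_out"] = batch_to_r(*m);
      }
      m = net->dec[2 * l].forward(m, false);
      d = net->dec[2 * l + 1].forward(m, false);
      li["out"] = batch_to_r(*d);
      lev[l] = li;
    }
    net->head.forward(*d, logits);
    stages["encoder"] = ef;
    stages["decoder"] = lev;
    net->feats.assign(5, nullptr);
  }
  Batch probs;
  softmax_probs(logits, probs);
  const int N = probs.size(), H = probs[0].n_rows, W = probs[0].n_cols,
            K = probs[0].n_slices;
  IntegerVector pred((R_xlen_t)N * H * W);
  int* pp = INTEGER(pred);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        int am = 0;
        float best = probs[n](h, w, 0);
        for (int c = 1; c < K; ++c)
          if (probs[n](h, w, c) > best) { best = probs[n](h, w, c); am = c; }
        pp[n + (size_t)N * (h + (size_t)H * w)] = am;
      }
  pred.attr("dim") = IntegerVector::create(N, H, W);
  List out;
  out["probabilities"] = batch_to_r(probs);
  out["predicted_mask"] = pred;
  out["logits"] = batch_to_r(logits);
  if (want_stages) out["stages"] = stages;
  return out;
}

// [[Rcpp::export(name = ".unet_train_step")]]
List unet_train_step_cpp(SEXP ptr_, NumericVector x, IntegerVector y,
                         double lr, double w1, double w2,
                         double beta1 = 0.9, double beta2 = 0.999,
                         double adam_eps = 1e-8, double smooth = 1.0) {
  XPtr<UNet> net(ptr_);
  BatchP xb = r_to_batch(x);
  check_input(*net, *xb);
  std::vector<arma::Mat<int>> yb = r_to_masks(y);
  Batch logits;
  net->forward(xb, true, logits);
  Batch probs, dlogits;
  softmax_probs(logits, probs);
  LossOut lo = (probs[0].n_slices == 2)
    ? joint_loss_grad2(probs, yb, w1, w2, smooth, dlogits)
    : joint_loss_grad(probs, yb, w1, w2, smooth, dlogits);
  net->zero_grads();
  net->backward(dlogits);
  net->adam_step(lr, beta1, beta2, adam_eps);
  return List::create(_["loss"] = lo.joint, _["dice_loss"] = lo.dice,
                      _["ce_loss"] = lo.ce);
}

// [[Rcpp::export(name = ".unet_loss_grads")]]
List unet_loss_grads_cpp(SEXP ptr_, NumericVector x, IntegerVector y,
                         double w1, double w2, double smooth = 1.0) {
  XPtr<UNet> net(ptr_);
  BatchP xb = r_to_batch(x);
  check_input(*net, *xb);
  std::vector<arma::Mat<int>> yb = r_to_masks(y);
  Batch logits;
  net->forward(xb, true, logits);
  Batch probs, dlogits;
  softmax_probs(logits, probs);
  LossOut lo = (probs[0].n_slices == 2)
    ? joint_loss_grad2(probs, yb, w1, w2, smooth, dlogits)
    : joint_loss_grad(probs, yb, w1, w2, smooth, dlogits);
  net->zero_grads();
  net->backward(dlogits);
  // export gradients in the same layout as .unet_get_weights: conv kernels
  // as (Cout, Cin, kh, kw) arrays, everything else flat
  List g;
  auto put_flat = [&](const PTensor& p) {
    NumericVector gv(p.g.n_elem);
    for (arma::uword i = 0; i < p.g.n_elem; ++i) gv[i] = p.g(i);
    if (p.g.n_cols > 1)
      gv.attr("dim") = IntegerVector::create(p.g.n_rows, p.g.n_cols);
    g[p.name] = gv;
  };
  auto put_conv = [&](const Conv2d& cv) {
    g[cv.W.name] = convw_to_r(cv.W.g, cv.ci, cv.k);
    put_flat(cv.b);
  };
  auto put_block = [&](ConvBlock& b) {
    put_conv(b.conv);
    put_flat(b.bn.gamma);
    put_flat(b.bn.beta);
  };
  for (auto& b : net->enc) put_block(b);
  for (auto& f : net->flab) {
    for (auto& B : f.br) {
      put_flat(B.f1w); put_flat(B.f1b);
      put_flat(B.f2w); put_flat(B.f2b);
      g[B.locw.name] = convw_to_r(B.locw.g, 2, 7);   // (1, 2, 7, 7) layout
      put_flat(B.locb);
    }
    put_conv(f.proj);
  }
  for (auto& b : net->dec) put_block(b);
  put_conv(net->head);
  return List::create(_["loss"] = lo.joint, _["dice_loss"] = lo.dice,
                      _["ce_loss"] = lo.ce, _["grads"] = g);
}

// conv weight (CiKK x Co) -> R array (Co, Ci, k, k)
static NumericVector convw_to_r(const fmat& W, int ci, int k) {
  const int co = W.n_cols;
  NumericVector out((R_xlen_t)co * ci * k * k);
  double* op = REAL(out);
  for (int o = 0; o < co; ++o)
    for (int i = 0; i < ci; ++i)
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc)
          op[o + (size_t)co * (i + (size_t)ci * (kr + (size_t)k * kc))] =
            W((size_t)i * k * k + (size_t)kr * k + kc, o);
  out.attr("dim") = IntegerVector::create(co, ci, k, k);
  return out;
}

static void convw_from_r(fmat& W, const NumericVector& x, int ci, int k) {
  const int co = W.n_cols;
  const double* xp = REAL(x);
  for (int o = 0; o < co; ++o)
    for (int i = 0; i < ci; ++i)
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc)
          W((size_t)i * k * k + (size_t)kr * k + kc, o) =
            (float)xp[o + (size_t)co * (i + (size_t)ci * (kr + (size_t)k * kc))];
}

static NumericVector fmat_to_r(const fmat& m) {
  NumericVector out(m.n_elem);
  for (arma::uword i = 0; i < m.n_elem; ++i) out[i] = m(i);
  if (m.n_cols > 1)
    out.attr("dim") = IntegerVector::create(m.n_rows, m.n_cols);
  return out;
}

static NumericVector fvec_to_r(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

// [[Rcpp::export(name = ".unet_get_weights")]]
List unet_get_weights_cpp(SEXP ptr_) {
  XPtr<UNet> net(ptr_);
  List out;
  auto put_block = [&](ConvBlock& b) {
    out[b.conv.W.name] = convw_to_r(b.conv.W.w, b.conv.ci, b.conv.k);
    out[b.conv.b.name] = fmat_to_r(b.conv.b.w);
    out[b.bn.gamma.name] = fmat_to_r(b.bn.gamma.w);
    out[b.bn.beta.name] = fmat_to_r(b.bn.beta.w);
    out[b.bn.gamma.name.substr(0, b.bn.gamma.name.size() - 6) + "_rmean"] =
      fvec_to_r(b.bn.rmean);
    out[b.bn.gamma.name.substr(0, b.bn.gamma.name.size() - 6) + "_rvar"] =
      fvec_to_r(b.bn.rvar);
  };
  for (auto& b : net->enc) put_block(b);
  for (auto& f : net->flab) {
    for (auto& B : f.br) {
      out[B.f1w.name] = fmat_to_r(B.f1w.w);
      out[B.f1b.name] = fmat_to_r(B.f1b.w);
      out[B.f2w.name] = fmat_to_r(B.f2w.w);
      out[B.f2b.name] = fmat_to_r(B.f2b.w);
      out[B.locw.name] = convw_to_r(B.locw.w, 2, 7);
      out[B.locb.name] = fmat_to_r(B.locb.w);
    }
    out[f.proj.W.name] = convw_to_r(f.proj.W.w, f.proj.ci, 3);
    out[f.proj.b.name] = fmat_to_r(f.proj.b.w);
  }
  for (auto& b : net->dec) put_block(b);
  out[net->head.W.name] = convw_to_r(net->head.W.w, net->head.ci, 1);
  out[net->head.b.name] = fmat_to_r(net->head.b.w);
  return out;
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights_cpp(SEXP ptr_, List w) {
  XPtr<UNet> net(ptr_);
  auto getv = [&](const std::string& nm) -> NumericVector {
    if (!w.containsElementNamed(nm.c_str())) stop("missing weight '%s'", nm.c_str());
    return as<NumericVector>(w[nm]);
  };
  auto set_fmat = [&](fmat& m, const std::string& nm) {
    NumericVector v = getv(nm);
    if ((arma::uword)v.size() != m.n_elem)
      stop("weight '%s' has %d values, expected %d", nm.c_str(), (int)v.size(),
           (int)m.n_elem);
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (float)v[i];
  };
  auto set_fvec = [&](fvec& m, const std::string& nm) {
    NumericVector v = getv(nm);
    if ((arma::uword)v.size() != m.n_elem)
      stop("weight '%s' has wrong length", nm.c_str());
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (float)v[i];
  };
  auto set_block = [&](ConvBlock& b) {
    convw_from_r(b.conv.W.w, getv(b.conv.W.name), b.conv.ci, b.conv.k);
    set_fmat(b.conv.b.w, b.conv.b.name);
    set_fmat(b.bn.gamma.w, b.bn.gamma.name);
    set_fmat(b.bn.beta.w, b.bn.beta.name);
    const std::string stem = b.bn.gamma.name.substr(0, b.bn.gamma.name.size() - 6);
    set_fvec(b.bn.rmean, stem + "_rmean");
    set_fvec(b.bn.rvar, stem + "_rvar");
  };
  for (auto& b : net->enc) set_block(b);
  for (auto& f : net->flab) {
    for (auto& B : f.br) {
      set_fmat(B.f1w.w, B.f1w.name);
      set_fmat(B.f1b.w, B.f1b.name);
      set_fmat(B.f2w.w, B.f2w.name);
      set_fmat(B.f2b.w, B.f2b.name);
      convw_from_r(B.locw.w, getv(B.locw.name), 2, 7);
      set_fmat(B.locb.w, B.locb.name);
    }
    convw_from_r(f.proj.W.w, getv(f.proj.W.name), f.proj.ci, 3);
    set_fmat(f.proj.b.w, f.proj.b.name);
  }
  for (auto& b : net->dec) set_block(b);
  convw_from_r(net->head.W.w, getv(net->head.W.name), net->head.ci, 1);
  set_fmat(net->head.b.w, net->head.b.name);
}

// [[Rcpp::export(name = ".unet_census")]]
List unet_census_cpp(SEXP ptr_) {
  XPtr<UNet> net(ptr_);
  std::vector<PTensor*> ps;
  net->collect(ps);
  std::vector<std::string> nm;
  IntegerVector n(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    nm.push_back(ps[i]->name);
    n[i] = (int)ps[i]->w.n_elem;
  }
  n.attr("names") = wrap(nm);
  double tot = 0;
  for (int i = 0; i < n.size(); ++i) tot += n[i];
  return List::create(_["sizes"] = n, _["total"] = tot);
}

// [[Rcpp::export(name = ".unet_flab_apply")]]
List unet_flab_apply_cpp(SEXP ptr_, int level, NumericVector x) {
  XPtr<UNet> net(ptr_);
  if (!net->cfg.use_flab) stop("model was built with use_flab = FALSE");
  if (level < 1 || level > 4) stop("level must be in 1..4");
  Flab& f = net->flab[level - 1];
  BatchP xb = r_to_batch(x);
  if ((int)(*xb)[0].n_slices != f.C)
    stop("feature-location attention block at level %d expects %d channels, got %d",
         level, f.C, (int)(*xb)[0].n_slices);
  BatchP out = f.forward(xb, true);   // train mode to capture gates
  const size_t N = xb->size();
  Batch gates(N);
  for (size_t n = 0; n < N; ++n) gates[n] = f.gateB[n];
  List res = List::create(_["out"] = batch_to_r(*out),
                          _["gates"] = batch_to_r(gates),
                          _["gated"] = batch_to_r(*f.gatedB));
  f.in_x.reset(); f.gatedB.reset();
  return res;
}

// [[Rcpp::export(name = ".unet_conv_block_apply")]]
NumericVector unet_conv_block_apply_cpp(SEXP ptr_, std::string which, int stage,
                                        int block, NumericVector x, bool train) {
  XPtr<UNet> net(ptr_);
  ConvBlock* b;
  if (which == "enc") {
    if (stage < 1 || stage > 5 || block < 1 || block > 2) stop("bad encoder index");
    b = &net->enc[2 * (stage - 1) + (block - 1)];
  } else if (which == "dec") {
    if (stage < 1 || stage > 4 || block < 1 || block > 2) stop("bad decoder index");
    b = &net->dec[2 * (stage - 1) + (block - 1)];
  } else stop("which must be 'enc' or 'dec'");
  BatchP xb = r_to_batch(x);
  if ((int)(*xb)[0].n_slices != b->conv.ci)
    stop("conv block expects %d input channels, got %d", b->conv.ci,
         (int)(*xb)[0].n_slices);
  BatchP out = b->forward(xb, train);
  NumericVector res = batch_to_r(*out);
  b->in_x.reset(); b->out_y.reset(); b->bn.xhat.clear();
  return res;
}

// [[Rcpp::export(name = ".unet_encoder_forward")]]
List unet_encoder_forward_cpp(SEXP ptr_, NumericVector x) {
  XPtr<UNet> net(ptr_);
  BatchP xb = r_to_batch(x);
  check_input(*net, *xb);
  net->encode(xb, false);
  List out(5);
  for (int s = 0; s < 5; ++s) out[s] = batch_to_r(*net->feats[s]);
  net->feats.assign(5, nullptr);
  return out;
}

// [[Rcpp::export(name = ".unet_decoder_forward")]]
NumericVector unet_decoder_forward_cpp(SEXP ptr_, NumericVector bottom, List skips) {
  XPtr<UNet> net(ptr_);
  if (skips.size() != 4) stop("expected 4 skip feature maps, deepest first");
  BatchP d = r_to_batch(bottom);
  std::vector<BatchP> sk(4);
  for (int l = 0; l < 4; ++l) sk[l] = r_to_batch(as<NumericVector>(skips[l]));
  int ch = (int)(*d)[0].n_rows, cw = (int)(*d)[0].n_cols;
  for (int l = 0; l < 4; ++l) {
    const int uh = 2 * ch, uw = 2 * cw;
    if ((int)(*sk[l])[0].n_rows != uh || (int)(*sk[l])[0].n_cols != uw)
      stop("decoder level %d: upsampled map is %d x %d but skip is %d x %d", l + 1,
           uh, uw, (int)(*sk[l])[0].n_rows, (int)(*sk[l])[0].n_cols);
    ch = uh; cw = uw;
  }
  BatchP out = net->decode(d, sk, false);
  return batch_to_r(*out);
}

// [[Rcpp::export(name = ".unet_config_echo")]]
List unet_config_echo_cpp(SEXP ptr_) {
  XPtr<UNet> net(ptr_);
  return List::create(
    _["in_channels"] = net->cfg.in_ch, _["num_classes"] = net->cfg.num_classes,
    _["base_width"] = net->cfg.base, _["use_flab"] = net->cfg.use_flab,
    _["pool_kernel"] = net->cfg.pool_k, _["hidden_width"] = net->cfg.hidden_r,
    _["share_across_channels"] = net->cfg.flab_share);
}

// [[Rcpp::export(name = ".nn_prof_report")]]
List nn_prof_report_cpp(bool reset = true) {
  List out;
  for (auto& kv : prof_.t) out[kv.first] = kv.second;
  if (reset) prof_.t.clear();
  return out;
}

// -------------------------------------------------------- resize utils ----

// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix x, int out_h, int out_w) {
  const int H = x.nrow(), W = x.ncol();
  if (out_h < 1 || out_w < 1) stop("bad output size");
  NumericMatrix out(out_h, out_w);
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double src = (j + 0.5) * sw - 0.5;
    int j0 = (int)std::floor(src);
    double tj = src - j0;
    int j1 = j0 + 1;
    if (j0 < 0) { j0 = 0; j1 = 0; tj = 0; }
    if (j1 >= W) { j1 = W - 1; if (j0 >= W) j0 = W - 1; }
    for (int i = 0; i < out_h; ++i) {
      double srci = (i + 0.5) * sh - 0.5;
      int i0 = (int)std::floor(srci);
      double ti = srci - i0;
      int i1 = i0 + 1;
      if (i0 < 0) { i0 = 0; i1 = 0; ti = 0; }
      if (i1 >= H) { i1 = H - 1; if (i0 >= H) i0 = H - 1; }
      out(i, j) = (1 - ti) * (1 - tj) * x(i0, j0) + ti * (1 - tj) * x(i1, j0) +
                  (1 - ti) * tj * x(i0, j1) + ti * tj * x(i1, j1);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".resize_nearest")]]
IntegerMatrix resize_nearest_cpp(IntegerMatrix x, int out_h, int out_w) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix out(out_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    int js = (int)std::floor((j + 0.5) * (double)W / out_w);
    if (js >= W) js = W - 1;
    for (int i = 0; i < out_h; ++i) {
      int is = (int)std::floor((i + 0.5) * (double)H / out_h);
      if (is >= H) is = H - 1;
      out(i, j) = x(is, js);
    }
  }
  return out;
}
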
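// Compact two-block convolutional classifier for single-trial EEG
// (temporal conv -> depthwise spatial conv -> separable conv -> dense softmax),
// with batch normalization, ELU, average pooling, inverted dropout, max-norm
// weight constraints, ADAM optimization and input-gradient saliency.
//
// Written from scratch in C++ because the model itself is the method under
// study; single precision + BLAS sgemm keep a full leave-one-subject-out run
// tractable on one CPU. All randomness (shuffling, dropout) comes from one
// std::mt19937 seeded from R, so training is reproducible for a fixed seed.

#include <RcppArmadillo.h>
#include <deque>
#include <random>
#if defined(__x86_64__) || defined(__i386__)
#include <immintrin.h>
#define EEGNET_X86 1
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;
using arma::uword;

namespace {

struct NetCfg {
  int F1, D, F2, K1, K2, P1, P2, N;
  double dropout;
  int C, T, T1, T2, FL;
};

NetCfg read_cfg(const List& cfg, int C, int T) {
  NetCfg c;
  c.F1 = as<int>(cfg["F1"]);
  c.D  = as<int>(cfg["D"]);
  c.F2 = as<int>(cfg["F2"]);
  c.K1 = as<int>(cfg["temporalKernel"]);
  c.K2 = as<int>(cfg["separableKernel"]);
  c.P1 = as<int>(cfg["pool1"]);
  c.P2 = as<int>(cfg["pool2"]);
  c.N  = as<int>(cfg["nClasses"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.C = C; c.T = T;
  c.T1 = T / c.P1;
  c.T2 = c.T1 / c.P2;
  c.FL = c.F2 * c.T2;
  if (c.F2 != c.F1 * c.D) stop("F2 must equal F1 * D");
  if (T < c.K1) stop("number of timepoints is smaller than the temporal kernel");
  if (c.T2 < 1) stop("too few timepoints after pooling");
  return c;
}

struct Weights {
  fmat W1;        // F1 x K1
  fmat Wd;        // F2 x C
  fmat Wsd;       // F2 x K2
  fmat Wsp;       // F2 x F2 (out x in)
  fmat Wf;        // N x FL
  fvec bf;        // N
  fvec g1, b1, g2, b2, g3, b3;
  fvec rm1, rv1, rm2, rv2, rm3, rv3;  // batch-norm running stats
};

fmat getm(const List& w, const char* nm) {
  return as<fmat>(as<NumericMatrix>(w[nm]));
}
fvec getv(const List& w, const char* nm) {
  return as<fvec>(as<NumericVector>(w[nm]));
}

Weights read_weights(const List& w) {
  Weights W;
  W.W1 = getm(w, "W1");  W.Wd = getm(w, "Wd");
  W.Wsd = getm(w, "Wsd"); W.Wsp = getm(w, "Wsp");
  W.Wf = getm(w, "Wf");  W.bf = getv(w, "bf");
  W.g1 = getv(w, "g1"); W.b1 = getv(w, "b1");
  W.g2 = getv(w, "g2"); W.b2 = getv(w, "b2");
  W.g3 = getv(w, "g3"); W.b3 = getv(w, "b3");
  W.rm1 = getv(w, "rm1"); W.rv1 = getv(w, "rv1");
  W.rm2 = getv(w, "rm2"); W.rv2 = getv(w, "rv2");
  W.rm3 = getv(w, "rm3"); W.rv3 = getv(w, "rv3");
  return W;
}

List dump_weights(const Weights& W) {
  return List::create(
    _["W1"] = wrap(W.W1), _["Wd"] = wrap(W.Wd),
    _["Wsd"] = wrap(W.Wsd), _["Wsp"] = wrap(W.Wsp),
    _["Wf"] = wrap(W.Wf), _["bf"] = wrap(W.bf),
    _["g1"] = wrap(W.g1), _["b1"] = wrap(W.b1),
    _["g2"] = wrap(W.g2), _["b2"] = wrap(W.b2),
    _["g3"] = wrap(W.g3), _["b3"] = wrap(W.b3),
    _["rm1"] = wrap(W.rm1), _["rv1"] = wrap(W.rv1),
    _["rm2"] = wrap(W.rm2), _["rv2"] = wrap(W.rv2),
    _["rm3"] = wrap(W.rm3), _["rv3"] = wrap(W.rv3));
}

// Per-parameter ADAM state mirroring Weights (trainable entries only).
struct Adam {
  fmat mW1, vW1, mWd, vWd, mWsd, vWsd, mWsp, vWsp, mWf, vWf;
  fvec mbf, vbf;
  fvec mg1, vg1, mb1, vb1, mg2, vg2, mb2, vb2, mg3, vg3, mb3, vb3;
  long t = 0;
  void init(const Weights& W) {
    mW1.zeros(arma::size(W.W1)); vW1 = mW1;
    mWd.zeros(arma::size(W.Wd)); vWd = mWd;
    mWsd.zeros(arma::size(W.Wsd)); vWsd = mWsd;
    mWsp.zeros(arma::size(W.Wsp)); vWsp = mWsp;
    mWf.zeros(arma::size(W.Wf)); vWf = mWf;
    mbf.zeros(arma::size(W.bf)); vbf = mbf;
    mg1.zeros(arma::size(W.g1)); vg1 = mg1; mb1 = mg1; vb1 = mg1;
    mg2.zeros(arma::size(W.g2)); vg2 = mg2; mb2 = mg2; vb2 = mg2;
    mg3.zeros(arma::size(W.g3)); vg3 = mg3; mb3 = mg3; vb3 = mg3;
  }
};

struct Grads {
  fmat W1, Wd, Wsd, Wsp, Wf;
  fvec bf, g1, b1, g2, b2, g3, b3;
};

// Workspace for one batch (sized once at the maximum batch size).
struct Work {
  int Bmax;
  fmat Z1, A1, dA1, dZ1;  // (B*C*T) x F1
  fcube Z2, B2, E2, dT;   // T  x F2 x B   (dT reused for gradients)
  fcube P1c, M1, S, Q, B3, E3, dT1a, dT1b;  // T1 x F2 x B
  fcube Fp, M2, dF;   // T2 x F2 x B
  fmat Flat, dFlat;   // FL x B
  fmat logits, probs; // N x B
  fvec mu1, sd1, mu2, sd2, mu3, sd3;  // batch stats actually used (train or running)
  std::vector<float> rowbuf;
  std::vector<double> wacc;  // dW1 accumulator (double across rows)

  void init(const NetCfg& c, int Bmax_) {
    Bmax = Bmax_;
    uword M = (uword)Bmax * c.C * c.T;
    Z1.set_size(M, c.F1); A1.set_size(M, c.F1);
    dA1.set_size(M, c.F1); dZ1.set_size(M, c.F1);
    Z2.set_size(c.T, c.F2, Bmax); B2.set_size(c.T, c.F2, Bmax);
    E2.set_size(c.T, c.F2, Bmax); dT.set_size(c.T, c.F2, Bmax);
    P1c.set_size(c.T1, c.F2, Bmax); M1.set_size(c.T1, c.F2, Bmax);
    S.set_size(c.T1, c.F2, Bmax); Q.set_size(c.T1, c.F2, Bmax);
    B3.set_size(c.T1, c.F2, Bmax); E3.set_size(c.T1, c.F2, Bmax);
    dT1a.set_size(c.T1, c.F2, Bmax); dT1b.set_size(c.T1, c.F2, Bmax);
    Fp.set_size(c.T2, c.F2, Bmax); M2.set_size(c.T2, c.F2, Bmax);
    dF.set_size(c.T2, c.F2, Bmax);
    Flat.set_size(c.FL, Bmax); dFlat.set_size(c.FL, Bmax);
    logits.set_size(c.N, Bmax); probs.set_size(c.N, Bmax);
    mu1.set_size(c.F1); sd1.set_size(c.F1);
    mu2.set_size(c.F2); sd2.set_size(c.F2);
    mu3.set_size(c.F2); sd3.set_size(c.F2);
    rowbuf.assign(c.T + c.K1 + 16, 0.0f);
    wacc.assign((size_t)c.F1 * c.K1, 0.0);
  }
};

const float BN_EPS = 1e-3f;
const float BN_MOM = 0.99f;

// Input trials are stored transposed, (T x C) per slice, so each channel's
// time series is contiguous. The temporal convolution runs per (trial,
// channel) row on a zero-padded copy that stays in L1 cache; hot kernels are
// hand-vectorized (AVX2/FMA) with a scalar fallback so the package builds on
// any x86-64 / other architecture.

// Fill the padded row buffer: rb[padL .. padL+T-1] = signal, zeros elsewhere.
inline void build_row(const float* x, float* rb, int T, int K1) {
  int padL = (K1 - 1) / 2;
  std::fill(rb, rb + T + K1 + 16, 0.0f);
  std::memcpy(rb + padL, x, sizeof(float) * T);
}

#ifdef EEGNET_X86
// The hot kernels are compiled for AVX2/FMA with full optimization via
// pragmas (the global compiler flags may target an older baseline at -O2)
// and selected at run time.
#pragma GCC push_options
#pragma GCC optimize("O3,unroll-loops")
#pragma GCC target("avx2,fma")

// out[f][t] = sum_k W1(f,k) * rb[t+k]; computes all F1T filters per t-block.
template <int F1T>
inline void conv_row_fwd_vec(const float* __restrict rb,
                             const float* __restrict w1, int ldw,
                             float* const* out, int T, int K1) {
  int t = 0;
  for (; t + 8 <= T; t += 8) {
    __m256 acc[F1T];
    for (int f = 0; f < F1T; ++f) acc[f] = _mm256_setzero_ps();
    for (int k = 0; k < K1; ++k) {
      __m256 x = _mm256_loadu_ps(rb + t + k);
      const float* wk = w1 + (size_t)k * ldw;
      for (int f = 0; f < F1T; ++f)
        acc[f] = _mm256_fmadd_ps(_mm256_broadcast_ss(wk + f), x, acc[f]);
    }
    for (int f = 0; f < F1T; ++f) _mm256_storeu_ps(out[f] + t, acc[f]);
  }
  for (; t < T; ++t)
    for (int f = 0; f < F1T; ++f) {
      float a = 0;
      for (int k = 0; k < K1; ++k) a += w1[f + (size_t)k * ldw] * rb[t + k];
      out[f][t] = a;
    }
}

// wacc[f + k*ldw] += sum_t dz[f][t] * rb[t+k]  (K1 <= 64)
template <int F1T>
inline void conv_row_wgrad_vec(const float* __restrict rb,
                               const float* const* dz,
                               double* __restrict wacc, int ldw, int T,
                               int K1) {
  int nv = K1 / 8;
  for (int f = 0; f < F1T; ++f) {
    __m256 vacc[8];
    for (int j = 0; j < nv; ++j) vacc[j] = _mm256_setzero_ps();
    const float* d = dz[f];
    for (int t = 0; t < T; ++t) {
      __m256 b = _mm256_broadcast_ss(d + t);
      for (int j = 0; j < nv; ++j)
        vacc[j] = _mm256_fmadd_ps(b, _mm256_loadu_ps(rb + t + 8 * j), vacc[j]);
    }
    float tmp[8];
    for (int j = 0; j < nv; ++j) {
      _mm256_storeu_ps(tmp, vacc[j]);
      for (int e = 0; e < 8; ++e) wacc[f + (size_t)(8 * j + e) * ldw] += tmp[e];
    }
    for (int k = nv * 8; k < K1; ++k) {
      double a = 0;
      for (int t = 0; t < T; ++t) a += (double)d[t] * rb[t + k];
      wacc[f + (size_t)k * ldw] += a;
    }
  }
}

// chunked double-accumulated vector reductions
void red_sum_sq_avx(const float* x, size_t n, double& s, double& s2) {
  s = 0; s2 = 0;
  size_t i = 0;
  while (i < n) {
    size_t end = std::min(n, i + ((size_t)1 << 16));
    __m256 a0 = _mm256_setzero_ps(), a1 = _mm256_setzero_ps();
    for (; i + 8 <= end; i += 8) {
      __m256 v = _mm256_loadu_ps(x + i);
      a0 = _mm256_add_ps(a0, v);
      a1 = _mm256_fmadd_ps(v, v, a1);
    }
    float t0[8], t1[8];
    _mm256_storeu_ps(t0, a0); _mm256_storeu_ps(t1, a1);
    for (int e = 0; e < 8; ++e) { s += t0[e]; s2 += t1[e]; }
    for (; i < end; ++i) { s += x[i]; s2 += (double)x[i] * x[i]; }
  }
}

void red_sum_dot_avx(const float* x, const float* y, size_t n, double& s,
                     double& sxy) {
  s = 0; sxy = 0;
  size_t i = 0;
  while (i < n) {
    size_t end = std::min(n, i + ((size_t)1 << 16));
    __m256 a0 = _mm256_setzero_ps(), a1 = _mm256_setzero_ps();
    for (; i + 8 <= end; i += 8) {
      __m256 vx = _mm256_loadu_ps(x + i);
      __m256 vy = _mm256_loadu_ps(y + i);
      a0 = _mm256_add_ps(a0, vx);
      a1 = _mm256_fmadd_ps(vx, vy, a1);
    }
    float t0[8], t1[8];
    _mm256_storeu_ps(t0, a0); _mm256_storeu_ps(t1, a1);
    for (int e = 0; e < 8; ++e) { s += t0[e]; sxy += t1[e]; }
    for (; i < end; ++i) { s += x[i]; sxy += (double)x[i] * y[i]; }
  }
}
#pragma GCC pop_options

bool cpu_avx2() {
  static const bool ok =
      __builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma");
  return ok;
}
#endif

void conv_row_fwd(const float* rb, const fmat& W1, float* const* out, int T,
                  int K1, int F1) {
#ifdef EEGNET_X86
  if (K1 <= 64 && cpu_avx2()) {
    if (F1 == 8) { conv_row_fwd_vec<8>(rb, W1.memptr(), F1, out, T, K1); return; }
    if (F1 == 4) { conv_row_fwd_vec<4>(rb, W1.memptr(), F1, out, T, K1); return; }
  }
#endif
  for (int f = 0; f < F1; ++f) {
    float* __restrict o = out[f];
    std::fill(o, o + T, 0.0f);
    for (int k = 0; k < K1; ++k) {
      float wv = W1(f, k);
      const float* __restrict x = rb + k;
      for (int t = 0; t < T; ++t) o[t] += wv * x[t];
    }
  }
}

void conv_row_wgrad(const float* rb, const float* const* dz, double* wacc,
                    int T, int K1, int F1) {
#ifdef EEGNET_X86
  if (K1 <= 64 && cpu_avx2()) {
    if (F1 == 8) { conv_row_wgrad_vec<8>(rb, dz, wacc, F1, T, K1); return; }
    if (F1 == 4) { conv_row_wgrad_vec<4>(rb, dz, wacc, F1, T, K1); return; }
  }
#endif
  std::vector<float> loc(K1);
  for (int f = 0; f < F1; ++f) {
    std::fill(loc.begin(), loc.end(), 0.0f);
    const float* __restrict d = dz[f];
    float* __restrict lp = loc.data();
    for (int t = 0; t < T; ++t) {
      float dv = d[t];
      const float* __restrict x = rb + t;
      for (int k = 0; k < K1; ++k) lp[k] += dv * x[k];
    }
    for (int k = 0; k < K1; ++k) wacc[f + (size_t)k * F1] += lp[k];
  }
}

// Fused vector reductions: sum & sum of squares / sum & dot. Chunked into
// double accumulators so long sums keep precision.
inline void red_sum_sq(const float* x, size_t n, double& s, double& s2) {
#ifdef EEGNET_X86
  if (cpu_avx2()) { red_sum_sq_avx(x, n, s, s2); return; }
#endif
  s = 0; s2 = 0;
  for (size_t i = 0; i < n; ++i) { s += x[i]; s2 += (double)x[i] * x[i]; }
}

inline void red_sum_dot(const float* x, const float* y, size_t n, double& s,
                        double& sxy) {
#ifdef EEGNET_X86
  if (cpu_avx2()) { red_sum_dot_avx(x, y, n, s, sxy); return; }
#endif
  s = 0; sxy = 0;
  for (size_t i = 0; i < n; ++i) { s += x[i]; sxy += (double)x[i] * y[i]; }
}

// Batch-norm forward over the columns of an (M x F) matrix.
void bn_cols_forward(const fmat& Zin, fmat& Aout, const fvec& g, const fvec& b,
                     fvec& mu, fvec& sd, fvec* rm, fvec* rv, bool training,
                     uword M) {
  int F = Zin.n_cols;
  for (int f = 0; f < F; ++f) {
    const float* z = Zin.colptr(f);
    float m, s2;
    if (training) {
      double acc, acc2;
      red_sum_sq(z, M, acc, acc2);
      m = (float)(acc / M);
      double var = acc2 / M - (double)m * m;
      s2 = (float)std::max(var, 0.0);
      (*rm)(f) = BN_MOM * (*rm)(f) + (1.0f - BN_MOM) * m;
      (*rv)(f) = BN_MOM * (*rv)(f) + (1.0f - BN_MOM) * s2;
    } else {
      m = (*rm)(f); s2 = (*rv)(f);
    }
    float sdv = std::sqrt(s2 + BN_EPS);
    mu(f) = m; sd(f) = sdv;
    float sc = g(f) / sdv, off = b(f) - sc * m;
    float* __restrict a = Aout.colptr(f);
    const float* __restrict zz = z;
    for (uword i = 0; i < M; ++i) a[i] = sc * zz[i] + off;
  }
}

// Batch-norm forward per feature map over (T x B) entries of a cube
// laid out (T, F, B).
void bn_cube_forward(const fcube& Zin, fcube& Aout, const fvec& g, const fvec& b,
                     fvec& mu, fvec& sd, fvec* rm, fvec* rv, bool training,
                     int Tn, int F, int B) {
  double Mtot = (double)Tn * B;
  for (int f = 0; f < F; ++f) {
    float m, s2;
    if (training) {
      double acc = 0, acc2 = 0;
      for (int bb = 0; bb < B; ++bb) {
        const float* z = Zin.slice(bb).colptr(f);
        for (int t = 0; t < Tn; ++t) acc += z[t];
      }
      m = (float)(acc / Mtot);
      for (int bb = 0; bb < B; ++bb) {
        const float* z = Zin.slice(bb).colptr(f);
        for (int t = 0; t < Tn; ++t) { double d = z[t] - m; acc2 += d * d; }
      }
      s2 = (float)(acc2 / Mtot);
      (*rm)(f) = BN_MOM * (*rm)(f) + (1.0f - BN_MOM) * m;
      (*rv)(f) = BN_MOM * (*rv)(f) + (1.0f - BN_MOM) * s2;
    } else {
      m = (*rm)(f); s2 = (*rv)(f);
    }
    float sdv = std::sqrt(s2 + BN_EPS);
    mu(f) = m; sd(f) = sdv;
    float sc = g(f) / sdv, off = b(f) - sc * m;
    for (int bb = 0; bb < B; ++bb) {
      const float* z = Zin.slice(bb).colptr(f);
      float* a = Aout.slice(bb).colptr(f);
      for (int t = 0; t < Tn; ++t) a[t] = sc * z[t] + off;
    }
  }
}

inline float elu(float x) { return x > 0 ? x : std::expm1(x); }

// Forward pass for a batch; fills the workspace. `training` selects batch
// statistics + dropout; masks (M1, M2 cubes) must be pre-filled when training.
void forward(const fcube& X, const std::vector<int>& idx, int B,
             const NetCfg& c, const Weights& W, Work& w, bool training) {
  uword M = (uword)B * c.C * c.T;
  // No-copy aliases sized to the actual batch (stride M, not Mmax), so
  // partial batches stay consistent.
  fmat Z1v(w.Z1.memptr(), M, c.F1, false, true);
  fmat A1v(w.A1.memptr(), M, c.F1, false, true);

  // Block 1: temporal convolution (F1 filters, width K1, same padding, linear)
  {
    std::vector<float*> outp(c.F1);
    for (int b = 0; b < B; ++b) {
      const fmat& sl = X.slice(idx[b]);  // T x C (transposed storage)
      for (int ch = 0; ch < c.C; ++ch) {
        build_row(sl.colptr(ch), w.rowbuf.data(), c.T, c.K1);
        for (int f = 0; f < c.F1; ++f)
          outp[f] = Z1v.colptr(f) + ((uword)b * c.C + ch) * c.T;
        conv_row_fwd(w.rowbuf.data(), W.W1, outp.data(), c.T, c.K1, c.F1);
      }
    }
  }
  bn_cols_forward(Z1v, A1v, W.g1, W.b1, w.mu1, w.sd1,
                  const_cast<fvec*>(&W.rm1), const_cast<fvec*>(&W.rv1),
                  training, M);

  // Depthwise spatial convolution: D filters per temporal map, spanning all C.
  for (int b = 0; b < B; ++b) {
    fmat& Z2b = w.Z2.slice(b);
    for (int f = 0; f < c.F1; ++f) {
      // view of map f, trial b: T x C block (t fastest within channel)
      const float* base = A1v.colptr(f) + (uword)b * c.C * c.T;
      const fmat Vb(const_cast<float*>(base), c.T, c.C, false, true);
      fmat Wf_t = W.Wd.rows(f * c.D, f * c.D + c.D - 1).t();  // C x D
      Z2b.cols(f * c.D, f * c.D + c.D - 1) = Vb * Wf_t;
    }
  }
  bn_cube_forward(w.Z2, w.B2, W.g2, W.b2, w.mu2, w.sd2,
                  const_cast<fvec*>(&W.rm2), const_cast<fvec*>(&W.rv2),
                  training, c.T, c.F2, B);

  // ELU -> average pool P1 -> dropout
  float inv1 = 1.0f / c.P1;
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < c.F2; ++f) {
      const float* x = w.B2.slice(b).colptr(f);
      float* e = w.E2.slice(b).colptr(f);
      for (int t = 0; t < c.T; ++t) e[t] = elu(x[t]);
      float* p = w.P1c.slice(b).colptr(f);
      for (int u = 0; u < c.T1; ++u) {
        float s = 0;
        for (int k = 0; k < c.P1; ++k) s += e[u * c.P1 + k];
        p[u] = s * inv1;
      }
    }
  }
  if (training) {
    for (int b = 0; b < B; ++b)
      w.P1c.slice(b) %= w.M1.slice(b);
  }

  // Block 2: separable convolution = depthwise temporal (width K2, same
  // padding) then pointwise mixing across the F2 maps.
  int padL2 = (c.K2 - 1) / 2;
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < c.F2; ++f) {
      const float* p = w.P1c.slice(b).colptr(f);
      float* s = w.S.slice(b).colptr(f);
      for (int u = 0; u < c.T1; ++u) {
        float acc = 0;
        int k0 = std::max(0, padL2 - u);
        int k1 = std::min(c.K2, c.T1 + padL2 - u);
        for (int k = k0; k < k1; ++k)
          acc += W.Wsd(f, k) * p[u + k - padL2];
        s[u] = acc;
      }
    }
    w.Q.slice(b) = w.S.slice(b) * W.Wsp.t();
  }
  bn_cube_forward(w.Q, w.B3, W.g3, W.b3, w.mu3, w.sd3,
                  const_cast<fvec*>(&W.rm3), const_cast<fvec*>(&W.rv3),
                  training, c.T1, c.F2, B);

  float inv2 = 1.0f / c.P2;
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < c.F2; ++f) {
      const float* x = w.B3.slice(b).colptr(f);
      float* e = w.E3.slice(b).colptr(f);
      for (int t = 0; t < c.T1; ++t) e[t] = elu(x[t]);
      float* p = w.Fp.slice(b).colptr(f);
      for (int u = 0; u < c.T2; ++u) {
        float s = 0;
        for (int k = 0; k < c.P2; ++k) s += e[u * c.P2 + k];
        p[u] = s * inv2;
      }
    }
  }
  if (training) {
    for (int b = 0; b < B; ++b)
      w.Fp.slice(b) %= w.M2.slice(b);
  }

  // Flatten (map-major: feature index = f*T2 + u) and dense softmax.
  for (int b = 0; b < B; ++b)
    std::memcpy(w.Flat.colptr(b), w.Fp.slice(b).memptr(),
                sizeof(float) * c.FL);
  w.logits.cols(0, B - 1) = W.Wf * w.Flat.cols(0, B - 1);
  w.logits.cols(0, B - 1).each_col() += W.bf;
  for (int b = 0; b < B; ++b) {
    fvec l = w.logits.col(b);
    float mx = l.max();
    fvec e = arma::exp(l - mx);
    w.probs.col(b) = e / arma::accu(e);
  }
}

// Batch-norm backward. In training mode the batch statistics depend on the
// input (compact biased-variance Jacobian); in inference mode the running
// statistics are constants and the layer is a fixed affine map.
// training: dx = (g/sd) * (dy - mean(dy) - xhat * mean(dy * xhat))
// inference: dx = (g/sd) * dy
void bn_cols_backward(const fmat& Zin, const fmat& dY, fmat& dZ,
                      const fvec& g, const fvec& mu, const fvec& sd,
                      fvec& dg, fvec& db, uword M, bool training) {
  int F = Zin.n_cols;
  for (int f = 0; f < F; ++f) {
    const float* z = Zin.colptr(f);
    const float* dy = dY.colptr(f);
    float* dz = dZ.colptr(f);
    float m = mu(f), s = sd(f);
    float sc = g(f) / s;
    if (!training) {
      for (uword i = 0; i < M; ++i) dz[i] = sc * dy[i];
      continue;
    }
    double sdy, sdyz;
    red_sum_dot(dy, z, M, sdy, sdyz);
    double sdyx = (sdyz - (double)m * sdy) / s;
    dg(f) += (float)sdyx; db(f) += (float)sdy;
    float mdy = (float)(sdy / M), mdyx = (float)(sdyx / M);
    // dz = sc*(dy - mdy - xh*mdyx) = a*dy - c*z + b
    float a = sc, cz = sc * mdyx / s, bb = sc * (mdyx * m / s - mdy);
    const float* __restrict dyp = dy;
    const float* __restrict zp = z;
    for (uword i = 0; i < M; ++i) dz[i] = a * dyp[i] - cz * zp[i] + bb;
  }
}

void bn_cube_backward(const fcube& Zin, const fcube& dY, fcube& dZ,
                      const fvec& g, const fvec& mu, const fvec& sd,
                      fvec& dg, fvec& db, int Tn, int F, int B, bool training) {
  double M = (double)Tn * B;
  for (int f = 0; f < F; ++f) {
    float m = mu(f), s = sd(f);
    float sc = g(f) / s;
    if (!training) {
      for (int b = 0; b < B; ++b) {
        const float* dy = dY.slice(b).colptr(f);
        float* dz = dZ.slice(b).colptr(f);
        for (int t = 0; t < Tn; ++t) dz[t] = sc * dy[t];
      }
      continue;
    }
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const float* z = Zin.slice(b).colptr(f);
      const float* dy = dY.slice(b).colptr(f);
      for (int t = 0; t < Tn; ++t) {
        float xh = (z[t] - m) / s;
        sdy += dy[t]; sdyx += (double)dy[t] * xh;
      }
    }
    dg(f) += (float)sdyx; db(f) += (float)sdy;
    float mdy = (float)(sdy / M), mdyx = (float)(sdyx / M);
    for (int b = 0; b < B; ++b) {
      const float* z = Zin.slice(b).colptr(f);
      const float* dy = dY.slice(b).colptr(f);
      float* dz = dZ.slice(b).colptr(f);
      for (int t = 0; t < Tn; ++t) {
        float xh = (z[t] - m) / s;
        dz[t] = sc * (dy[t] - mdy - xh * mdyx);
      }
    }
  }
}

// Backward pass from dlogits (already stored in w.probs as modified copy is
// NOT assumed; pass explicitly). Fills G. If dXout != nullptr, also
// accumulates the gradient with respect to the input trials (C x T slices).
void backward(const fcube& X, const std::vector<int>& idx, int B,
              const NetCfg& c, const Weights& W, Work& w,
              const fmat& dlogits, Grads& G, bool training,
              fcube* dXout = nullptr) {
  uword M = (uword)B * c.C * c.T;

  G.Wf += dlogits * w.Flat.cols(0, B - 1).t();
  G.bf += arma::sum(dlogits, 1);
  w.dFlat.cols(0, B - 1) = W.Wf.t() * dlogits;
  for (int b = 0; b < B; ++b)
    std::memcpy(w.dF.slice(b).memptr(), w.dFlat.colptr(b),
                sizeof(float) * c.FL);

  if (training) {
    for (int b = 0; b < B; ++b) w.dF.slice(b) %= w.M2.slice(b);
  }

  // unpool P2 -> dE3 ; ELU' ; BN3 backward -> dQ (into dT1a)
  float inv2 = 1.0f / c.P2;
  for (int b = 0; b < B; ++b) {
    fmat& dE3 = w.dT1a.slice(b);
    dE3.zeros();
    for (int f = 0; f < c.F2; ++f) {
      const float* dp = w.dF.slice(b).colptr(f);
      float* de = dE3.colptr(f);
      for (int u = 0; u < c.T2; ++u)
        for (int k = 0; k < c.P2; ++k) de[u * c.P2 + k] = dp[u] * inv2;
      const float* bx = w.B3.slice(b).colptr(f);
      const float* ex = w.E3.slice(b).colptr(f);
      for (int t = 0; t < c.T1; ++t)
        de[t] *= (bx[t] > 0 ? 1.0f : ex[t] + 1.0f);
    }
  }
  bn_cube_backward(w.Q, w.dT1a, w.dT1b, W.g3, w.mu3, w.sd3,
                   G.g3, G.b3, c.T1, c.F2, B, training);  // dT1b = dQ

  // pointwise backward: dS = dQ * Wsp ; dWsp += dQ^T S
  for (int b = 0; b < B; ++b) {
    G.Wsp += w.dT1b.slice(b).t() * w.S.slice(b);
    w.dT1a.slice(b) = w.dT1b.slice(b) * W.Wsp;  // dT1a = dS
  }

  // separable depthwise backward
  int padL2 = (c.K2 - 1) / 2;
  for (int b = 0; b < B; ++b) {
    fmat& dP = w.dT1b.slice(b);  // becomes dP1 (post-dropout side)
    dP.zeros();
    for (int f = 0; f < c.F2; ++f) {
      const float* ds = w.dT1a.slice(b).colptr(f);
      const float* p = w.P1c.slice(b).colptr(f);
      float* dp = dP.colptr(f);
      for (int u = 0; u < c.T1; ++u) {
        int k0 = std::max(0, padL2 - u);
        int k1 = std::min(c.K2, c.T1 + padL2 - u);
        float dsu = ds[u];
        for (int k = k0; k < k1; ++k) {
          G.Wsd(f, k) += dsu * p[u + k - padL2];
          dp[u + k - padL2] += dsu * W.Wsd(f, k);
        }
      }
    }
  }

  if (training) {
    for (int b = 0; b < B; ++b) w.dT1b.slice(b) %= w.M1.slice(b);
  }

  // unpool P1 -> dE2 ; ELU' ; BN2 backward -> dZ2 (into dT)
  float inv1 = 1.0f / c.P1;
  for (int b = 0; b < B; ++b) {
    fmat& dE2 = w.dT.slice(b);
    dE2.zeros();
    for (int f = 0; f < c.F2; ++f) {
      const float* dp = w.dT1b.slice(b).colptr(f);
      float* de = dE2.colptr(f);
      for (int u = 0; u < c.T1; ++u)
        for (int k = 0; k < c.P1; ++k) de[u * c.P1 + k] = dp[u] * inv1;
      const float* bx = w.B2.slice(b).colptr(f);
      const float* ex = w.E2.slice(b).colptr(f);
      for (int t = 0; t < c.T; ++t)
        de[t] *= (bx[t] > 0 ? 1.0f : ex[t] + 1.0f);
    }
  }
  // reuse Z2 cube as dZ2 target via B2? keep separate: write into E2 (done
  // with its cached values after this point except depthwise needs A1 only).
  bn_cube_backward(w.Z2, w.dT, w.E2, W.g2, w.mu2, w.sd2,
                   G.g2, G.b2, c.T, c.F2, B, training);  // E2 now holds dZ2

  // depthwise backward: dWd and dA1
  fmat A1v(w.A1.memptr(), M, c.F1, false, true);
  fmat dA1v(w.dA1.memptr(), M, c.F1, false, true);
  fmat dZ1v(w.dZ1.memptr(), M, c.F1, false, true);
  fmat Z1v(w.Z1.memptr(), M, c.F1, false, true);
  for (int b = 0; b < B; ++b) {
    const fmat& dZ2b = w.E2.slice(b);
    for (int f = 0; f < c.F1; ++f) {
      const float* base = A1v.colptr(f) + (uword)b * c.C * c.T;
      const fmat Vb(const_cast<float*>(base), c.T, c.C, false, true);
      fmat dRb = dZ2b.cols(f * c.D, f * c.D + c.D - 1);  // T x D
      G.Wd.rows(f * c.D, f * c.D + c.D - 1) += dRb.t() * Vb;
      float* dbase = dA1v.colptr(f) + (uword)b * c.C * c.T;
      fmat dVb(dbase, c.T, c.C, false, true);
      dVb = dRb * W.Wd.rows(f * c.D, f * c.D + c.D - 1);
    }
  }

  bn_cols_backward(Z1v, dA1v, dZ1v, W.g1, w.mu1, w.sd1, G.g1, G.b1, M,
                   training);

  // temporal conv weight gradient
  {
    std::fill(w.wacc.begin(), w.wacc.end(), 0.0);
    std::vector<const float*> dzp(c.F1);
    for (int b = 0; b < B; ++b) {
      const fmat& sl = X.slice(idx[b]);  // T x C
      for (int ch = 0; ch < c.C; ++ch) {
        build_row(sl.colptr(ch), w.rowbuf.data(), c.T, c.K1);
        for (int f = 0; f < c.F1; ++f)
          dzp[f] = dZ1v.colptr(f) + ((uword)b * c.C + ch) * c.T;
        conv_row_wgrad(w.rowbuf.data(), dzp.data(), w.wacc.data(), c.T, c.K1,
                       c.F1);
      }
    }
    for (int k = 0; k < c.K1; ++k)
      for (int f = 0; f < c.F1; ++f)
        G.W1(f, k) += (float)w.wacc[f + (size_t)k * c.F1];
  }

  // input gradient (saliency only; the input is data during training)
  if (dXout) {
    int padL = (c.K1 - 1) / 2;
    for (int b = 0; b < B; ++b) {
      fmat& dXs = dXout->slice(idx[b]);  // T x C
      for (int ch = 0; ch < c.C; ++ch) {
        float* rb = w.rowbuf.data();
        std::fill(rb, rb + c.T + c.K1 + 16, 0.0f);
        for (int f = 0; f < c.F1; ++f) {
          const float* dz = dZ1v.colptr(f) + ((uword)b * c.C + ch) * c.T;
          for (int t = 0; t < c.T; ++t) {
            float d = dz[t];
            if (d != 0.0f)
              for (int k = 0; k < c.K1; ++k) rb[t + k] += d * W.W1(f, k);
          }
        }
        float* dxc = dXs.colptr(ch);
        for (int t = 0; t < c.T; ++t) dxc[t] += rb[padL + t];
      }
    }
  }
}

void adam_step(fmat& w, fmat& m, fmat& v, const fmat& g, float lr,
               float b1, float b2, float eps, float c1, float c2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}
void adam_step(fvec& w, fvec& m, fvec& v, const fvec& g, float lr,
               float b1, float b2, float eps, float c1, float c2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

// Convert the R (C x T x trials) array to float, transposing each slice to
// (T x C) so channel time series are contiguous for the conv kernels.
fcube to_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (C x T x trials)");
  int C = d[0], T = d[1], n = d[2];
  fcube out(T, C, n);
  const double* src = x.begin();
  for (int i = 0; i < n; ++i) {
    float* dst = out.slice(i).memptr();
    const double* s = src + (size_t)i * C * T;
    for (int ch = 0; ch < C; ++ch)
      for (int t = 0; t < T; ++t) dst[(size_t)ch * T + t] = (float)s[ch + (size_t)t * C];
  }
  return out;
}

double eval_loss_acc(const fcube& X, const IntegerVector& y, const NetCfg& c,
                     const Weights& W, Work& w, double* acc_out) {
  int n = X.n_slices;
  double loss = 0; int correct = 0;
  std::vector<int> idx;
  for (int start = 0; start < n; start += w.Bmax) {
    int B = std::min(w.Bmax, n - start);
    idx.resize(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    forward(X, idx, B, c, const_cast<Weights&>(W), w, false);
    for (int b = 0; b < B; ++b) {
      float p = std::max(w.probs(y[start + b], b), 1e-12f);
      loss += -std::log((double)p);
      if ((int)w.probs.col(b).index_max() == y[start + b]) ++correct;
    }
  }
  if (acc_out) *acc_out = (double)correct / n;
  return loss / n;
}

}  // namespace

// [[Rcpp::export]]
List cppNetTrain(NumericVector Xtr, IntegerVector ytr, NumericVector Xval,
                 IntegerVector yval, List weights, List cfg, NumericVector clsw,
                 int maxEpochs, int batchSize, double lr, int seed) {
  fcube X = to_fcube(Xtr), Xv = to_fcube(Xval);
  NetCfg c = read_cfg(cfg, X.n_cols, X.n_rows);
  Weights W = read_weights(weights);
  Adam A; A.init(W);
  int n = X.n_slices;
  int Bmax = std::max(batchSize, 1);
  Work w; w.init(c, Bmax);
  Work wev; wev.init(c, std::min(64, std::max(1, (int)Xv.n_slices)));

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  float keep = 1.0f - (float)c.dropout;

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  fvec cw = as<fvec>(clsw);

  Grads G;
  G.W1.set_size(arma::size(W.W1)); G.Wd.set_size(arma::size(W.Wd));
  G.Wsd.set_size(arma::size(W.Wsd)); G.Wsp.set_size(arma::size(W.Wsp));
  G.Wf.set_size(arma::size(W.Wf)); G.bf.set_size(arma::size(W.bf));
  G.g1.set_size(arma::size(W.g1)); G.b1.set_size(arma::size(W.b1));
  G.g2.set_size(arma::size(W.g2)); G.b2.set_size(arma::size(W.b2));
  G.g3.set_size(arma::size(W.g3)); G.b3.set_size(arma::size(W.b3));

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  NumericVector trainLoss(maxEpochs), valLoss(maxEpochs);
  double bestVal = R_PosInf;
  int bestEpoch = 0;
  Weights Wbest = W;
  fmat dlogits(c.N, Bmax);
  std::vector<int> idx;

  for (int ep = 0; ep < maxEpochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double epLoss = 0; int nBatches = 0;
    for (int start = 0; start < n; start += batchSize) {
      int B = std::min(batchSize, n - start);
      idx.assign(perm.begin() + start, perm.begin() + start + B);

      // fresh inverted-dropout masks
      for (int b = 0; b < B; ++b) {
        float* m1 = w.M1.slice(b).memptr();
        for (uword i = 0; i < (uword)c.T1 * c.F2; ++i)
          m1[i] = unif(rng) < keep ? 1.0f / keep : 0.0f;
        float* m2 = w.M2.slice(b).memptr();
        for (uword i = 0; i < (uword)c.T2 * c.F2; ++i)
          m2[i] = unif(rng) < keep ? 1.0f / keep : 0.0f;
      }

      forward(X, idx, B, c, W, w, true);

      // class-weighted cross-entropy; dlogits = w_i (p - onehot) / sum(w)
      double sw = 0, lsum = 0;
      for (int b = 0; b < B; ++b) sw += cw(ytr[idx[b]]);
      for (int b = 0; b < B; ++b) {
        int yy = ytr[idx[b]];
        float p = std::max(w.probs(yy, b), 1e-12f);
        lsum += cw(yy) * -std::log((double)p);
        for (int k = 0; k < c.N; ++k) {
          float tgt = (k == yy) ? 1.0f : 0.0f;
          dlogits(k, b) = cw(yy) * (w.probs(k, b) - tgt) / (float)sw;
        }
      }
      epLoss += lsum / sw; ++nBatches;

      G.W1.zeros(); G.Wd.zeros(); G.Wsd.zeros(); G.Wsp.zeros();
      G.Wf.zeros(); G.bf.zeros();
      G.g1.zeros(); G.b1.zeros(); G.g2.zeros(); G.b2.zeros();
      G.g3.zeros(); G.b3.zeros();
      backward(X, idx, B, c, W, w, dlogits.cols(0, B - 1), G, true);

      A.t += 1;
      float c1 = 1.0f - std::pow(b1, (float)A.t);
      float c2 = 1.0f - std::pow(b2, (float)A.t);
      adam_step(W.W1, A.mW1, A.vW1, G.W1, lr, b1, b2, eps, c1, c2);
      adam_step(W.Wd, A.mWd, A.vWd, G.Wd, lr, b1, b2, eps, c1, c2);
      adam_step(W.Wsd, A.mWsd, A.vWsd, G.Wsd, lr, b1, b2, eps, c1, c2);
      adam_step(W.Wsp, A.mWsp, A.vWsp, G.Wsp, lr, b1, b2, eps, c1, c2);
      adam_step(W.Wf, A.mWf, A.vWf, G.Wf, lr, b1, b2, eps, c1, c2);
      adam_step(W.bf, A.mbf, A.vbf, G.bf, lr, b1, b2, eps, c1, c2);
      adam_step(W.g1, A.mg1, A.vg1, G.g1, lr, b1, b2, eps, c1, c2);
      adam_step(W.b1, A.mb1, A.vb1, G.b1, lr, b1, b2, eps, c1, c2);
      adam_step(W.g2, A.mg2, A.vg2, G.g2, lr, b1, b2, eps, c1, c2);
      adam_step(W.b2, A.mb2, A.vb2, G.b2, lr, b1, b2, eps, c1, c2);
      adam_step(W.g3, A.mg3, A.vg3, G.g3, lr, b1, b2, eps, c1, c2);
      adam_step(W.b3, A.mb3, A.vb3, G.b3, lr, b1, b2, eps, c1, c2);

      // max-norm constraints: depthwise spatial filters (rows of Wd) <= 1,
      // incoming dense weights per class (rows of Wf) <= 0.25
      for (uword r = 0; r < W.Wd.n_rows; ++r) {
        float nn = arma::norm(W.Wd.row(r), 2);
        if (nn > 1.0f) W.Wd.row(r) *= 1.0f / nn;
      }
      for (uword r = 0; r < W.Wf.n_rows; ++r) {
        float nn = arma::norm(W.Wf.row(r), 2);
        if (nn > 0.25f) W.Wf.row(r) *= 0.25f / nn;
      }
    }
    trainLoss[ep] = epLoss / nBatches;
    valLoss[ep] = eval_loss_acc(Xv, yval, c, W, wev, nullptr);
    if (valLoss[ep] < bestVal) {
      bestVal = valLoss[ep];
      bestEpoch = ep + 1;
      Wbest = W;
    }
  }

  return List::create(
    _["weights"] = dump_weights(Wbest),
    _["finalWeights"] = dump_weights(W),
    _["trainLoss"] = trainLoss,
    _["valLoss"] = valLoss,
    _["bestEpoch"] = bestEpoch);
}

// [[Rcpp::export]]
List cppNetPredict(NumericVector Xin, List weights, List cfg) {
  fcube X = to_fcube(Xin);
  NetCfg c = read_cfg(cfg, X.n_cols, X.n_rows);
  Weights W = read_weights(weights);
  int n = X.n_slices;
  Work w; w.init(c, std::min(64, std::max(1, n)));
  NumericMatrix logits(n, c.N), probs(n, c.N);
  std::vector<int> idx;
  for (int start = 0; start < n; start += w.Bmax) {
    int B = std::min(w.Bmax, n - start);
    idx.resize(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    forward(X, idx, B, c, W, w, false);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < c.N; ++k) {
        logits(start + b, k) = w.logits(k, b);
        probs(start + b, k) = w.probs(k, b);
      }
  }
  return List::create(_["scores"] = logits, _["probabilities"] = probs);
}

// Gradient of the pre-softmax score of classIdx (0-based, per trial) with
// respect to the input, evaluated in inference mode (no dropout, running
// batch-norm statistics). Returns an array shaped like the input.
// [[Rcpp::export]]
NumericVector cppNetInputGrad(NumericVector Xin, List weights, List cfg,
                              IntegerVector classIdx) {
  fcube X = to_fcube(Xin);
  NetCfg c = read_cfg(cfg, X.n_cols, X.n_rows);
  Weights W = read_weights(weights);
  int n = X.n_slices;
  if (classIdx.size() != n) stop("classIdx must have one entry per trial");
  Work w; w.init(c, std::min(32, std::max(1, n)));
  fcube dX(arma::size(X), arma::fill::zeros);

  Grads G;  // discarded, but backward() accumulates into it
  G.W1.zeros(arma::size(W.W1)); G.Wd.zeros(arma::size(W.Wd));
  G.Wsd.zeros(arma::size(W.Wsd)); G.Wsp.zeros(arma::size(W.Wsp));
  G.Wf.zeros(arma::size(W.Wf)); G.bf.zeros(arma::size(W.bf));
  G.g1.zeros(arma::size(W.g1)); G.b1.zeros(arma::size(W.b1));
  G.g2.zeros(arma::size(W.g2)); G.b2.zeros(arma::size(W.b2));
  G.g3.zeros(arma::size(W.g3)); G.b3.zeros(arma::size(W.b3));

  fmat dlogits(c.N, w.Bmax);
  std::vector<int> idx;
  for (int start = 0; start < n; start += w.Bmax) {
    int B = std::min(w.Bmax, n - start);
    idx.resize(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    forward(X, idx, B, c, W, w, false);
    dlogits.zeros();
    for (int b = 0; b < B; ++b) {
      int k = classIdx[start + b];
      if (k < 0 || k >= c.N) stop("class index out of range");
      dlogits(k, b) = 1.0f;
    }
    backward(X, idx, B, c, W, w, dlogits.cols(0, B - 1), G, false, &dX);
  }

  // back to the R layout (C x T x trials); internal slices are (T x C)
  NumericVector out(dX.n_elem);
  out.attr("dim") = IntegerVector::create(c.C, c.T, n);
  for (int i = 0; i < n; ++i) {
    const float* src = dX.slice(i).memptr();
    double* dst = out.begin() + (size_t)i * c.C * c.T;
    for (int ch = 0; ch < c.C; ++ch)
      for (int t = 0; t < c.T; ++t) {
        float v = src[(size_t)ch * c.T + t];
        if (!std::isfinite(v)) stop("non-finite saliency gradient");
        dst[ch + (size_t)t * c.C] = (double)v;
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Artifact criteria scanner. data: C x T x trials array (microvolts).
// Criteria per epoch, any channel:
//   step : |x[t+1] - x[t]| > stepThr (uV between adjacent samples)
//   range: sliding max-min over rangeWin samples > rangeThr on some window
//   flat : some channel whose max-min < flatThr in EVERY flatWin window
// Returns an (trials x 3) logical matrix (step, range, flat).
// [[Rcpp::export]]
LogicalMatrix cppEpochArtifacts(NumericVector data, double stepThr,
                                int rangeWin, double rangeThr, int flatWin,
                                double flatThr) {
  IntegerVector d = data.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  int C = d[0], T = d[1], n = d[2];
  LogicalMatrix out(n, 3);
  const double* p = data.begin();

  // sliding-window max-min via monotonic deques
  auto window_ranges = [&](const std::vector<double>& x, int w,
                           std::vector<double>& rng) {
    int len = (int)x.size();
    int nw = len - w + 1;
    rng.assign(std::max(nw, 0), 0.0);
    std::deque<int> qmax, qmin;
    for (int i = 0; i < len; ++i) {
      while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
      qmax.push_back(i);
      while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
      qmin.push_back(i);
      int lo = i - w + 1;
      if (lo >= 0) {
        while (qmax.front() < lo) qmax.pop_front();
        while (qmin.front() < lo) qmin.pop_front();
        rng[lo] = x[qmax.front()] - x[qmin.front()];
      }
    }
  };

  std::vector<double> x(T), rng;
  for (int i = 0; i < n; ++i) {
    bool step = false, range = false, flat = false;
    for (int ch = 0; ch < C; ++ch) {
      for (int t = 0; t < T; ++t) x[t] = p[(size_t)i * C * T + (size_t)t * C + ch];
      if (!step) {
        for (int t = 0; t + 1 < T; ++t)
          if (std::fabs(x[t + 1] - x[t]) > stepThr) { step = true; break; }
      }
      if (!range && rangeWin <= T) {
        window_ranges(x, rangeWin, rng);
        for (double r : rng) if (r > rangeThr) { range = true; break; }
      }
      if (!flat && flatWin <= T) {
        window_ranges(x, flatWin, rng);
        bool all_small = true;
        for (double r : rng) if (r >= flatThr) { all_small = false; break; }
        if (all_small) flat = true;
      }
      if (step && range && flat) break;
    }
    out(i, 0) = step; out(i, 1) = range; out(i, 2) = flat;
  }
  return out;
}
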
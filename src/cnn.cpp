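// Convolutional classifier for 64x64 plantar pressure maps with a
// laterality embedding, implemented directly on BLAS (im2col + gemm,
// single precision).  Also implements the multiplier back-propagation
// (rescale rule) used for Shapley-additive per-pixel attributions.
//
// Architecture: three blocks of [conv3x3 -> BN -> ReLU] x2 -> maxpool2x2
// -> channel dropout, filter counts configurable (default 32/64/128);
// flattened features concatenated with an embedding of the integer side
// label; head = FC (no bias) -> BN -> ReLU -> dropout -> FC -> logits.
//
// Pixel index convention: q = r + c*S (column-major, matching R matrices).
// Activation layout: [channels x (S*S*batch)], sample b occupying the
// contiguous column block [b*S*S, (b+1)*S*S).
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;

// ---------------------------------------------------------------------------
// deterministic RNG (mt19937 + Box-Muller; avoids implementation-defined
// std::*_distribution behaviour)
struct Rng {
  std::mt19937 g;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t seed) : g(seed) {}
  double unif() { return (g() >> 5) * (1.0 / 134217728.0); }  // [0,1)
  int unif_int(int n) { return (int)(g() % (uint32_t)n); }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 1e-12) u1 = unif();
    u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// architecture description
struct Arch {
  int S0 = 64;            // input spatial size
  int in_ch = 1;
  std::vector<int> filters;  // per block
  int emb_dim, head_width, n_classes, n_sides = 2;
  float conv_dropout, head_dropout;
  int n_blocks() const { return (int)filters.size(); }
  int out_spatial() const { return S0 >> n_blocks(); }
  int flat_dim() const { return filters.back() * out_spatial() * out_spatial(); }
};

struct Params {
  std::vector<fmat> Wc;                    // conv weights [F, Cin*9]
  std::vector<fvec> gamma, beta, rmean, rvar;  // one per conv layer + head BN (last)
  fmat emb;                                // [emb_dim, n_sides]
  fmat W1;                                 // [head_width, flat+emb_dim]
  fmat W2;                                 // [n_classes, head_width]
  fvec b2;
};

static Params init_params(const Arch& a, Rng& rng) {
  Params p;
  int nb = a.n_blocks(), nconv = 2 * nb;
  p.Wc.resize(nconv);
  p.gamma.resize(nconv + 1); p.beta.resize(nconv + 1);
  p.rmean.resize(nconv + 1); p.rvar.resize(nconv + 1);
  int cin = a.in_ch;
  for (int b = 0; b < nb; ++b) {
    for (int l = 0; l < 2; ++l) {
      int i = 2 * b + l;
      int f = a.filters[b];
      double sd = std::sqrt(2.0 / (9.0 * cin));
      p.Wc[i].set_size(f, cin * 9);
      for (auto& w : p.Wc[i]) w = (float)(sd * rng.norm());
      p.gamma[i] = fvec(f, arma::fill::ones);
      p.beta[i] = fvec(f, arma::fill::zeros);
      p.rmean[i] = fvec(f, arma::fill::zeros);
      p.rvar[i] = fvec(f, arma::fill::ones);
      cin = f;
    }
  }
  p.emb.set_size(a.emb_dim, a.n_sides);  // standard embedding init, N(0,1)
  for (auto& w : p.emb) w = (float)rng.norm();
  int fdim = a.flat_dim() + a.emb_dim;
  p.W1.set_size(a.head_width, fdim);
  { double sd = std::sqrt(2.0 / fdim);
    for (auto& w : p.W1) w = (float)(sd * rng.norm()); }
  p.gamma[nconv] = fvec(a.head_width, arma::fill::ones);
  p.beta[nconv] = fvec(a.head_width, arma::fill::zeros);
  p.rmean[nconv] = fvec(a.head_width, arma::fill::zeros);
  p.rvar[nconv] = fvec(a.head_width, arma::fill::ones);
  p.W2.set_size(a.n_classes, a.head_width);
  { double sd = std::sqrt(1.0 / a.head_width);
    for (auto& w : p.W2) w = (float)(sd * rng.norm()); }
  p.b2 = fvec(a.n_classes, arma::fill::zeros);
  return p;
}

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 kernels with zero padding 1.  The column matrix
// has 9C rows (offset-major blocks of C channels) and one column per
// output pixel; pixels of one image column are memory-contiguous, so the
// copies below run over long strided spans with a vectorizable inner loop.
static void im2col3(const fmat& A, int S, int B, fmat& col) {
  const int C = A.n_rows, HW = S * S;
  col.set_size((size_t)9 * C, (size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < S; ++c) {
      const float* srccol[3];  // image columns c-1, c, c+1
      for (int dci = 0; dci < 3; ++dci) {
        int sc = c + dci - 1;
        srccol[dci] = (sc >= 0 && sc < S)
          ? A.colptr((size_t)b * HW + (size_t)sc * S) : nullptr;
      }
      float* dst = col.colptr((size_t)b * HW + (size_t)c * S);
      for (int r = 0; r < S; ++r) {
        for (int dci = 0; dci < 3; ++dci) {
          for (int dri = 0; dri < 3; ++dri) {
            int rr = r + dri - 1;
            const float* src =
              (srccol[dci] && rr >= 0 && rr < S)
                ? srccol[dci] + (size_t)rr * C : nullptr;
            if (src) {
              for (int i = 0; i < C; ++i) dst[i] = src[i];
            } else {
              for (int i = 0; i < C; ++i) dst[i] = 0.0f;
            }
            dst += C;
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& col, int S, int B, fmat& A) {
  const int C = A.n_rows, HW = S * S;
  A.zeros();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < S; ++c) {
      float* dstcol[3];
      for (int dci = 0; dci < 3; ++dci) {
        int sc = c + dci - 1;
        dstcol[dci] = (sc >= 0 && sc < S)
          ? A.colptr((size_t)b * HW + (size_t)sc * S) : nullptr;
      }
      const float* cp = col.colptr((size_t)b * HW + (size_t)c * S);
      for (int r = 0; r < S; ++r) {
        for (int dci = 0; dci < 3; ++dci) {
          for (int dri = 0; dri < 3; ++dri) {
            int rr = r + dri - 1;
            float* dst = (dstcol[dci] && rr >= 0 && rr < S)
              ? dstcol[dci] + (size_t)rr * C : nullptr;
            if (dst) {
              for (int i = 0; i < C; ++i) dst[i] += cp[i];
            }
            cp += C;
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// batch norm over rows (channel/feature in rows, batch*spatial in cols)
struct BnCache { fmat xhat; fvec istd; };

static void bn_forward_train(fmat& X, fvec& gamma, fvec& beta, fvec& rmean,
                             fvec& rvar, BnCache& cache, float momentum = 0.1f,
                             float eps = 1e-5f) {
  const int C = X.n_rows;
  const size_t N = X.n_cols;
  std::vector<double> s(C, 0.0), ss(C, 0.0);
  for (size_t j = 0; j < N; ++j) {
    const float* p = X.colptr(j);
    for (int i = 0; i < C; ++i) {
      s[i] += p[i];
      ss[i] += (double)p[i] * p[i];
    }
  }
  fvec mu(C), var(C);
  for (int i = 0; i < C; ++i) {
    double m = s[i] / N;
    mu[i] = (float)m;
    var[i] = (float)std::max(ss[i] / N - m * m, 0.0);
  }
  cache.istd = 1.0f / arma::sqrt(var + eps);
  cache.xhat.set_size(X.n_rows, X.n_cols);
  for (size_t j = 0; j < N; ++j) {
    float* p = X.colptr(j);
    float* xh = cache.xhat.colptr(j);
    for (int i = 0; i < C; ++i) {
      float h = (p[i] - mu[i]) * cache.istd[i];
      xh[i] = h;
      p[i] = gamma[i] * h + beta[i];
    }
  }
  float unb = N > 1 ? (float)N / (N - 1) : 1.0f;
  rmean = (1 - momentum) * rmean + momentum * mu;
  rvar = (1 - momentum) * rvar + momentum * (var * unb);
}

static void bn_forward_eval(fmat& X, const fvec& gamma, const fvec& beta,
                            const fvec& rmean, const fvec& rvar,
                            float eps = 1e-5f) {
  const int C = X.n_rows;
  const size_t N = X.n_cols;
  fvec sc(C), sh(C);
  for (int i = 0; i < C; ++i) {
    sc[i] = gamma[i] / std::sqrt(rvar[i] + eps);
    sh[i] = beta[i] - rmean[i] * sc[i];
  }
  for (size_t j = 0; j < N; ++j) {
    float* p = X.colptr(j);
    for (int i = 0; i < C; ++i) p[i] = sc[i] * p[i] + sh[i];
  }
}

static void bn_backward(fmat& dY, const BnCache& cache, const fvec& gamma,
                        fvec& dgamma, fvec& dbeta) {
  const int C = dY.n_rows;
  const size_t N = dY.n_cols;
  std::vector<double> sdy(C, 0.0), sdyx(C, 0.0);
  for (size_t j = 0; j < N; ++j) {
    const float* dp = dY.colptr(j);
    const float* xh = cache.xhat.colptr(j);
    for (int i = 0; i < C; ++i) {
      sdy[i] += dp[i];
      sdyx[i] += (double)dp[i] * xh[i];
    }
  }
  dgamma.set_size(C); dbeta.set_size(C);
  fvec k(C), av(C), bv(C);
  for (int i = 0; i < C; ++i) {
    dgamma[i] = (float)sdyx[i];
    dbeta[i] = (float)sdy[i];
    k[i] = gamma[i] * cache.istd[i] / (float)N;
    av[i] = (float)sdy[i];
    bv[i] = (float)sdyx[i];
  }
  for (size_t j = 0; j < N; ++j) {
    float* dp = dY.colptr(j);
    const float* xh = cache.xhat.colptr(j);
    for (int i = 0; i < C; ++i)
      dp[i] = k[i] * ((float)N * dp[i] - av[i] - xh[i] * bv[i]);
  }
}

// ---------------------------------------------------------------------------
// max pool 2x2 stride 2 over the pixel blocks; records winner offset 0..3
static void maxpool_forward(const fmat& A, int S, int B, fmat& out,
                            arma::Mat<unsigned char>& arg) {
  const int C = A.n_rows, S2 = S / 2, HW = S * S, HW2 = S2 * S2;
  out.set_size(C, (size_t)HW2 * B);
  arg.set_size(C, (size_t)HW2 * B);
  for (int b = 0; b < B; ++b) {
    for (int c2 = 0; c2 < S2; ++c2) {
      for (int r2 = 0; r2 < S2; ++r2) {
        size_t oc = (size_t)b * HW2 + (size_t)c2 * S2 + r2;
        size_t q0 = (size_t)b * HW + (size_t)(2 * c2) * S + 2 * r2;
        const float* p0 = A.colptr(q0);          // (2r2,   2c2)
        const float* p1 = A.colptr(q0 + 1);      // (2r2+1, 2c2)
        const float* p2 = A.colptr(q0 + S);      // (2r2,   2c2+1)
        const float* p3 = A.colptr(q0 + S + 1);  // (2r2+1, 2c2+1)
        float* op = out.colptr(oc);
        unsigned char* ap = arg.colptr(oc);
        for (int i = 0; i < C; ++i) {
          float v = p0[i]; unsigned char w = 0;
          if (p1[i] > v) { v = p1[i]; w = 1; }
          if (p2[i] > v) { v = p2[i]; w = 2; }
          if (p3[i] > v) { v = p3[i]; w = 3; }
          op[i] = v; ap[i] = w;
        }
      }
    }
  }
}

static void maxpool_backward(const fmat& dOut, int S, int B,
                             const arma::Mat<unsigned char>& arg, fmat& dA) {
  const int C = dOut.n_rows, S2 = S / 2, HW = S * S, HW2 = S2 * S2;
  dA.zeros(C, (size_t)HW * B);
  const size_t off[4] = {0, 1, (size_t)S, (size_t)S + 1};
  for (int b = 0; b < B; ++b) {
    for (int c2 = 0; c2 < S2; ++c2) {
      for (int r2 = 0; r2 < S2; ++r2) {
        size_t oc = (size_t)b * HW2 + (size_t)c2 * S2 + r2;
        size_t q0 = (size_t)b * HW + (size_t)(2 * c2) * S + 2 * r2;
        const float* dp = dOut.colptr(oc);
        const unsigned char* ap = arg.colptr(oc);
        for (int i = 0; i < C; ++i) dA(i, q0 + off[ap[i]]) += dp[i];
      }
    }
  }
}

// ---------------------------------------------------------------------------
// flatten [C x HW*B] -> [C*HW x B] (channel-major feature order)
static void flatten(const fmat& A, int HW, int B, fmat& out, int extra_rows) {
  const int C = A.n_rows;
  out.zeros((size_t)C * HW + extra_rows, B);
  for (int b = 0; b < B; ++b)
    for (int q = 0; q < HW; ++q) {
      const float* src = A.colptr((size_t)b * HW + q);
      for (int i = 0; i < C; ++i) out((size_t)i * HW + q, b) = src[i];
    }
}

static void unflatten(const fmat& dF, int C, int HW, int B, fmat& dA) {
  dA.set_size(C, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    for (int q = 0; q < HW; ++q) {
      float* dst = dA.colptr((size_t)b * HW + q);
      for (int i = 0; i < C; ++i) dst[i] = dF((size_t)i * HW + q, b);
    }
}

// ---------------------------------------------------------------------------
// forward pass (training mode caches everything needed for the gradients)
struct FwdCache {
  std::vector<fmat> col;           // im2col matrix of each conv layer
  std::vector<BnCache> bn;         // conv BNs + head BN (last)
  std::vector<fmat> relu_out;      // post-ReLU activation of each conv layer
  std::vector<arma::Mat<unsigned char>> pool_arg;
  std::vector<fmat> drop_mask;     // per-block channel dropout [C x B]
  fmat flat;                       // [flat+emb x B] post-concat
  fmat h1;                         // post-ReLU head activation
  fmat head_drop;                  // head dropout mask
  fmat dcol;                       // backward scratch
};

static fmat forward(const Arch& a, Params& p, const fmat& X,
                    const std::vector<int>& sides, bool train, Rng* rng,
                    FwdCache* cache) {
  const int B = X.n_cols, nb = a.n_blocks(), nconv = 2 * nb;
  fmat A = X;  // [1 x 4096] rows? input arrives as [npix x B] -> reshape
  // reinterpret input as [in_ch x HW*B]
  {
    fmat A0(a.in_ch, (size_t)a.S0 * a.S0 * B);
    std::memcpy(A0.memptr(), X.memptr(), X.n_elem * sizeof(float));
    A = std::move(A0);
  }
  if (cache) {
    cache->col.resize(nconv);
    cache->bn.resize(nconv + 1);
    cache->relu_out.resize(nconv);
    cache->pool_arg.resize(nb);
    cache->drop_mask.resize(nb);
  }
  int S = a.S0;
  fmat local_col, Z;
  for (int b = 0; b < nb; ++b) {
    for (int l = 0; l < 2; ++l) {
      int i = 2 * b + l;
      fmat& col = cache ? cache->col[i] : local_col;
      im2col3(A, S, B, col);
      Z = p.Wc[i] * col;
      if (train)
        bn_forward_train(Z, p.gamma[i], p.beta[i], p.rmean[i], p.rvar[i],
                         cache->bn[i]);
      else
        bn_forward_eval(Z, p.gamma[i], p.beta[i], p.rmean[i], p.rvar[i]);
      Z.transform([](float v) { return v > 0 ? v : 0.0f; });
      if (cache) cache->relu_out[i] = Z;
      A = std::move(Z);
    }
    // pool
    fmat pooled;
    arma::Mat<unsigned char> arg;
    maxpool_forward(A, S, B, pooled, arg);
    if (cache) cache->pool_arg[b] = std::move(arg);
    S /= 2;
    A = std::move(pooled);
    // channel dropout
    if (train && a.conv_dropout > 0) {
      const int C = A.n_rows, HW = S * S;
      fmat mask(C, B);
      float keep = 1.0f - a.conv_dropout;
      for (auto& m : mask) m = (rng->unif() < keep) ? 1.0f / keep : 0.0f;
      for (int bb = 0; bb < B; ++bb)
        for (int q = 0; q < HW; ++q) {
          float* ap = A.colptr((size_t)bb * HW + q);
          for (int i = 0; i < C; ++i) ap[i] *= mask(i, bb);
        }
      cache->drop_mask[b] = std::move(mask);
    }
  }
  // flatten + embedding concat
  const int HW = S * S;
  fmat F;
  flatten(A, HW, B, F, a.emb_dim);
  const int fd = a.flat_dim();
  for (int b2 = 0; b2 < B; ++b2)
    for (int e = 0; e < a.emb_dim; ++e) F(fd + e, b2) = p.emb(e, sides[b2]);
  if (cache) cache->flat = F;
  // head
  fmat H = p.W1 * F;
  if (train)
    bn_forward_train(H, p.gamma[nconv], p.beta[nconv], p.rmean[nconv],
                     p.rvar[nconv], cache->bn[nconv]);
  else
    bn_forward_eval(H, p.gamma[nconv], p.beta[nconv], p.rmean[nconv],
                    p.rvar[nconv]);
  H.transform([](float v) { return v > 0 ? v : 0.0f; });
  if (cache) cache->h1 = H;
  if (train && a.head_dropout > 0) {
    float keep = 1.0f - a.head_dropout;
    fmat mask(H.n_rows, H.n_cols);
    for (auto& m : mask) m = (rng->unif() < keep) ? 1.0f / keep : 0.0f;
    H %= mask;
    cache->head_drop = std::move(mask);
  }
  fmat logits = p.W2 * H;
  logits.each_col() += p.b2;
  return logits;
}

// softmax over rows per column
static fmat softmax(const fmat& logits) {
  fmat P = logits;
  for (size_t j = 0; j < P.n_cols; ++j) {
    float mx = P.col(j).max();
    P.col(j) = arma::exp(P.col(j) - mx);
    P.col(j) /= arma::accu(P.col(j));
  }
  return P;
}

// weighted cross-entropy (mean weighted by class weight, as in standard
// weighted-CE implementations); returns loss, fills dLogits if requested
static double wce_loss(const fmat& logits, const std::vector<int>& y,
                       const fvec& w, fmat* dLogits) {
  const int B = logits.n_cols;
  fmat P = softmax(logits);
  double loss = 0, wsum = 0;
  for (int j = 0; j < B; ++j) {
    loss += -w[y[j]] * std::log(std::max(P(y[j], j), 1e-12f));
    wsum += w[y[j]];
  }
  loss /= wsum;
  if (dLogits) {
    *dLogits = P;
    for (int j = 0; j < B; ++j) {
      (*dLogits)(y[j], j) -= 1.0f;
      dLogits->col(j) *= (float)(w[y[j]] / wsum);
    }
  }
  return loss;
}

// ---------------------------------------------------------------------------
// gradients container + Adam
struct Grads {
  std::vector<fmat> Wc;
  std::vector<fvec> gamma, beta;
  fmat emb, W1, W2;
  fvec b2;
};

struct Adam {
  std::vector<fmat> mWc, vWc;
  std::vector<fvec> mg, vg, mb, vb;
  fmat memb, vemb, mW1, vW1, mW2, vW2;
  fvec mb2, vb2;
  long t = 0;
  void init(const Params& p) {
    size_t n = p.Wc.size();
    mWc.resize(n); vWc.resize(n);
    mg.resize(p.gamma.size()); vg.resize(p.gamma.size());
    mb.resize(p.beta.size()); vb.resize(p.beta.size());
    for (size_t i = 0; i < n; ++i) {
      mWc[i].zeros(arma::size(p.Wc[i])); vWc[i].zeros(arma::size(p.Wc[i]));
    }
    for (size_t i = 0; i < p.gamma.size(); ++i) {
      mg[i].zeros(p.gamma[i].n_elem); vg[i].zeros(p.gamma[i].n_elem);
      mb[i].zeros(p.beta[i].n_elem); vb[i].zeros(p.beta[i].n_elem);
    }
    memb.zeros(arma::size(p.emb)); vemb.zeros(arma::size(p.emb));
    mW1.zeros(arma::size(p.W1)); vW1.zeros(arma::size(p.W1));
    mW2.zeros(arma::size(p.W2)); vW2.zeros(arma::size(p.W2));
    mb2.zeros(p.b2.n_elem); vb2.zeros(p.b2.n_elem);
  }
  template <class M>
  void upd(M& w, M& m, M& v, const M& g, float lr, float bc1, float bc2) {
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8f);
  }
  void step(Params& p, const Grads& g, float lr) {
    ++t;
    float bc1 = 1.0f - std::pow(0.9f, (float)t);
    float bc2 = 1.0f - std::pow(0.999f, (float)t);
    for (size_t i = 0; i < p.Wc.size(); ++i)
      upd(p.Wc[i], mWc[i], vWc[i], g.Wc[i], lr, bc1, bc2);
    for (size_t i = 0; i < p.gamma.size(); ++i) {
      upd(p.gamma[i], mg[i], vg[i], g.gamma[i], lr, bc1, bc2);
      upd(p.beta[i], mb[i], vb[i], g.beta[i], lr, bc1, bc2);
    }
    upd(p.emb, memb, vemb, g.emb, lr, bc1, bc2);
    upd(p.W1, mW1, vW1, g.W1, lr, bc1, bc2);
    upd(p.W2, mW2, vW2, g.W2, lr, bc1, bc2);
    upd(p.b2, mb2, vb2, g.b2, lr, bc1, bc2);
  }
};

static void backward(const Arch& a, const Params& p, const FwdCache& cache,
                     const std::vector<int>& sides, fmat dLogits, Grads& g) {
  const int B = dLogits.n_cols, nb = a.n_blocks(), nconv = 2 * nb;
  g.Wc.resize(nconv);
  g.gamma.resize(nconv + 1); g.beta.resize(nconv + 1);
  // head (h1 is cached pre-dropout; apply the mask for the W2 gradient)
  if (a.head_dropout > 0)
    g.W2 = dLogits * (cache.h1 % cache.head_drop).t();
  else
    g.W2 = dLogits * cache.h1.t();
  g.b2 = arma::sum(dLogits, 1);
  fmat dH = p.W2.t() * dLogits;
  if (a.head_dropout > 0) dH %= cache.head_drop;
  for (size_t j = 0; j < dH.n_elem; ++j)
    if (cache.h1[j] <= 0) dH[j] = 0;
  bn_backward(dH, cache.bn[nconv], p.gamma[nconv], g.gamma[nconv], g.beta[nconv]);
  g.W1 = dH * cache.flat.t();
  fmat dF = p.W1.t() * dH;
  // embedding grad
  g.emb.zeros(arma::size(p.emb));
  const int fd = a.flat_dim();
  for (int b2 = 0; b2 < B; ++b2)
    for (int e = 0; e < a.emb_dim; ++e) g.emb(e, sides[b2]) += dF(fd + e, b2);
  // unflatten conv part
  int S = a.out_spatial();
  fmat dA;
  unflatten(dF.rows(0, fd - 1), a.filters.back(), S * S, B, dA);
  fmat dcol;
  for (int b = nb - 1; b >= 0; --b) {
    // channel dropout backward
    if (a.conv_dropout > 0) {
      const int C = dA.n_rows, HW = S * S;
      for (int bb = 0; bb < B; ++bb)
        for (int q = 0; q < HW; ++q) {
          float* dp = dA.colptr((size_t)bb * HW + q);
          for (int i = 0; i < C; ++i) dp[i] *= cache.drop_mask[b](i, bb);
        }
    }
    // pool backward (input spatial = 2S)
    fmat dPrev;
    maxpool_backward(dA, 2 * S, B, cache.pool_arg[b], dPrev);
    S *= 2;
    dA = std::move(dPrev);
    for (int l = 1; l >= 0; --l) {
      int i = 2 * b + l;
      for (size_t j = 0; j < dA.n_elem; ++j)
        if (cache.relu_out[i][j] <= 0) dA[j] = 0;
      bn_backward(dA, cache.bn[i], p.gamma[i], g.gamma[i], g.beta[i]);
      const fmat& col = cache.col[i];
      g.Wc[i] = dA * col.t();
      dcol = p.Wc[i].t() * dA;
      fmat dIn(col.n_rows / 9, col.n_cols);
      col2im3(dcol, S, B, dIn);
      dA = std::move(dIn);
    }
  }
}

// ---------------------------------------------------------------------------
// R interface helpers
static Arch arch_from_list(const List& cfg) {
  Arch a;
  a.filters = as<std::vector<int>>(cfg["filters"]);
  a.emb_dim = as<int>(cfg["emb_dim"]);
  a.head_width = as<int>(cfg["head_width"]);
  a.n_classes = as<int>(cfg["n_classes"]);
  a.conv_dropout = (float)as<double>(cfg["conv_dropout"]);
  a.head_dropout = (float)as<double>(cfg["head_dropout"]);
  return a;
}

static List params_to_list(const Params& p) {
  List wc, gam, bet, rm, rv;
  for (size_t i = 0; i < p.Wc.size(); ++i)
    wc.push_back(NumericMatrix(wrap(arma::conv_to<arma::mat>::from(p.Wc[i]))));
  for (size_t i = 0; i < p.gamma.size(); ++i) {
    gam.push_back(wrap(arma::conv_to<arma::vec>::from(p.gamma[i])));
    bet.push_back(wrap(arma::conv_to<arma::vec>::from(p.beta[i])));
    rm.push_back(wrap(arma::conv_to<arma::vec>::from(p.rmean[i])));
    rv.push_back(wrap(arma::conv_to<arma::vec>::from(p.rvar[i])));
  }
  return List::create(
      _["Wc"] = wc, _["gamma"] = gam, _["beta"] = bet, _["rmean"] = rm,
      _["rvar"] = rv,
      _["emb"] = wrap(arma::conv_to<arma::mat>::from(p.emb)),
      _["W1"] = wrap(arma::conv_to<arma::mat>::from(p.W1)),
      _["W2"] = wrap(arma::conv_to<arma::mat>::from(p.W2)),
      _["b2"] = wrap(arma::conv_to<arma::vec>::from(p.b2)));
}

static Params params_from_list(const List& lp) {
  Params p;
  List wc = lp["Wc"], gam = lp["gamma"], bet = lp["beta"], rm = lp["rmean"],
       rv = lp["rvar"];
  for (int i = 0; i < wc.size(); ++i)
    p.Wc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(wc[i])));
  for (int i = 0; i < gam.size(); ++i) {
    p.gamma.push_back(arma::conv_to<fvec>::from(as<arma::vec>(gam[i])));
    p.beta.push_back(arma::conv_to<fvec>::from(as<arma::vec>(bet[i])));
    p.rmean.push_back(arma::conv_to<fvec>::from(as<arma::vec>(rm[i])));
    p.rvar.push_back(arma::conv_to<fvec>::from(as<arma::vec>(rv[i])));
  }
  p.emb = arma::conv_to<fmat>::from(as<arma::mat>(lp["emb"]));
  p.W1 = arma::conv_to<fmat>::from(as<arma::mat>(lp["W1"]));
  p.W2 = arma::conv_to<fmat>::from(as<arma::mat>(lp["W2"]));
  p.b2 = arma::conv_to<fvec>::from(as<arma::vec>(lp["b2"]));
  return p;
}

static double eval_loss(const Arch& a, Params& p, const fmat& X,
                        const std::vector<int>& sides, const std::vector<int>& y,
                        const fvec& w, int eval_batch = 256) {
  const int N = X.n_cols;
  double loss = 0, wsum = 0;
  for (int s = 0; s < N; s += eval_batch) {
    int e = std::min(N, s + eval_batch);
    fmat Xb = X.cols(s, e - 1);
    std::vector<int> sb(sides.begin() + s, sides.begin() + e);
    std::vector<int> yb(y.begin() + s, y.begin() + e);
    fmat logits = forward(a, p, Xb, sb, false, nullptr, nullptr);
    fmat P = softmax(logits);
    for (int j = 0; j < e - s; ++j) {
      loss += -w[yb[j]] * std::log(std::max(P(yb[j], j), 1e-12f));
      wsum += w[yb[j]];
    }
  }
  return loss / wsum;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat& Xtr, IntegerVector side_tr,
                   IntegerVector y_tr, const arma::mat& Xval,
                   IntegerVector side_val, IntegerVector y_val,
                   List arch_cfg, NumericVector class_weights, double lr,
                   int batch, int max_epochs, int patience, double min_delta,
                   bool balanced_sampling, int seed, bool verbose) {
#ifdef __GLIBC__
  // keep the large per-batch workspaces in the heap instead of
  // mmap/munmap-ing them on every minibatch
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  Arch a = arch_from_list(arch_cfg);
  Rng rng((uint32_t)seed);
  Params p = init_params(a, rng);
  Adam opt; opt.init(p);
  fmat Xtr_f = arma::conv_to<fmat>::from(Xtr);
  fmat Xval_f = arma::conv_to<fmat>::from(Xval);
  std::vector<int> str(side_tr.begin(), side_tr.end());
  std::vector<int> ytr(y_tr.begin(), y_tr.end());
  std::vector<int> sval(side_val.begin(), side_val.end());
  std::vector<int> yval(y_val.begin(), y_val.end());
  fvec w = arma::conv_to<fvec>::from(as<arma::vec>(class_weights));
  const int N = Xtr_f.n_cols, K = a.n_classes;
  // per-class index pools for balanced sampling
  std::vector<std::vector<int>> by_class(K);
  for (int i = 0; i < N; ++i) by_class[ytr[i]].push_back(i);
  std::vector<double> tr_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  double improve_ref = std::numeric_limits<double>::infinity();
  Params best = p;
  int best_epoch = -1, last_improve = -1;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // epoch ordering
    std::vector<int> order(N);
    if (balanced_sampling) {
      for (int i = 0; i < N; ++i) {
        int c = rng.unif_int(K);
        while (by_class[c].empty()) c = rng.unif_int(K);
        order[i] = by_class[c][rng.unif_int((int)by_class[c].size())];
      }
    } else {
      for (int i = 0; i < N; ++i) order[i] = i;
      for (int i = N - 1; i > 0; --i) std::swap(order[i], order[rng.unif_int(i + 1)]);
    }
    double ep_loss = 0;
    int nb_done = 0;
    FwdCache cache;
    Grads g;
    fmat Xb, logits, dLogits;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch);
      if (e - s < 2) break;  // batch norm needs >= 2 samples
      Xb.set_size(Xtr_f.n_rows, e - s);
      std::vector<int> sb(e - s), yb(e - s);
      for (int j = s; j < e; ++j) {
        Xb.col(j - s) = Xtr_f.col(order[j]);
        sb[j - s] = str[order[j]];
        yb[j - s] = ytr[order[j]];
      }
      logits = forward(a, p, Xb, sb, true, &rng, &cache);
      ep_loss += wce_loss(logits, yb, w, &dLogits);
      ++nb_done;
      backward(a, p, cache, sb, dLogits, g);
      opt.step(p, g, (float)lr);
    }
    double vl = eval_loss(a, p, Xval_f, sval, yval, w);
    tr_hist.push_back(ep_loss / std::max(nb_done, 1));
    val_hist.push_back(vl);
    if (vl < best_val) {  // checkpoint: strictly lowest validation loss
      best_val = vl;
      best = p;
      best_epoch = epoch;
    }
    if (vl < improve_ref - min_delta) {  // meaningful improvement
      improve_ref = vl;
      last_improve = epoch;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch + 1 << " train " << tr_hist.back()
                  << " val " << vl << std::endl;
    Rcpp::checkUserInterrupt();
    if (epoch - last_improve >= patience) break;
  }
  return List::create(_["params"] = params_to_list(best),
                      _["train_loss"] = wrap(tr_hist),
                      _["val_loss"] = wrap(val_hist),
                      _["best_epoch"] = best_epoch + 1);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(List param_list, List arch_cfg,
                              const arma::mat& X, IntegerVector side) {
  Arch a = arch_from_list(arch_cfg);
  Params p = params_from_list(param_list);
  fmat Xf = arma::conv_to<fmat>::from(X);
  std::vector<int> sd(side.begin(), side.end());
  const int N = Xf.n_cols, eb = 256;
  arma::mat out(a.n_classes, N);
  for (int s = 0; s < N; s += eb) {
    int e = std::min(N, s + eb);
    fmat Xb = Xf.cols(s, e - 1);
    std::vector<int> sb(sd.begin() + s, sd.begin() + e);
    fmat P = softmax(forward(a, p, Xb, sb, false, nullptr, nullptr));
    out.cols(s, e - 1) = arma::conv_to<arma::mat>::from(P);
  }
  return wrap(out);
}

// ---------------------------------------------------------------------------
// DeepLIFT-style multiplier propagation (rescale rule) for Shapley-additive
// attributions.  For each background reference the contributions to the
// target-class logit satisfy summation-to-delta exactly: linear layers and
// eval-mode BN are linear, ReLU uses the rescale multiplier, and max-pool
// assigns the window's output delta to the input with the largest |delta|.

struct EvalActs {
  std::vector<fmat> conv_in, relu_out;  // per conv layer, single sample
  fmat flat, h1_pre;                    // h1_pre = post-BN pre-ReLU head
  fvec logits;
};

static void forward_eval_single(const Arch& a, Params& p, const fvec& x,
                                int side, EvalActs& acts) {
  const int nb = a.n_blocks(), nconv = 2 * nb;
  fmat A(a.in_ch, (size_t)a.S0 * a.S0);
  std::memcpy(A.memptr(), x.memptr(), x.n_elem * sizeof(float));
  acts.conv_in.resize(nconv);
  acts.relu_out.resize(nconv);
  int S = a.S0;
  fmat col, Z;
  for (int b = 0; b < nb; ++b) {
    for (int l = 0; l < 2; ++l) {
      int i = 2 * b + l;
      acts.conv_in[i] = A;
      im2col3(A, S, 1, col);
      Z = p.Wc[i] * col;
      bn_forward_eval(Z, p.gamma[i], p.beta[i], p.rmean[i], p.rvar[i]);
      Z.transform([](float v) { return v > 0 ? v : 0.0f; });
      acts.relu_out[i] = Z;
      A = Z;
    }
    fmat pooled; arma::Mat<unsigned char> arg;
    maxpool_forward(A, S, 1, pooled, arg);
    S /= 2;
    A = std::move(pooled);
  }
  flatten(A, S * S, 1, acts.flat, a.emb_dim);
  const int fd = a.flat_dim();
  for (int e = 0; e < a.emb_dim; ++e) acts.flat(fd + e, 0) = p.emb(e, side);
  fmat H = p.W1 * acts.flat;
  bn_forward_eval(H, p.gamma[nconv], p.beta[nconv], p.rmean[nconv], p.rvar[nconv]);
  acts.h1_pre = H;
  H.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat L = p.W2 * H;
  L.each_col() += p.b2;
  acts.logits = L.col(0);
}

// rescale multiplier for an elementwise ReLU given pre-activation deltas
static inline float rescale_m(float zx, float zr) {
  float dz = zx - zr;
  if (std::fabs(dz) < 1e-7f) return zx > 0 ? 1.0f : 0.0f;
  float ax = zx > 0 ? zx : 0.0f, ar = zr > 0 ? zr : 0.0f;
  return (ax - ar) / dz;
}

// [[Rcpp::export(name = ".cnn_deeplift_cpp")]]
List cnn_deeplift_cpp(List param_list, List arch_cfg, const arma::vec& x,
                      int side, const arma::mat& bgX, IntegerVector bg_side,
                      int target) {
  Arch a = arch_from_list(arch_cfg);
  Params p = params_from_list(param_list);
  const int nb = a.n_blocks(), nconv = 2 * nb, M = bgX.n_cols;
  fvec xf = arma::conv_to<fvec>::from(x);
  EvalActs ax_;
  forward_eval_single(a, p, xf, side, ax_);
  arma::vec attr(a.S0 * a.S0, arma::fill::zeros);
  double emb_attr = 0, base_sum = 0, delta_err = 0;
  for (int m = 0; m < M; ++m) {
    fvec rf = arma::conv_to<fvec>::from(bgX.col(m));
    EvalActs ar_;
    forward_eval_single(a, p, rf, bg_side[m], ar_);
    base_sum += ar_.logits[target];
    // start multipliers at the target logit
    fvec mh(a.head_width);
    for (int i = 0; i < a.head_width; ++i) mh[i] = p.W2(target, i);
    for (int i = 0; i < a.head_width; ++i)
      mh[i] *= rescale_m(ax_.h1_pre(i, 0), ar_.h1_pre(i, 0));
    // head BN eval is linear: scale gamma*istd built into W1 path
    fvec scale(a.head_width);
    for (int i = 0; i < a.head_width; ++i)
      scale[i] = p.gamma[nconv][i] / std::sqrt(p.rvar[nconv][i] + 1e-5f);
    mh %= scale;
    fvec mflat = p.W1.t() * mh;  // multipliers on [flat + emb]
    const int fd = a.flat_dim();
    // embedding contribution
    for (int e = 0; e < a.emb_dim; ++e)
      emb_attr += mflat[fd + e] * (p.emb(e, side) - p.emb(e, bg_side[m]));
    // conv part
    int S = a.out_spatial();
    fmat mA;
    {
      fmat tmp(fd, 1);
      for (int i = 0; i < fd; ++i) tmp(i, 0) = mflat[i];
      unflatten(tmp, a.filters.back(), S * S, 1, mA);
    }
    for (int b = nb - 1; b >= 0; --b) {
      // max-pool: route the output delta to the input with largest |delta|
      int S2 = S, Sin = 2 * S;
      const int C = mA.n_rows, HWin = Sin * Sin, HW2 = S2 * S2;
      const fmat& inx = ax_.relu_out[2 * b + 1];
      const fmat& inr = ar_.relu_out[2 * b + 1];
      fmat mPrev(C, HWin, arma::fill::zeros);
      const size_t off[4] = {0, 1, (size_t)Sin, (size_t)Sin + 1};
      for (int c2 = 0; c2 < S2; ++c2)
        for (int r2 = 0; r2 < S2; ++r2) {
          size_t oc = (size_t)c2 * S2 + r2;
          size_t q0 = (size_t)(2 * c2) * Sin + 2 * r2;
          for (int i = 0; i < C; ++i) {
            float vx = -1e30f, vr = -1e30f;
            float dbest = 0; size_t jbest = q0;
            for (int k = 0; k < 4; ++k) {
              float ix = inx(i, q0 + off[k]), ir = inr(i, q0 + off[k]);
              vx = std::max(vx, ix); vr = std::max(vr, ir);
              float d = ix - ir;
              if (std::fabs(d) > std::fabs(dbest)) { dbest = d; jbest = q0 + off[k]; }
            }
            float dout = vx - vr;
            if (std::fabs(dbest) > 1e-9f)
              mPrev(i, jbest) = mA(i, oc) * dout / dbest;
          }
        }
      S = Sin;
      mA = std::move(mPrev);
      for (int l = 1; l >= 0; --l) {
        int i = 2 * b + l;
        // ReLU rescale: pre-activation = BN(eval) of conv out; deltas of the
        // pre-activations equal deltas of relu inputs; use relu_out and the
        // linear BN to recover them.  We recompute pre-activations cheaply
        // from conv outputs of both passes.
        fmat colx, colr;
        im2col3(ax_.conv_in[i], S, 1, colx);
        im2col3(ar_.conv_in[i], S, 1, colr);
        fmat zx = p.Wc[i] * colx, zr = p.Wc[i] * colr;
        bn_forward_eval(zx, p.gamma[i], p.beta[i], p.rmean[i], p.rvar[i]);
        bn_forward_eval(zr, p.gamma[i], p.beta[i], p.rmean[i], p.rvar[i]);
        for (size_t j = 0; j < mA.n_elem; ++j)
          mA[j] *= rescale_m(zx[j], zr[j]);
        // BN eval linear scale
        const int C2 = mA.n_rows;
        for (int ch = 0; ch < C2; ++ch) {
          float sc = p.gamma[i][ch] / std::sqrt(p.rvar[i][ch] + 1e-5f);
          mA.row(ch) *= sc;
        }
        // conv transpose
        fmat mcol = p.Wc[i].t() * mA;
        fmat mIn(ax_.conv_in[i].n_rows, ax_.conv_in[i].n_cols);
        col2im3(mcol, S, 1, mIn);
        mA = std::move(mIn);
      }
    }
    // input contributions: multiplier times input delta
    for (int q = 0; q < a.S0 * a.S0; ++q)
      attr[q] += mA(0, q) * (xf[q] - rf[q]);
    delta_err += 0;  // completeness holds by construction; kept for clarity
  }
  attr /= M;
  emb_attr /= M;
  double baseline = base_sum / M;
  return List::create(_["attr"] = wrap(attr), _["emb_attr"] = emb_attr,
                      _["fx"] = (double)ax_.logits[target],
                      _["baseline"] = baseline);
}
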
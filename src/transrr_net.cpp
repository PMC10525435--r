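// Compiled core of the TransRR network: forward pass, hand-derived
// backpropagation, Adam training loop with plateau LR schedule and early
// stopping. Parameters live in one flat vector; arma::mat views (no copy)
// index into it via a layout table built from the config.
//
// Attention is computed in a low-rank form: with module width W the score
// matrix is S = Z~ A_h Z~^T where Z~ = [Z, 1] (L x (W+1)) and
// A_h = Wq~_h Wk~_h^T / sqrt(hs) is (W+1) x (W+1).  For the default W = 2
// this avoids ever forming L x head_size products inside the L x L GEMMs.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

static const double LN_EPS = 1e-6;

// Fast single-precision exp for softmax scores (arguments are
// max-subtracted, so x <= 0): magic-constant rounding splits x/ln2 into an
// integer exponent (assembled into the float's exponent bits) and a
// fractional part handled by a degree-5 polynomial. Relative error ~1e-5 —
// below single precision's own noise in the attention weights, and the
// backward pass uses the probabilities actually stored, so gradients stay
// consistent with the forward map.
// Hot per-head kernels for the default module width (W = 2, augmented
// A = 3).  Compiled twice via target_clones: an AVX2 version used when the
// CPU supports it and a baseline fallback, resolved once at load time.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define TRANSRR_CLONES __attribute__((target_clones("avx2", "default")))
#else
#define TRANSRR_CLONES
#endif

static inline float softmax_expf(float x) {
  x = x < -80.0f ? -80.0f : x;
  const float magic = 12582912.0f;        // 1.5 * 2^23
  float t = x * 1.44269504f;              // x / ln 2
  float tk = t + magic;
  uint32_t bits;
  std::memcpy(&bits, &tk, 4);
  int32_t k = (int32_t)(bits << 10) >> 10;  // sign-extended round(t)
  float f = t - (tk - magic);               // in [-0.5, 0.5]
  float r = f * 0.69314718f;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.16666667f +
            r * (0.041666667f + r * 0.0083333333f))));
  uint32_t b2 = (uint32_t)(k + 127) << 23;
  float s;
  std::memcpy(&s, &b2, 4);
  return p * s;
}

// forward attention for one head, A = 3: unnormalized exp scores (column i
// of E = scores of query i) plus the row-sum inverses
TRANSRR_CLONES
static void attn_fwd_head3(int L, const float* RESTRICT z0,
                           const float* RESTRICT z1, const float* RESTRICT z2,
                           const double* RESTRICT U, float* RESTRICT E,
                           float* RESTRICT inv_out) {
  for (int i = 0; i < L; i++) {
    float u0 = (float)U[i], u1 = (float)U[L + i], u2 = (float)U[2 * L + i];
    float* RESTRICT p = E + (size_t)i * L;
    float mx = -1e30f;
    for (int j = 0; j < L; j++) {
      float s = u0 * z0[j] + u1 * z1[j] + u2 * z2[j];
      p[j] = s;
      mx = s > mx ? s : mx;
    }
    float tot = 0;
    for (int j = 0; j < L; j++) {
      float e = softmax_expf(p[j] - mx);
      p[j] = e;
      tot += e;
    }
    inv_out[i] = 1.0f / tot;
  }
}

// fused softmax backward for one head, A = 3 (see derivation at the call
// site); accumulates into dz*, writes dU (L x 3, column-major)
TRANSRR_CLONES
static void attn_bwd_head3(int L, const float* RESTRICT z0,
                           const float* RESTRICT z1, const float* RESTRICT z2,
                           const float* RESTRICT E, const float* RESTRICT inv,
                           const double* RESTRICT Gm, const double* RESTRICT U,
                           float* RESTRICT dz0, float* RESTRICT dz1,
                           float* RESTRICT dz2, double* RESTRICT dU,
                           float* RESTRICT dp) {
  for (int i = 0; i < L; i++) {
    const float* RESTRICT p = E + (size_t)i * L;
    float in = inv[i];
    float g0 = (float)Gm[i], g1 = (float)Gm[L + i], g2 = (float)Gm[2 * L + i];
    float v0 = (float)U[i], v1 = (float)U[L + i], v2 = (float)U[2 * L + i];
    float rdot = 0;
    for (int j = 0; j < L; j++) {
      float d = g0 * z0[j] + g1 * z1[j] + g2 * z2[j];
      dp[j] = d;
      rdot += d * (p[j] * in);
    }
    float s0 = 0, s1 = 0, s2 = 0;
    for (int j = 0; j < L; j++) {
      float pj = p[j] * in;
      float ds = pj * (dp[j] - rdot);
      dz0[j] += pj * g0 + ds * v0;
      dz1[j] += pj * g1 + ds * v1;
      dz2[j] += pj * g2 + ds * v2;
      s0 += ds * z0[j];
      s1 += ds * z1[j];
      s2 += ds * z2[j];
    }
    dU[i] = s0;
    dU[L + i] = s1;
    dU[2 * L + i] = s2;
  }
}

// ---------------------------------------------------------------------------
// config / layout

struct NetConfig {
  int L, C, W, B, H, hs, dk, bc;
  std::vector<int> ks, dr, fc;
  double dropout;
  bool use_kern, use_dil;
  int D() const { return H * hs; }
  int kout() const { return use_kern ? (int)ks.size() * bc : W; }
  int dout() const { return use_dil ? (int)dr.size() * bc : kout(); }
};

static NetConfig parse_config(const Rcpp::List& cfg) {
  NetConfig c;
  c.L = Rcpp::as<int>(cfg["input_len"]);
  c.C = Rcpp::as<int>(cfg["input_channels"]);
  c.W = Rcpp::as<int>(cfg["module_width"]);
  c.B = Rcpp::as<int>(cfg["n_blocks"]);
  c.H = Rcpp::as<int>(cfg["n_heads"]);
  c.hs = Rcpp::as<int>(cfg["head_size"]);
  c.dk = Rcpp::as<int>(cfg["dilation_kernel"]);
  c.bc = Rcpp::as<int>(cfg["branch_channels"]);
  c.ks = Rcpp::as<std::vector<int>>(cfg["kernel_sizes"]);
  c.dr = Rcpp::as<std::vector<int>>(cfg["dilation_rates"]);
  c.fc = Rcpp::as<std::vector<int>>(cfg["fc_sizes"]);
  c.dropout = Rcpp::as<double>(cfg["dropout_rate"]);
  c.use_kern = Rcpp::as<bool>(cfg["use_kernel_inception"]);
  c.use_dil = Rcpp::as<bool>(cfg["use_dilated_inception"]);
  return c;
}

struct TensorSlot { size_t off, r, c; };

struct BlockIdx {
  int Wq, bq, Wk, bk, Wv, bv, Wo, bo, g1, b1, k0, d0, Aw, Ab, g2, b2;
};

struct Layout {
  std::vector<TensorSlot> slots;
  size_t total = 0;
  int inW = -1, inb = -1;
  std::vector<BlockIdx> blk;
  int fc0 = -1;
  int add(size_t r, size_t c) {
    slots.push_back({total, r, c});
    total += r * c;
    return (int)slots.size() - 1;
  }
};

static Layout make_layout(const NetConfig& c) {
  Layout lay;
  if (c.W != c.C) {
    lay.inW = lay.add(c.C, c.W);
    lay.inb = lay.add(1, c.W);
  }
  for (int b = 0; b < c.B; b++) {
    BlockIdx bi;
    bi.Wq = lay.add(c.W, c.D()); bi.bq = lay.add(1, c.D());
    bi.Wk = lay.add(c.W, c.D()); bi.bk = lay.add(1, c.D());
    bi.Wv = lay.add(c.W, c.D()); bi.bv = lay.add(1, c.D());
    bi.Wo = lay.add(c.D(), c.W); bi.bo = lay.add(1, c.W);
    bi.g1 = lay.add(1, c.W); bi.b1 = lay.add(1, c.W);
    bi.k0 = -1; bi.d0 = -1;
    if (c.use_kern) {
      bi.k0 = (int)lay.slots.size();
      for (int k : c.ks) { lay.add((size_t)k * c.W, c.bc); lay.add(1, c.bc); }
    }
    if (c.use_dil) {
      bi.d0 = (int)lay.slots.size();
      for (size_t j = 0; j < c.dr.size(); j++) {
        lay.add((size_t)c.dk * c.kout(), c.bc); lay.add(1, c.bc);
      }
    }
    bi.Aw = lay.add(c.dout(), c.W); bi.Ab = lay.add(1, c.W);
    bi.g2 = lay.add(1, c.W); bi.b2 = lay.add(1, c.W);
    lay.blk.push_back(bi);
  }
  lay.fc0 = (int)lay.slots.size();
  int fin = c.L * c.W;
  for (int f : c.fc) { lay.add(fin, f); lay.add(1, f); fin = f; }
  return lay;
}

// non-owning matrix views into a flat parameter (or gradient) vector
struct Views {
  std::vector<mat> v;
  Views(double* base, const Layout& lay) {
    v.reserve(lay.slots.size());
    for (const TensorSlot& s : lay.slots)
      v.emplace_back(base + s.off, s.r, s.c, false, true);
  }
  mat& operator[](int i) { return v[i]; }
};

// ---------------------------------------------------------------------------
// deterministic rng (independent of stdlib distribution implementations)

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// positional encoding (sin/cos interleaved, d = input channels)

static mat pos_encoding(int L, int d) {
  mat pe(L, d);
  for (int j = 0; j < d; j++) {
    int i2 = 2 * (j / 2);
    double denom = std::pow(10000.0, (double)i2 / d);
    for (int p = 0; p < L; p++) {
      double a = p / denom;
      pe(p, j) = (j % 2 == 0) ? std::sin(a) : std::cos(a);
    }
  }
  return pe;
}

// ---------------------------------------------------------------------------
// caches

struct BlockCache {
  mat Zin, Zt;                 // block input, augmented [Z, 1]
  fmat Ztf;                    // single-precision copy for the L x L kernels
  // Et[h] holds the UNNORMALIZED softmax numerators TRANSPOSED (column i =
  // exp scores of query position i; multiply by sinv[h][i] to normalize) so
  // the fused row-wise kernels touch contiguous single-precision memory.
  std::vector<fmat> Et;
  std::vector<fvec> sinv;
  std::vector<mat> PZ, Ah, U;
  mat O, attn;
  mat R1, N1h, N1;
  double istd1 = 0;
  std::vector<mat> Kcol, Dcol;
  mat KpreAll, Kout, dropmask, Kdrop;
  mat DpreAll, Dout;
  mat Adj, R2, N2h, N2;
  double istd2 = 0;
};

struct Cache {
  mat Xpe;                          // PE-augmented input (kept for projection grad)
  mat Zin0;
  std::vector<BlockCache> blk;
  std::vector<vec> a, pre, fmask;   // fc activations / pre-activations / masks
};

// ---------------------------------------------------------------------------
// layers

static void layer_norm_fwd(const mat& R, const rowvec& g, const rowvec& b,
                           mat& Nh, mat& N, double& istd) {
  double m = accu(R) / R.n_elem;
  double v = accu(square(R - m)) / R.n_elem;
  istd = 1.0 / std::sqrt(v + LN_EPS);
  Nh = (R - m) * istd;
  N = Nh;
  N.each_row() %= g;
  N.each_row() += b;
}

static mat layer_norm_bwd(const mat& dN, const mat& Nh, const rowvec& g,
                          double istd, mat& dg, mat& db) {
  dg += sum(dN % Nh, 0);
  db += sum(dN, 0);
  mat dNh = dN;
  dNh.each_row() %= g;
  double m1 = accu(dNh) / dNh.n_elem;
  double m2 = accu(dNh % Nh) / dNh.n_elem;
  return istd * (dNh - m1 - Nh * m2);
}

// im2col for 1-D same-padded (possibly dilated) convolution
static void im2col(const mat& In, int k, int dil, mat& M) {
  int L = In.n_rows, inC = In.n_cols, ctr = (k - 1) / 2;
  M.zeros(L, (size_t)k * inC);
  for (int j = 0; j < k; j++) {
    int s = (j - ctr) * dil;
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    M.submat(t0, j * inC, t1, (j + 1) * inC - 1) = In.rows(t0 + s, t1 + s);
  }
}

static void col2im_add(const mat& dM, int k, int dil, mat& dIn) {
  int L = dIn.n_rows, inC = dIn.n_cols, ctr = (k - 1) / 2;
  for (int j = 0; j < k; j++) {
    int s = (j - ctr) * dil;
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    dIn.rows(t0 + s, t1 + s) += dM.submat(t0, j * inC, t1, (j + 1) * inC - 1);
  }
}

// ---------------------------------------------------------------------------
// forward

static double forward_example(const NetConfig& c, const Layout& lay, Views& P,
                              const mat& pe, const rowvec& xrow, Cache& cc,
                              bool training, Rng* rng) {
  int L = c.L, W = c.W;
  mat X(L, c.C);
  for (int ch = 0; ch < c.C; ch++)
    X.col(ch) = xrow.subvec((size_t)ch * L, (size_t)(ch + 1) * L - 1).t();
  X += pe;
  if (c.W != c.C) {
    cc.Xpe = X;
    cc.Zin0 = X * P[lay.inW];
    cc.Zin0.each_row() += P[lay.inb].row(0);
  } else {
    cc.Zin0 = X;
  }
  cc.blk.resize(c.B);
  double scale = 1.0 / std::sqrt((double)c.hs);
  mat Z = cc.Zin0;
  for (int b = 0; b < c.B; b++) {
    BlockCache& bc = cc.blk[b];
    const BlockIdx& bi = lay.blk[b];
    bc.Zin = Z;
    int A = W + 1;
    bc.Zt.set_size(L, A);
    bc.Zt.cols(0, W - 1) = Z;
    bc.Zt.col(W).ones();
    // augmented projection matrices (weights stacked over bias row)
    mat Wqt = join_cols(P[bi.Wq], P[bi.bq]);
    mat Wkt = join_cols(P[bi.Wk], P[bi.bk]);
    mat Wvt = join_cols(P[bi.Wv], P[bi.bv]);
    bc.Ztf = conv_to<fmat>::from(bc.Zt);
    bc.Et.resize(c.H); bc.sinv.resize(c.H);
    bc.PZ.resize(c.H); bc.Ah.resize(c.H); bc.U.resize(c.H);
    bc.O.set_size(L, c.D());
    std::vector<const float*> zp(A);
    for (int a = 0; a < A; a++) zp[a] = bc.Ztf.colptr(a);
    std::vector<float> ui(A);
    for (int h = 0; h < c.H; h++) {
      int c0 = h * c.hs, c1 = (h + 1) * c.hs - 1;
      bc.Ah[h] = Wqt.cols(c0, c1) * Wkt.cols(c0, c1).t() * scale;
      bc.U[h] = bc.Zt * bc.Ah[h];
      bc.Et[h].set_size(L, L);
      bc.sinv[h].set_size(L);
      // fused scores + exp; column i of Et = unnormalized attention of
      // query position i
      const double* u = bc.U[h].memptr();
      if (A == 3) {
        attn_fwd_head3(L, zp[0], zp[1], zp[2], u, bc.Et[h].memptr(),
                       bc.sinv[h].memptr());
      } else {
        for (int i = 0; i < L; i++) {
          float* RESTRICT p = bc.Et[h].colptr(i);
          for (int a = 0; a < A; a++) ui[a] = (float)u[(size_t)a * L + i];
          float mx = -datum::inf;
          for (int j = 0; j < L; j++) {
            float s = 0;
            for (int a = 0; a < A; a++) s += ui[a] * zp[a][j];
            p[j] = s;
            mx = s > mx ? s : mx;
          }
          float tot = 0;
          for (int j = 0; j < L; j++) {
            float e = softmax_expf(p[j] - mx);
            p[j] = e;
            tot += e;
          }
          bc.sinv[h](i) = 1.0f / tot;
        }
      }
      fmat PZf = bc.Et[h].t() * bc.Ztf;      // sgemm over the big block
      PZf.each_col() %= bc.sinv[h];
      bc.PZ[h] = conv_to<mat>::from(PZf);
      bc.O.cols(c0, c1) = bc.PZ[h] * Wvt.cols(c0, c1);
    }
    bc.attn = bc.O * P[bi.Wo];
    bc.attn.each_row() += P[bi.bo].row(0);
    bc.R1 = bc.Zin + bc.attn;
    layer_norm_fwd(bc.R1, P[bi.g1].row(0), P[bi.b1].row(0), bc.N1h, bc.N1,
                   bc.istd1);
    // kernel inception
    mat Kin = bc.N1;
    if (c.use_kern) {
      int nb = (int)c.ks.size();
      bc.Kcol.resize(nb);
      bc.KpreAll.set_size(L, c.kout());
      for (int j = 0; j < nb; j++) {
        im2col(Kin, c.ks[j], 1, bc.Kcol[j]);
        mat pre = bc.Kcol[j] * P[bi.k0 + 2 * j];
        pre.each_row() += P[bi.k0 + 2 * j + 1].row(0);
        bc.KpreAll.cols(j * c.bc, (j + 1) * c.bc - 1) = pre;
      }
      bc.Kout = clamp(bc.KpreAll, 0.0, datum::inf);
      if (training && c.dropout > 0) {
        bc.dropmask.set_size(L, c.kout());
        double keep = 1.0 - c.dropout;
        for (uword i = 0; i < bc.dropmask.n_elem; i++)
          bc.dropmask(i) = (rng->unif() < keep) ? 1.0 / keep : 0.0;
        bc.Kdrop = bc.Kout % bc.dropmask;
      } else {
        bc.Kdrop = bc.Kout;
      }
    } else {
      bc.Kdrop = Kin;
    }
    // dilated inception
    if (c.use_dil) {
      int nb = (int)c.dr.size();
      bc.Dcol.resize(nb);
      bc.DpreAll.set_size(L, c.dout());
      for (int j = 0; j < nb; j++) {
        im2col(bc.Kdrop, c.dk, c.dr[j], bc.Dcol[j]);
        mat pre = bc.Dcol[j] * P[bi.d0 + 2 * j];
        pre.each_row() += P[bi.d0 + 2 * j + 1].row(0);
        bc.DpreAll.cols(j * c.bc, (j + 1) * c.bc - 1) = pre;
      }
      bc.Dout = clamp(bc.DpreAll, 0.0, datum::inf);
    } else {
      bc.Dout = bc.Kdrop;
    }
    // channel adjust (pointwise, linear)
    bc.Adj = bc.Dout * P[bi.Aw];
    bc.Adj.each_row() += P[bi.Ab].row(0);
    bc.R2 = bc.N1 + bc.Adj;
    layer_norm_fwd(bc.R2, P[bi.g2].row(0), P[bi.b2].row(0), bc.N2h, bc.N2,
                   bc.istd2);
    Z = bc.N2;
  }
  // head
  int nf = (int)c.fc.size();
  cc.a.assign(nf + 1, vec());
  cc.pre.assign(nf, vec());
  cc.fmask.assign(nf, vec());
  cc.a[0] = vectorise(Z);
  for (int i = 0; i < nf; i++) {
    cc.pre[i] = P[lay.fc0 + 2 * i].t() * cc.a[i] + P[lay.fc0 + 2 * i + 1].t();
    if (i < nf - 1) {
      vec h = clamp(cc.pre[i], 0.0, datum::inf);
      if (training && c.dropout > 0) {
        cc.fmask[i].set_size(h.n_elem);
        double keep = 1.0 - c.dropout;
        for (uword q = 0; q < h.n_elem; q++)
          cc.fmask[i](q) = (rng->unif() < keep) ? 1.0 / keep : 0.0;
        h %= cc.fmask[i];
      }
      cc.a[i + 1] = h;
    } else {
      cc.a[i + 1] = cc.pre[i];
    }
  }
  return cc.a[nf](0);
}

// ---------------------------------------------------------------------------
// backward (accumulates into gradient views G)

static void backward_example(const NetConfig& c, const Layout& lay, Views& P,
                             Views& G, Cache& cc, double dy, bool training) {
  int L = c.L, W = c.W, nf = (int)c.fc.size();
  double scale = 1.0 / std::sqrt((double)c.hs);
  vec da(1); da(0) = dy;
  for (int i = nf - 1; i >= 0; i--) {
    vec dpre;
    if (i < nf - 1) {
      vec dh = da;
      if (training && c.dropout > 0) dh %= cc.fmask[i];
      dpre = dh % conv_to<vec>::from(cc.pre[i] > 0);
    } else {
      dpre = da;
    }
    G[lay.fc0 + 2 * i] += cc.a[i] * dpre.t();
    G[lay.fc0 + 2 * i + 1] += dpre.t();
    da = P[lay.fc0 + 2 * i] * dpre;
  }
  mat dZ = reshape(da, L, W);
  for (int b = c.B - 1; b >= 0; b--) {
    BlockCache& bc = cc.blk[b];
    const BlockIdx& bi = lay.blk[b];
    // LN2
    mat dR2 = layer_norm_bwd(dZ, bc.N2h, P[bi.g2].row(0), bc.istd2,
                             G[bi.g2], G[bi.b2]);
    mat dN1 = dR2;           // residual into N1
    mat dAdj = dR2;
    // adjust conv
    G[bi.Aw] += bc.Dout.t() * dAdj;
    G[bi.Ab] += sum(dAdj, 0);
    mat dDout = dAdj * P[bi.Aw].t();
    // dilated inception
    mat dKdrop;
    if (c.use_dil) {
      dKdrop.zeros(L, bc.Kdrop.n_cols);
      mat dpre = dDout % conv_to<mat>::from(bc.DpreAll > 0);
      for (int j = (int)c.dr.size() - 1; j >= 0; j--) {
        mat dpj = dpre.cols(j * c.bc, (j + 1) * c.bc - 1);
        G[bi.d0 + 2 * j] += bc.Dcol[j].t() * dpj;
        G[bi.d0 + 2 * j + 1] += sum(dpj, 0);
        mat dM = dpj * P[bi.d0 + 2 * j].t();
        col2im_add(dM, c.dk, c.dr[j], dKdrop);
      }
    } else {
      dKdrop = dDout;
    }
    // kernel inception
    if (c.use_kern) {
      mat dKout = dKdrop;
      if (training && c.dropout > 0) dKout %= bc.dropmask;
      mat dpre = dKout % conv_to<mat>::from(bc.KpreAll > 0);
      mat dKin(L, W, fill::zeros);
      for (int j = (int)c.ks.size() - 1; j >= 0; j--) {
        mat dpj = dpre.cols(j * c.bc, (j + 1) * c.bc - 1);
        G[bi.k0 + 2 * j] += bc.Kcol[j].t() * dpj;
        G[bi.k0 + 2 * j + 1] += sum(dpj, 0);
        mat dM = dpj * P[bi.k0 + 2 * j].t();
        col2im_add(dM, c.ks[j], 1, dKin);
      }
      dN1 += dKin;
    } else {
      dN1 += dKdrop;
    }
    // LN1
    mat dR1 = layer_norm_bwd(dN1, bc.N1h, P[bi.g1].row(0), bc.istd1,
                             G[bi.g1], G[bi.b1]);
    mat dAttn = dR1;
    mat dZin = dR1;          // residual into block input
    // attention output projection
    G[bi.Wo] += bc.O.t() * dAttn;
    G[bi.bo] += sum(dAttn, 0);
    mat dO = dAttn * P[bi.Wo].t();
    mat Wqt = join_cols(P[bi.Wq], P[bi.bq]);
    mat Wkt = join_cols(P[bi.Wk], P[bi.bk]);
    mat Wvt = join_cols(P[bi.Wv], P[bi.bv]);
    int A = W + 1;
    mat dWqt(A, c.D(), fill::zeros), dWkt(A, c.D(), fill::zeros),
        dWvt(A, c.D(), fill::zeros);
    mat dZt(L, A, fill::zeros);
    fmat dZf(L, A, fill::zeros);   // accumulates the L x L kernel paths
    mat dU(L, A);
    std::vector<float> dp(L), gi(A), uu(A), du(A);
    std::vector<const float*> zp(A);
    std::vector<float*> dz(A);
    for (int a = 0; a < A; a++) {
      zp[a] = bc.Ztf.colptr(a);
      dz[a] = dZf.colptr(a);
    }
    for (int h = 0; h < c.H; h++) {
      int c0 = h * c.hs, c1 = (h + 1) * c.hs - 1;
      mat dOh = dO.cols(c0, c1);
      dWvt.cols(c0, c1) += bc.PZ[h].t() * dOh;
      mat Gm = dOh * Wvt.cols(c0, c1).t();          // L x (W+1)
      // fused softmax backward over query positions i:
      //   dP_ij = Gm_i . Zt_j;  dS_ij = P_ij (dP_ij - sum_j dP_ij P_ij)
      //   dZt_j += P_ij Gm_i + dS_ij U_i;  dU_i = sum_j dS_ij Zt_j
      if (A == 3) {
        attn_bwd_head3(L, zp[0], zp[1], zp[2], bc.Et[h].memptr(),
                       bc.sinv[h].memptr(), Gm.memptr(), bc.U[h].memptr(),
                       dz[0], dz[1], dz[2], dU.memptr(), dp.data());
      } else {
        for (int i = 0; i < L; i++) {
          const float* RESTRICT p = bc.Et[h].colptr(i);
          const float inv = bc.sinv[h](i);
          for (int a = 0; a < A; a++) {
            gi[a] = (float)Gm(i, a);
            uu[a] = (float)bc.U[h](i, a);
            du[a] = 0;
          }
          float rdot = 0;
          for (int j = 0; j < L; j++) {
            float d = 0;
            for (int a = 0; a < A; a++) d += gi[a] * zp[a][j];
            dp[j] = d;
            rdot += d * (p[j] * inv);
          }
          for (int j = 0; j < L; j++) {
            float pj = p[j] * inv;
            float ds = pj * (dp[j] - rdot);
            for (int a = 0; a < A; a++) {
              dz[a][j] += pj * gi[a] + ds * uu[a];
              du[a] += ds * zp[a][j];
            }
          }
          for (int a = 0; a < A; a++) dU(i, a) = du[a];
        }
      }
      dZt += dU * bc.Ah[h].t();
      mat dAh = bc.Zt.t() * dU;
      dWqt.cols(c0, c1) += dAh * Wkt.cols(c0, c1) * scale;
      dWkt.cols(c0, c1) += dAh.t() * Wqt.cols(c0, c1) * scale;
    }
    dZt += conv_to<mat>::from(dZf);
    G[bi.Wq] += dWqt.rows(0, W - 1); G[bi.bq] += dWqt.row(W);
    G[bi.Wk] += dWkt.rows(0, W - 1); G[bi.bk] += dWkt.row(W);
    G[bi.Wv] += dWvt.rows(0, W - 1); G[bi.bv] += dWvt.row(W);
    dZin += dZt.cols(0, W - 1);
    dZ = dZin;
  }
  if (c.W != c.C) {
    G[lay.inW] += cc.Xpe.t() * dZ;
    G[lay.inb] += sum(dZ, 0);
  }
}

// ---------------------------------------------------------------------------
// init

static vec init_params(const NetConfig& c, const Layout& lay, uint64_t seed) {
  vec th(lay.total, fill::zeros);
  Views V(th.memptr(), lay);
  Rng rng(seed);
  auto glorot = [&](mat& M, double fan_in, double fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    for (uword i = 0; i < M.n_elem; i++) M(i) = (2.0 * rng.unif() - 1.0) * lim;
  };
  if (c.W != c.C) glorot(V[lay.inW], c.C, c.W);
  for (int b = 0; b < c.B; b++) {
    const BlockIdx& bi = lay.blk[b];
    glorot(V[bi.Wq], c.W, c.D());
    glorot(V[bi.Wk], c.W, c.D());
    glorot(V[bi.Wv], c.W, c.D());
    glorot(V[bi.Wo], c.D(), c.W);
    V[bi.g1].ones(); V[bi.g2].ones();
    if (c.use_kern)
      for (size_t j = 0; j < c.ks.size(); j++)
        glorot(V[bi.k0 + 2 * j], (double)c.ks[j] * c.W, c.bc);
    if (c.use_dil)
      for (size_t j = 0; j < c.dr.size(); j++)
        glorot(V[bi.d0 + 2 * j], (double)c.dk * c.kout(), c.bc);
    glorot(V[bi.Aw], c.dout(), c.W);
  }
  int fin = c.L * c.W;
  for (size_t i = 0; i < c.fc.size(); i++) {
    glorot(V[lay.fc0 + 2 * i], fin, c.fc[i]);
    fin = c.fc[i];
  }
  return th;
}

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
int cpp_param_count(Rcpp::List cfg) {
  NetConfig c = parse_config(cfg);
  return (int)make_layout(c).total;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_init_params(Rcpp::List cfg, int seed) {
  NetConfig c = parse_config(cfg);
  Layout lay = make_layout(c);
  vec th = init_params(c, lay, (uint64_t)seed);
  return Rcpp::NumericVector(th.begin(), th.end());
}

// [[Rcpp::export]]
arma::mat cpp_positional_encoding(int L, int d) { return pos_encoding(L, d); }

// [[Rcpp::export]]
arma::vec cpp_forward(Rcpp::List cfg, arma::vec params, arma::mat X,
                      bool training = false, int seed = 0) {
  NetConfig c = parse_config(cfg);
  Layout lay = make_layout(c);
  if (params.n_elem != lay.total) Rcpp::stop("parameter vector length mismatch");
  if ((int)X.n_cols != c.L * c.C)
    Rcpp::stop("input row length %d does not match input_len %d x %d channels",
               (int)X.n_cols, c.L, c.C);
  Views P(params.memptr(), lay);
  mat pe = pos_encoding(c.L, c.C);
  Cache cc;
  Rng rng((uint64_t)seed);
  vec out(X.n_rows);
  for (uword i = 0; i < X.n_rows; i++)
    out(i) = forward_example(c, lay, P, pe, X.row(i), cc, training, &rng);
  return out;
}

// final pre-flatten activation (last block output) for one example
// [[Rcpp::export]]
arma::mat cpp_block_activation(Rcpp::List cfg, arma::vec params,
                               arma::rowvec xrow) {
  NetConfig c = parse_config(cfg);
  Layout lay = make_layout(c);
  if (params.n_elem != lay.total) Rcpp::stop("parameter vector length mismatch");
  Views P(params.memptr(), lay);
  mat pe = pos_encoding(c.L, c.C);
  Cache cc;
  forward_example(c, lay, P, pe, xrow, cc, false, nullptr);
  return cc.blk.back().N2;
}

// MAE loss and its gradient on a batch (eval-mode, deterministic)
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List cfg, arma::vec params, arma::mat X,
                         arma::vec y) {
  NetConfig c = parse_config(cfg);
  Layout lay = make_layout(c);
  Views P(params.memptr(), lay);
  vec grad(lay.total, fill::zeros);
  Views G(grad.memptr(), lay);
  mat pe = pos_encoding(c.L, c.C);
  Cache cc;
  double loss = 0;
  int n = (int)X.n_rows;
  for (int i = 0; i < n; i++) {
    double yh = forward_example(c, lay, P, pe, X.row(i), cc, false, nullptr);
    double e = yh - y(i);
    loss += std::abs(e) / n;
    double dy = (e > 0 ? 1.0 : (e < 0 ? -1.0 : 0.0)) / n;
    backward_example(c, lay, P, G, cc, dy, false);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") =
                                Rcpp::NumericVector(grad.begin(), grad.end()));
}

// full training loop: Adam + MAE, plateau LR schedule, early stopping,
// best-validation-epoch parameter restoration
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List cfg, arma::vec params, arma::mat Xtr,
                     arma::vec ytr, arma::mat Xval, arma::vec yval,
                     Rcpp::List tcfg) {
  NetConfig c = parse_config(cfg);
  Layout lay = make_layout(c);
  if (params.n_elem != lay.total) Rcpp::stop("parameter vector length mismatch");
  int epochs = Rcpp::as<int>(tcfg["epochs"]);
  int batch = Rcpp::as<int>(tcfg["batch_size"]);
  double lr = Rcpp::as<double>(tcfg["lr_init"]);
  double lr_floor = Rcpp::as<double>(tcfg["lr_floor"]);
  double lr_factor = Rcpp::as<double>(tcfg["lr_factor"]);
  int lr_patience = Rcpp::as<int>(tcfg["lr_patience"]);
  int es_patience = Rcpp::as<int>(tcfg["early_stop_patience"]);
  uint64_t seed = (uint64_t)Rcpp::as<int>(tcfg["seed"]);

  int n = (int)Xtr.n_rows;
  vec th = params;
  vec m(lay.total, fill::zeros), v(lay.total, fill::zeros);
  vec grad(lay.total, fill::zeros);
  double b1 = 0.9, b2 = 0.999, aeps = 1e-8;
  long tstep = 0;
  Rng rng(seed * 2654435761ULL + 1);
  mat pe = pos_encoding(c.L, c.C);
  Cache cc;
  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;

  std::vector<double> h_train, h_val, h_lr;
  double best_val = datum::inf;
  vec best_th = th;
  int best_epoch = 0, lr_wait = 0, es_wait = 0;

  auto eval_mae = [&](const mat& X, const vec& y, Views& P) {
    double s = 0;
    for (uword i = 0; i < X.n_rows; i++)
      s += std::abs(forward_example(c, lay, P, pe, X.row(i), cc, false,
                                    nullptr) - y(i));
    return s / X.n_rows;
  };

  for (int ep = 0; ep < epochs; ep++) {
    // Fisher-Yates shuffle with our rng (stdlib shuffle is not portable)
    for (int i = n - 1; i > 0; i--) {
      int j = (int)(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0;
    int nb = 0;
    Views P(th.memptr(), lay);
    Views G(grad.memptr(), lay);
    for (int start = 0; start < n; start += batch) {
      int stop = std::min(start + batch, n);
      int bn = stop - start;
      grad.zeros();
      double bl = 0;
      for (int q = start; q < stop; q++) {
        int i = idx[q];
        double yh = forward_example(c, lay, P, pe, Xtr.row(i), cc, true, &rng);
        double e = yh - ytr(i);
        bl += std::abs(e) / bn;
        double dy = (e > 0 ? 1.0 : (e < 0 ? -1.0 : 0.0)) / bn;
        backward_example(c, lay, P, G, cc, dy, true);
      }
      tstep++;
      double bc1 = 1.0 - std::pow(b1, (double)tstep);
      double bc2 = 1.0 - std::pow(b2, (double)tstep);
      m = b1 * m + (1 - b1) * grad;
      v = b2 * v + (1 - b2) * square(grad);
      th -= lr * (m / bc1) / (sqrt(v / bc2) + aeps);
      ep_loss += bl;
      nb++;
      Rcpp::checkUserInterrupt();
    }
    double val_loss = eval_mae(Xval, yval, P);
    h_train.push_back(ep_loss / nb);
    h_val.push_back(val_loss);
    h_lr.push_back(lr);
    if (val_loss < best_val) {
      best_val = val_loss;
      best_th = th;
      best_epoch = ep + 1;
      lr_wait = 0;
      es_wait = 0;
    } else {
      lr_wait++;
      es_wait++;
      if (lr_wait >= lr_patience) {
        lr = std::max(lr_floor, lr * lr_factor);
        lr_wait = 0;
      }
      if (es_wait >= es_patience) break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::NumericVector(best_th.begin(), best_th.end()),
      Rcpp::Named("train_loss") = h_train, Rcpp::Named("val_loss") = h_val,
      Rcpp::Named("lr") = h_lr, Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val") = best_val);
}
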
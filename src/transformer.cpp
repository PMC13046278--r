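// Transformer encoder for fixed-length vital-sign windows.
//
// Forward/backward pass written against flat parameter vectors so the R side
// can drive AdamW and finite-difference gradient checks. Single precision:
// the matrices are small and the optimizer state is kept in double on the R
// side.
//
// Layouts: the R input array dim c(B, T, F) flattens column-major to rows
// r = b + B*t ("b-fast"), which the Conv1D stage uses (a time shift is then
// a contiguous block move). The encoder stack uses rows r = t + T*b
// ("t-fast") so each sample's T x d block is contiguous and attention works
// on submatrix views without gather copies.
//
// Architecture: Conv1D (same padding) -> sinusoidal positional encoding ->
// n_layers pre-norm encoder blocks (multi-head self-attention, position-wise
// feed-forward, layer normalization, residual dropout) -> final layer norm ->
// global average pooling over time -> concat static covariates -> linear
// head. The sigmoid lives in R together with the composite loss.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::stop;

static const float LN_EPS = 1e-5f;

struct TfConfig {
  int T, F, Fs, d, H, L, dff, kernel;
  int dh() const { return d / H; }
};

static TfConfig parse_cfg(const List& cfg) {
  TfConfig c;
  c.T = Rcpp::as<int>(cfg["seq_len"]);
  c.F = Rcpp::as<int>(cfg["f_dyn"]);
  c.Fs = Rcpp::as<int>(cfg["f_static"]);
  c.d = Rcpp::as<int>(cfg["d_model"]);
  c.H = Rcpp::as<int>(cfg["n_heads"]);
  c.L = Rcpp::as<int>(cfg["n_layers"]);
  c.dff = Rcpp::as<int>(cfg["d_ff"]);
  c.kernel = Rcpp::as<int>(cfg["conv_kernel"]);
  if (c.d % c.H != 0) stop("d_model must be divisible by n_heads");
  if (c.kernel % 2 == 0) stop("conv_kernel must be odd");
  return c;
}

// --- flat parameter layout -------------------------------------------------

struct LayerIdx {
  size_t ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv, Wo, bo;
  size_t ln2_g, ln2_b, W1, b1, W2, b2;
};

struct ParamIdx {
  size_t conv_W, conv_b;
  std::vector<LayerIdx> layer;
  size_t lnf_g, lnf_b, head_w, head_b;
  size_t total;
};

static ParamIdx make_idx(const TfConfig& c) {
  ParamIdx ix; size_t o = 0;
  ix.conv_W = o; o += (size_t)c.kernel * c.F * c.d;
  ix.conv_b = o; o += c.d;
  for (int l = 0; l < c.L; ++l) {
    LayerIdx li;
    li.ln1_g = o; o += c.d; li.ln1_b = o; o += c.d;
    li.Wq = o; o += (size_t)c.d * c.d; li.bq = o; o += c.d;
    li.Wk = o; o += (size_t)c.d * c.d; li.bk = o; o += c.d;
    li.Wv = o; o += (size_t)c.d * c.d; li.bv = o; o += c.d;
    li.Wo = o; o += (size_t)c.d * c.d; li.bo = o; o += c.d;
    li.ln2_g = o; o += c.d; li.ln2_b = o; o += c.d;
    li.W1 = o; o += (size_t)c.d * c.dff; li.b1 = o; o += c.dff;
    li.W2 = o; o += (size_t)c.dff * c.d; li.b2 = o; o += c.d;
    ix.layer.push_back(li);
  }
  ix.lnf_g = o; o += c.d; ix.lnf_b = o; o += c.d;
  ix.head_w = o; o += c.d + c.Fs;
  ix.head_b = o; o += 1;
  ix.total = o;
  return ix;
}

// [[Rcpp::export]]
int tf_nparams(List cfg) {
  return (int)make_idx(parse_cfg(cfg)).total;
}

// read-only views into the flat vector
static fmat P(const fvec& p, size_t off, int r, int cc) {
  return fmat(const_cast<float*>(p.memptr()) + off, r, cc, false, true);
}
static frowvec Pr(const fvec& p, size_t off, int n) {
  return frowvec(const_cast<float*>(p.memptr()) + off, n, false, true);
}

// --- tiny deterministic RNG for dropout masks ------------------------------

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  inline uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  inline float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
};

static fmat dropout_mask(size_t n, int m, float p, XorShift& rng) {
  fmat mask(n, m);
  float scale = 1.0f / (1.0f - p);
  float* ptr = mask.memptr();
  size_t tot = n * (size_t)m;
  for (size_t i = 0; i < tot; ++i) ptr[i] = rng.unif() < p ? 0.0f : scale;
  return mask;
}

// --- layer norm ------------------------------------------------------------

struct LnCache { fmat xhat; fvec istd; };

static fmat layernorm_fwd(const fmat& x, const frowvec& g, const frowvec& b,
                          LnCache& cache) {
  fvec mu = mean(x, 1);
  fmat cent = x.each_col() - mu;
  fvec v = mean(square(cent), 1);
  cache.istd = 1.0f / sqrt(v + LN_EPS);
  cache.xhat = cent.each_col() % cache.istd;
  fmat y = cache.xhat;
  y.each_row() %= g;
  y.each_row() += b;
  return y;
}

static fmat layernorm_bwd(const fmat& dy, const frowvec& g, const LnCache& cache,
                          frowvec& dg, frowvec& db) {
  dg = sum(dy % cache.xhat, 0);
  db = sum(dy, 0);
  fmat dxhat = dy.each_row() % g;
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % cache.xhat, 1);
  fmat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() %= cache.istd;
  return dx;
}

// --- caches ----------------------------------------------------------------

struct LayerCache {
  LnCache ln1;
  fmat QKV;           // N x 3d (post projection): [Q | K | V]
  fmat probs;         // (T*T) x (B*H) softmax probabilities, col = b*H+h
  fmat AO;            // concatenated attention output, pre-Wo
  fmat mask_attn;     // dropout masks (empty when dropout == 0)
  LnCache ln2;
  fmat H1;            // post-ReLU
  fmat mask_ff;
};

struct TfCache {
  TfConfig c;
  ParamIdx ix;
  fvec params;
  int B;
  bool spent = false; // backward releases the buffers
  fmat X0;            // conv input, b-fast
  fmat S;             // static (B x Fs)
  std::vector<LayerCache> layer;
  LnCache lnf;
  fmat pooled;        // B x d
  float inv_T;
};

// permute between b-fast (r = b + B*t) and t-fast (r = t + T*b) row layouts
static fmat bfast_to_tfast(const fmat& M, int B, int T) {
  fmat out(M.n_rows, M.n_cols);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      out.row(t + (size_t)T * b) = M.row(b + (size_t)B * t);
  return out;
}
static fmat tfast_to_bfast(const fmat& M, int B, int T) {
  fmat out(M.n_rows, M.n_cols);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      out.row(b + (size_t)B * t) = M.row(t + (size_t)T * b);
  return out;
}

// assemble the fused QKV weight (d x 3d) / bias (3d) from the flat params
static fmat fused_qkv_W(const fvec& p, const TfConfig& c, const LayerIdx& li) {
  fmat W(c.d, 3 * c.d);
  W.cols(0, c.d - 1) = P(p, li.Wq, c.d, c.d);
  W.cols(c.d, 2 * c.d - 1) = P(p, li.Wk, c.d, c.d);
  W.cols(2 * c.d, 3 * c.d - 1) = P(p, li.Wv, c.d, c.d);
  return W;
}
static frowvec fused_qkv_b(const fvec& p, const TfConfig& c, const LayerIdx& li) {
  frowvec b(3 * c.d);
  b.subvec(0, c.d - 1) = Pr(p, li.bq, c.d);
  b.subvec(c.d, 2 * c.d - 1) = Pr(p, li.bk, c.d);
  b.subvec(2 * c.d, 3 * c.d - 1) = Pr(p, li.bv, c.d);
  return b;
}

// [[Rcpp::export]]
List tf_forward(NumericVector params, List cfg, NumericVector X,
                NumericMatrix S, double dropout, int seed,
                bool keep_cache = true) {
  TfConfig c = parse_cfg(cfg);
  ParamIdx ix = make_idx(c);
  if ((size_t)params.size() != ix.total) stop("parameter vector has wrong length");
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 3 || dims[1] != c.T || dims[2] != c.F)
    stop("X must be an array [batch, seq_len, f_dyn]");
  int B = dims[0];
  size_t N = (size_t)B * c.T;
  int dh = c.dh();
  float scl = 1.0f / std::sqrt((float)dh);
  float dp = (float)dropout;

  fvec pv = conv_to<fvec>::from(Rcpp::as<arma::vec>(params));
  const fvec& p = pv;

  fmat X0(N, c.F);
  {
    const double* xp = X.begin();
    float* x0 = X0.memptr();
    for (size_t i = 0; i < N * (size_t)c.F; ++i) x0[i] = (float)xp[i];
  }
  fmat Sm(B, c.Fs);
  for (int j = 0; j < c.Fs; ++j)
    for (int b = 0; b < B; ++b) Sm(b, j) = (float)S(b, j);

  XorShift rng(((uint64_t)(uint32_t)seed << 17) ^ 0xD1B54A32D192ED03ULL);

  // Conv1D over time, same padding (b-fast: shift = block move)
  int pad = (c.kernel - 1) / 2;
  fmat xb(N, c.d, fill::zeros);
  for (int j = 0; j < c.kernel; ++j) {
    int off = j - pad;
    fmat Wj = P(p, ix.conv_W + (size_t)j * c.F * c.d, c.F, c.d);
    for (int t = 0; t < c.T; ++t) {
      int ts = t + off;
      if (ts < 0 || ts >= c.T) continue;
      xb.rows((size_t)t * B, (size_t)t * B + B - 1) +=
        X0.rows((size_t)ts * B, (size_t)ts * B + B - 1) * Wj;
    }
  }
  xb.each_row() += Pr(p, ix.conv_b, c.d);

  // sinusoidal positional encoding (still b-fast: per-t row blocks)
  for (int t = 0; t < c.T; ++t) {
    frowvec pe(c.d);
    for (int i = 0; i < c.d; i += 2) {
      double ang = t / std::pow(10000.0, (double)i / c.d);
      pe(i) = (float)std::sin(ang);
      if (i + 1 < c.d) pe(i + 1) = (float)std::cos(ang);
    }
    xb.rows((size_t)t * B, (size_t)t * B + B - 1).each_row() += pe;
  }

  fmat x = bfast_to_tfast(xb, B, c.T);
  xb.reset();

  TfCache* cc = nullptr;
  if (keep_cache) {
    cc = new TfCache();
    cc->c = c; cc->ix = ix; cc->B = B; cc->inv_T = 1.0f / c.T;
    cc->params = p;
    cc->X0 = std::move(X0);
    cc->S = Sm;
    cc->layer.resize(c.L);
  }

  LnCache ln_tmp;
  for (int l = 0; l < c.L; ++l) {
    const LayerIdx& li = ix.layer[l];
    LayerCache* lc = keep_cache ? &cc->layer[l] : nullptr;
    LnCache& ln1 = lc ? lc->ln1 : ln_tmp;
    fmat xn1 = layernorm_fwd(x, Pr(p, li.ln1_g, c.d), Pr(p, li.ln1_b, c.d), ln1);
    fmat QKV = xn1 * fused_qkv_W(p, c, li);
    QKV.each_row() += fused_qkv_b(p, c, li);

    fmat AO(N, c.d);
    fmat probs;
    if (lc) probs.set_size((size_t)c.T * c.T, (size_t)B * c.H);
    for (int b = 0; b < B; ++b) {
      size_t r0 = (size_t)b * c.T, r1 = r0 + c.T - 1;
      for (int h = 0; h < c.H; ++h) {
        fmat Sc = QKV.submat(r0, (size_t)h * dh, r1, (size_t)h * dh + dh - 1) *
                  QKV.submat(r0, (size_t)c.d + h * dh, r1,
                             (size_t)c.d + h * dh + dh - 1).t() * scl;
        for (int i = 0; i < c.T; ++i) {
          frowvec r = Sc.row(i);
          r -= r.max();
          r = exp(r);
          Sc.row(i) = r / accu(r);
        }
        if (lc) probs.col((size_t)b * c.H + h) = vectorise(Sc);
        AO.submat(r0, (size_t)h * dh, r1, (size_t)h * dh + dh - 1) =
          Sc * QKV.submat(r0, (size_t)2 * c.d + h * dh, r1,
                          (size_t)2 * c.d + h * dh + dh - 1);
      }
    }
    if (lc) { lc->QKV = std::move(QKV); lc->probs = std::move(probs); }

    fmat proj = AO * P(p, li.Wo, c.d, c.d);
    proj.each_row() += Pr(p, li.bo, c.d);
    if (lc) lc->AO = std::move(AO);
    if (dp > 0) {
      fmat mask = dropout_mask(N, c.d, dp, rng);
      proj %= mask;
      if (lc) lc->mask_attn = std::move(mask);
    }
    x += proj;

    LnCache& ln2 = lc ? lc->ln2 : ln_tmp;
    fmat xn2 = layernorm_fwd(x, Pr(p, li.ln2_g, c.d), Pr(p, li.ln2_b, c.d), ln2);
    fmat H1 = xn2 * P(p, li.W1, c.d, c.dff);
    H1.each_row() += Pr(p, li.b1, c.dff);
    H1.transform([](float v) { return v > 0 ? v : 0.0f; });
    fmat ff = H1 * P(p, li.W2, c.dff, c.d);
    ff.each_row() += Pr(p, li.b2, c.d);
    if (lc) lc->H1 = std::move(H1);
    if (dp > 0) {
      fmat mask = dropout_mask(N, c.d, dp, rng);
      ff %= mask;
      if (lc) lc->mask_ff = std::move(mask);
    }
    x += ff;
  }

  LnCache& lnf = keep_cache ? cc->lnf : ln_tmp;
  fmat xnf = layernorm_fwd(x, Pr(p, ix.lnf_g, c.d), Pr(p, ix.lnf_b, c.d), lnf);

  fmat pooled(B, c.d);
  for (int b = 0; b < B; ++b) {
    pooled.row(b) = mean(xnf.rows((size_t)b * c.T, (size_t)b * c.T + c.T - 1), 0);
  }
  if (keep_cache) cc->pooled = pooled;

  fvec hw = p.subvec(ix.head_w, ix.head_w + c.d + c.Fs - 1);
  fvec logits = pooled * hw.subvec(0, c.d - 1) +
                Sm * hw.subvec(c.d, c.d + c.Fs - 1) + p(ix.head_b);

  NumericVector out(B);
  for (int b = 0; b < B; ++b) out[b] = (double)logits(b);

  List res = List::create(Rcpp::Named("logits") = out);
  if (keep_cache) {
    Rcpp::XPtr<TfCache> ptr(cc, true);
    res["cache"] = ptr;
  }
  return res;
}

// [[Rcpp::export]]
NumericVector tf_backward(SEXP cache, NumericVector dlogits) {
  Rcpp::XPtr<TfCache> ptr(cache);
  TfCache* cc = ptr.get();
  if (cc->spent) stop("cache already consumed by a previous tf_backward call");
  const TfConfig& c = cc->c;
  const ParamIdx& ix = cc->ix;
  const fvec& p = cc->params;
  int B = cc->B, dh = c.dh();
  size_t N = (size_t)B * c.T;
  if (dlogits.size() != B) stop("dlogits has wrong length");
  float scl = 1.0f / std::sqrt((float)dh);

  fvec grad(ix.total, fill::zeros);
  fvec dl(B);
  for (int b = 0; b < B; ++b) dl(b) = (float)dlogits[b];

  // head
  fvec hw = p.subvec(ix.head_w, ix.head_w + c.d + c.Fs - 1);
  grad.subvec(ix.head_w, ix.head_w + c.d - 1) = cc->pooled.t() * dl;
  if (c.Fs > 0)
    grad.subvec(ix.head_w + c.d, ix.head_w + c.d + c.Fs - 1) = cc->S.t() * dl;
  grad(ix.head_b) = accu(dl);

  // pool -> final LN output (t-fast: each sample's block gets dpool/T)
  fmat dxnf(N, c.d);
  fmat dpool = dl * hw.subvec(0, c.d - 1).t() * cc->inv_T;   // B x d
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < c.T; ++t) dxnf.row((size_t)b * c.T + t) = dpool.row(b);
  }

  frowvec dg, db;
  fmat dx = layernorm_bwd(dxnf, Pr(p, ix.lnf_g, c.d), cc->lnf, dg, db);
  dxnf.reset();
  grad.subvec(ix.lnf_g, ix.lnf_g + c.d - 1) = dg.t();
  grad.subvec(ix.lnf_b, ix.lnf_b + c.d - 1) = db.t();

  for (int l = c.L - 1; l >= 0; --l) {
    LayerCache& lc = cc->layer[l];
    const LayerIdx& li = ix.layer[l];

    // FF branch
    fmat dff = dx;
    if (lc.mask_ff.n_elem) dff %= lc.mask_ff;
    fmat xn2 = lc.ln2.xhat;
    xn2.each_row() %= Pr(p, li.ln2_g, c.d);
    xn2.each_row() += Pr(p, li.ln2_b, c.d);
    grad.subvec(li.b2, li.b2 + c.d - 1) += sum(dff, 0).t();
    {
      fmat dW2 = lc.H1.t() * dff;
      grad.subvec(li.W2, li.W2 + (size_t)c.dff * c.d - 1) += vectorise(dW2);
    }
    fmat dH1 = dff * P(p, li.W2, c.dff, c.d).t();
    dff.reset();
    {
      float* dp_ = dH1.memptr();
      const float* hp = lc.H1.memptr();
      size_t ne = dH1.n_elem;
      for (size_t i = 0; i < ne; ++i) if (hp[i] <= 0) dp_[i] = 0.0f;
    }
    grad.subvec(li.b1, li.b1 + c.dff - 1) += sum(dH1, 0).t();
    {
      fmat dW1 = xn2.t() * dH1;
      grad.subvec(li.W1, li.W1 + (size_t)c.d * c.dff - 1) += vectorise(dW1);
    }
    fmat dxn2 = dH1 * P(p, li.W1, c.d, c.dff).t();
    dH1.reset(); lc.H1.reset(); xn2.reset();
    fmat dx_mid = layernorm_bwd(dxn2, Pr(p, li.ln2_g, c.d), lc.ln2, dg, db);
    dxn2.reset();
    grad.subvec(li.ln2_g, li.ln2_g + c.d - 1) += dg.t();
    grad.subvec(li.ln2_b, li.ln2_b + c.d - 1) += db.t();
    dx_mid += dx;   // residual
    dx.reset();

    // attention branch
    fmat dproj = dx_mid;
    if (lc.mask_attn.n_elem) dproj %= lc.mask_attn;
    grad.subvec(li.bo, li.bo + c.d - 1) += sum(dproj, 0).t();
    {
      fmat dWo = lc.AO.t() * dproj;
      grad.subvec(li.Wo, li.Wo + (size_t)c.d * c.d - 1) += vectorise(dWo);
    }
    fmat dAO = dproj * P(p, li.Wo, c.d, c.d).t();
    dproj.reset(); lc.AO.reset();

    fmat dQKV(N, 3 * c.d, fill::none);
    const fmat& QKV = lc.QKV;
    for (int b = 0; b < B; ++b) {
      size_t r0 = (size_t)b * c.T, r1 = r0 + c.T - 1;
      for (int h = 0; h < c.H; ++h) {
        size_t cq = (size_t)h * dh, ck = (size_t)c.d + h * dh,
               cv = (size_t)2 * c.d + h * dh;
        fmat Pm(lc.probs.colptr((size_t)b * c.H + h), c.T, c.T, false, true);
        fmat dOm = dAO.submat(r0, cq, r1, cq + dh - 1);
        fmat dP = dOm * QKV.submat(r0, cv, r1, cv + dh - 1).t();
        dQKV.submat(r0, cv, r1, cv + dh - 1) = Pm.t() * dOm;
        fvec rs = sum(dP % Pm, 1);
        fmat dS = Pm % (dP.each_col() - rs);
        dQKV.submat(r0, cq, r1, cq + dh - 1) =
          dS * QKV.submat(r0, ck, r1, ck + dh - 1) * scl;
        dQKV.submat(r0, ck, r1, ck + dh - 1) =
          dS.t() * QKV.submat(r0, cq, r1, cq + dh - 1) * scl;
      }
    }
    dAO.reset(); lc.probs.reset(); lc.QKV.reset();

    fmat xn1 = lc.ln1.xhat;
    xn1.each_row() %= Pr(p, li.ln1_g, c.d);
    xn1.each_row() += Pr(p, li.ln1_b, c.d);

    frowvec dbqkv = sum(dQKV, 0);
    grad.subvec(li.bq, li.bq + c.d - 1) += dbqkv.subvec(0, c.d - 1).t();
    grad.subvec(li.bk, li.bk + c.d - 1) += dbqkv.subvec(c.d, 2 * c.d - 1).t();
    grad.subvec(li.bv, li.bv + c.d - 1) += dbqkv.subvec(2 * c.d, 3 * c.d - 1).t();
    {
      fmat dWqkv = xn1.t() * dQKV;   // d x 3d
      grad.subvec(li.Wq, li.Wq + (size_t)c.d * c.d - 1) +=
        vectorise(dWqkv.cols(0, c.d - 1));
      grad.subvec(li.Wk, li.Wk + (size_t)c.d * c.d - 1) +=
        vectorise(dWqkv.cols(c.d, 2 * c.d - 1));
      grad.subvec(li.Wv, li.Wv + (size_t)c.d * c.d - 1) +=
        vectorise(dWqkv.cols(2 * c.d, 3 * c.d - 1));
    }
    fmat dxn1 = dQKV * fused_qkv_W(p, c, li).t();
    dQKV.reset(); xn1.reset();
    fmat dx_in = layernorm_bwd(dxn1, Pr(p, li.ln1_g, c.d), lc.ln1, dg, db);
    dxn1.reset();
    grad.subvec(li.ln1_g, li.ln1_g + c.d - 1) += dg.t();
    grad.subvec(li.ln1_b, li.ln1_b + c.d - 1) += db.t();
    dx = dx_mid + dx_in;
    lc = LayerCache();   // release this layer's buffers
  }

  // conv backward (b-fast layout)
  fmat dxb = tfast_to_bfast(dx, B, c.T);
  dx.reset();
  int pad = (c.kernel - 1) / 2;
  grad.subvec(ix.conv_b, ix.conv_b + c.d - 1) += sum(dxb, 0).t();
  for (int j = 0; j < c.kernel; ++j) {
    int off = j - pad;
    fmat dWj(c.F, c.d, fill::zeros);
    for (int t = 0; t < c.T; ++t) {
      int ts = t + off;
      if (ts < 0 || ts >= c.T) continue;
      dWj += cc->X0.rows((size_t)ts * B, (size_t)ts * B + B - 1).t() *
             dxb.rows((size_t)t * B, (size_t)t * B + B - 1);
    }
    grad.subvec(ix.conv_W + (size_t)j * c.F * c.d,
                ix.conv_W + (size_t)(j + 1) * c.F * c.d - 1) += vectorise(dWj);
  }

  // release the remaining buffers now rather than at GC time
  cc->spent = true;
  cc->layer.clear();
  cc->layer.shrink_to_fit();
  cc->X0.reset(); cc->S.reset(); cc->pooled.reset();
  cc->lnf.xhat.reset(); cc->lnf.istd.reset();
  cc->params.reset();

  NumericVector out(ix.total);
  for (size_t i = 0; i < ix.total; ++i) out[i] = (double)grad(i);
  return out;
}
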
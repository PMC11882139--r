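// Native CNN-LSTM engine for window classification.
//
// Activations are stored sample-major: a matrix with B*T rows (row = b*T + t)
// and C columns. Convolutions are im2col + GEMM; the LSTM runs batched per
// timestep. All randomness (init, shuffling, dropout) comes from one
// std::mt19937 so a fixed seed reproduces training bit-for-bit on one thread.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// Single precision internally (as deep-learning frameworks use); parameters
// cross the R boundary as doubles. Every float value is exactly
// representable as a double, so round trips are lossless and deterministic.
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef arma::frowvec rowvec;
using arma::uword;

static mat to_f(const Rcpp::NumericMatrix& m) {
  return arma::conv_to<mat>::from(Rcpp::as<arma::mat>(m));
}
static vec to_fv(const Rcpp::NumericVector& v) {
  return arma::conv_to<vec>::from(Rcpp::as<arma::vec>(v));
}
static SEXP from_f(const mat& m) {
  return Rcpp::wrap(arma::conv_to<arma::mat>::from(m));
}

static const double BN_EPS = 1e-3;     // batch-norm epsilon
static const double BN_MOMENTUM = 0.99;
static const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-7;
static const double BCE_CLAMP = 1e-7;

// ---------------------------------------------------------------------------
// Architecture description passed from R

struct NetSpec {
  int window_len;
  std::vector<int> filters, kernels, pools;  // pools[i] == 0 -> no pooling
  double alpha;            // leaky ReLU slope
  int lstm_units;
  double lstm_dropout;
  int dense_units;
  double dense_dropout;
  int n_blocks;
  std::vector<int> seq_len;   // timesteps entering each conv block
  int lstm_T, lstm_C;         // sequence length / channels entering the LSTM
};

static NetSpec parse_spec(const List& sp) {
  NetSpec s;
  s.window_len   = as<int>(sp["window_len"]);
  s.filters      = as<std::vector<int>>(sp["filters"]);
  s.kernels      = as<std::vector<int>>(sp["kernels"]);
  s.pools        = as<std::vector<int>>(sp["pools"]);
  s.alpha        = as<double>(sp["leaky_alpha"]);
  s.lstm_units   = as<int>(sp["lstm_units"]);
  s.lstm_dropout = as<double>(sp["lstm_dropout"]);
  s.dense_units  = as<int>(sp["dense_units"]);
  s.dense_dropout= as<double>(sp["dense_dropout"]);
  s.n_blocks = (int)s.filters.size();
  int T = s.window_len;
  for (int i = 0; i < s.n_blocks; ++i) {
    s.seq_len.push_back(T);
    if (s.kernels[i] % 2 == 0) stop("conv kernel sizes must be odd ('same' padding)");
    if (s.pools[i] > 0) {
      if (T % s.pools[i] != 0)
        stop("window length not divisible by pooling chain at block %d", i + 1);
      T /= s.pools[i];
    }
  }
  s.lstm_T = T;
  s.lstm_C = s.filters[s.n_blocks - 1];
  return s;
}

// ---------------------------------------------------------------------------
// Parameter container: ordered vector of named tensors

struct Params {
  std::vector<std::string> names;
  std::vector<mat> tensors;
  std::vector<bool> conv_part;   // belongs to a convolutional block (incl. BN)
  std::vector<bool> trainable;   // false for BN moving statistics

  int idx(const std::string& nm) const {
    for (size_t i = 0; i < names.size(); ++i) if (names[i] == nm) return (int)i;
    stop("missing parameter tensor '%s'", nm.c_str());
    return -1;
  }
  mat& operator[](const std::string& nm) { return tensors[idx(nm)]; }
  const mat& get(const std::string& nm) const { return tensors[idx(nm)]; }
};

static void add_tensor(Params& p, const std::string& nm, mat t,
                       bool conv, bool train) {
  p.names.push_back(nm); p.tensors.push_back(std::move(t));
  p.conv_part.push_back(conv); p.trainable.push_back(train);
}

// Declares every tensor (zero-filled) in a fixed order.
static Params make_params(const NetSpec& s) {
  Params p;
  int cin = 1;
  for (int i = 0; i < s.n_blocks; ++i) {
    std::string b = "conv" + std::to_string(i + 1);
    int k = s.kernels[i], cout = s.filters[i];
    add_tensor(p, b + "_W", mat(k * cin, cout, arma::fill::zeros), true, true);
    add_tensor(p, b + "_b", mat(1, cout, arma::fill::zeros), true, true);
    std::string bn = "bn" + std::to_string(i + 1);
    add_tensor(p, bn + "_gamma", mat(1, cout, arma::fill::ones),  true, true);
    add_tensor(p, bn + "_beta",  mat(1, cout, arma::fill::zeros), true, true);
    add_tensor(p, bn + "_rmean", mat(1, cout, arma::fill::zeros), true, false);
    add_tensor(p, bn + "_rvar",  mat(1, cout, arma::fill::ones),  true, false);
    cin = cout;
  }
  int U = s.lstm_units, C = s.lstm_C;
  for (std::string d : {"fw", "bw"}) {
    add_tensor(p, "lstm_" + d + "_Wx", mat(C, 4 * U, arma::fill::zeros), false, true);
    add_tensor(p, "lstm_" + d + "_Wh", mat(U, 4 * U, arma::fill::zeros), false, true);
    add_tensor(p, "lstm_" + d + "_b",  mat(1, 4 * U, arma::fill::zeros), false, true);
  }
  add_tensor(p, "dense1_W", mat(U, s.dense_units, arma::fill::zeros), false, true);
  add_tensor(p, "dense1_b", mat(1, s.dense_units, arma::fill::zeros), false, true);
  add_tensor(p, "dense2_W", mat(s.dense_units, 1, arma::fill::zeros), false, true);
  add_tensor(p, "dense2_b", mat(1, 1, arma::fill::zeros), false, true);
  return p;
}

static void glorot_fill(mat& W, double fan_in, double fan_out, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = u(rng);
}

static Params init_params(const NetSpec& s, unsigned int seed) {
  Params p = make_params(s);
  std::mt19937 rng(seed);
  int cin = 1;
  for (int i = 0; i < s.n_blocks; ++i) {
    mat& W = p["conv" + std::to_string(i + 1) + "_W"];
    glorot_fill(W, (double)s.kernels[i] * cin, (double)s.kernels[i] * s.filters[i], rng);
    cin = s.filters[i];
  }
  int U = s.lstm_units;
  for (std::string d : {"fw", "bw"}) {
    mat& Wx = p["lstm_" + d + "_Wx"]; glorot_fill(Wx, Wx.n_rows, Wx.n_cols, rng);
    mat& Wh = p["lstm_" + d + "_Wh"]; glorot_fill(Wh, Wh.n_rows, Wh.n_cols, rng);
    mat& b  = p["lstm_" + d + "_b"];
    b.cols(U, 2 * U - 1).ones();             // unit forget-gate bias
  }
  mat& D1 = p["dense1_W"]; glorot_fill(D1, D1.n_rows, D1.n_cols, rng);
  mat& D2 = p["dense2_W"]; glorot_fill(D2, D2.n_rows, D2.n_cols, rng);
  return p;
}

static Params params_from_list(const List& lst, const NetSpec& s) {
  Params p = make_params(s);
  for (size_t i = 0; i < p.names.size(); ++i) {
    if (!lst.containsElementNamed(p.names[i].c_str()))
      stop("parameter list missing tensor '%s'", p.names[i].c_str());
    mat t = to_f(lst[p.names[i]]);
    if (t.n_rows != p.tensors[i].n_rows || t.n_cols != p.tensors[i].n_cols)
      stop("tensor '%s' has shape %dx%d, expected %dx%d", p.names[i].c_str(),
           (int)t.n_rows, (int)t.n_cols,
           (int)p.tensors[i].n_rows, (int)p.tensors[i].n_cols);
    p.tensors[i] = t;
  }
  return p;
}

static List params_to_list(const Params& p) {
  List out(p.names.size());
  CharacterVector nms(p.names.size());
  for (size_t i = 0; i < p.names.size(); ++i) {
    nms[i] = p.names[i];
    out[i] = from_f(p.tensors[i]);
  }
  out.names() = nms;
  return out;
}

// ---------------------------------------------------------------------------
// Layer primitives

// input A: (B*T) x Cin -> (B*T) x (k*Cin), zero padded ('same')
static mat im2col(const mat& A, int B, int T, int k) {
  int C = A.n_cols, pad = (k - 1) / 2;
  mat M(A.n_rows, (uword)k * C, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    int off = j - pad;
    int t0 = std::max(0, -off), t1 = std::min(T, T - off);  // valid t range
    if (t0 >= t1) continue;
    for (int b = 0; b < B; ++b) {
      M.submat((uword)(b * T + t0), (uword)(j * C),
               (uword)(b * T + t1 - 1), (uword)((j + 1) * C - 1)) =
        A.rows((uword)(b * T + t0 + off), (uword)(b * T + t1 - 1 + off));
    }
  }
  return M;
}

static mat col2im(const mat& dM, int B, int T, int k, int C) {
  int pad = (k - 1) / 2;
  mat dA((uword)B * T, (uword)C, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    int off = j - pad;
    int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    if (t0 >= t1) continue;
    for (int b = 0; b < B; ++b) {
      dA.rows((uword)(b * T + t0 + off), (uword)(b * T + t1 - 1 + off)) +=
        dM.submat((uword)(b * T + t0), (uword)(j * C),
                  (uword)(b * T + t1 - 1), (uword)((j + 1) * C - 1));
    }
  }
  return dA;
}

static mat avgpool(const mat& A, int B, int T, int s) {
  int C = A.n_cols, T2 = T / s;
  mat out((uword)B * T2, (uword)C);
  float inv = 1.0f / (float)s;
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    for (int b = 0; b < B; ++b) {
      const float* sb = src + (uword)b * T;
      float* db = dst + (uword)b * T2;
      for (int t2 = 0; t2 < T2; ++t2) {
        float acc = 0;
        for (int j = 0; j < s; ++j) acc += sb[t2 * s + j];
        db[t2] = acc * inv;
      }
    }
  }
  return out;
}

static mat avgpool_back(const mat& dOut, int B, int T, int s) {
  int C = dOut.n_cols, T2 = T / s;
  mat dA((uword)B * T, (uword)C);
  float inv = 1.0f / (float)s;
  for (int c = 0; c < C; ++c) {
    const float* src = dOut.colptr(c);
    float* dst = dA.colptr(c);
    for (int b = 0; b < B; ++b) {
      const float* sb = src + (uword)b * T2;
      float* db = dst + (uword)b * T;
      for (int t2 = 0; t2 < T2; ++t2)
        for (int j = 0; j < s; ++j) db[t2 * s + j] = sb[t2] * inv;
    }
  }
  return dA;
}

static inline mat sigmoid_m(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// ---------------------------------------------------------------------------
// Forward/backward caches

struct BlockCache {
  mat X_in;      // input to conv (B*T x Cin)
  mat xhat;      // normalized pre-scale activations
  rowvec invstd; // training-mode 1/sqrt(var+eps) (empty in inference)
  mat act_in;    // BN output = leaky-ReLU input
  int T;         // timesteps at conv input
};

struct LstmCache {
  std::vector<mat> i, f, g, o, c, tanh_c, h_prev, c_prev;  // per timestep
};

struct FwdCache {
  std::vector<BlockCache> blocks;
  mat lstm_in_tm;     // time-major (T_l*B x C_l) after input dropout
  mat lstm_drop_mask; // B x C_l (empty when not training)
  LstmCache fw, bw;
  mat h_merged;       // B x U
  mat d1_act_in;      // dense1 pre-activation
  mat d1_out;         // after activation + dropout
  mat d1_drop_mask;
  vec p;              // sigmoid outputs
};

// Accumulator for exact whole-set batch-norm statistics (re-estimated with
// frozen weights after every epoch, so inference-mode normalisation matches
// the trained weights instead of lagging them).
struct BnStats {
  std::vector<rowvec> sum, sumsq;
  std::vector<double> n;
  void init(const NetSpec& s) {
    sum.clear(); sumsq.clear(); n.clear();
    for (int i = 0; i < s.n_blocks; ++i) {
      sum.push_back(rowvec(s.filters[i], arma::fill::zeros));
      sumsq.push_back(rowvec(s.filters[i], arma::fill::zeros));
      n.push_back(0.0);
    }
  }
};

// One full forward pass over a batch X (B x window_len).
// training: batch-statistics BN + dropout; bn_update: update moving stats.
// freeze_conv: conv blocks always run in inference mode (frozen BN stats).
// bn_stats: when set, per-block pre-BN moments are accumulated and the pass
// stops after the conv stack (weights and moving stats untouched).
static vec forward(Params& P, const NetSpec& s, const mat& X, bool training,
                   bool freeze_conv, std::mt19937* rng, FwdCache* cache,
                   BnStats* bn_stats = nullptr) {
  int B = X.n_rows;
  // (B x T) -> sample-major (B*T x 1)
  mat A((uword)B * s.window_len, 1);
  for (int b = 0; b < B; ++b)
    A.submat((uword)b * s.window_len, 0, (uword)(b + 1) * s.window_len - 1, 0) =
      X.row(b).t();

  int T = s.window_len;
  for (int i = 0; i < s.n_blocks; ++i) {
    std::string cb = "conv" + std::to_string(i + 1), bn = "bn" + std::to_string(i + 1);
    bool cache_block = cache && !freeze_conv;   // conv grads not needed if frozen
    BlockCache bc; bc.T = T;
    if (cache_block) bc.X_in = A;
    mat M = im2col(A, B, T, s.kernels[i]);
    bool bn_batch_mode = (training || bn_stats) && !freeze_conv;
    mat Z;
    if (!bn_batch_mode) {
      // inference: fold conv bias + batch norm into the GEMM
      rowvec scl = P[bn + "_gamma"].row(0) /
        arma::sqrt(P[bn + "_rvar"].row(0) + (float)BN_EPS);
      mat Wf = P[cb + "_W"];
      Wf.each_row() %= scl;
      rowvec bf = (P[cb + "_b"].row(0) - P[bn + "_rmean"].row(0)) % scl +
        P[bn + "_beta"].row(0);
      Z = M * Wf;
      Z.each_row() += bf;
    } else {
      Z = M * P[cb + "_W"];
      Z.each_row() += P[cb + "_b"].row(0);
    }
    if (bn_batch_mode) {
      rowvec mu = arma::mean(Z, 0);
      mat Zc = Z; Zc.each_row() -= mu;
      rowvec var = arma::mean(arma::square(Zc), 0);   // biased
      rowvec invstd = 1.0 / arma::sqrt(var + BN_EPS);
      mat xhat = Zc; xhat.each_row() %= invstd;
      if (bn_stats) {
        double N = (double)Z.n_rows;
        bn_stats->sum[i] += mu * N;
        bn_stats->sumsq[i] += (var + arma::square(mu)) * N;
        bn_stats->n[i] += N;
      } else {
        P[bn + "_rmean"].row(0) = BN_MOMENTUM * P[bn + "_rmean"].row(0) + (1 - BN_MOMENTUM) * mu;
        P[bn + "_rvar"].row(0)  = BN_MOMENTUM * P[bn + "_rvar"].row(0)  + (1 - BN_MOMENTUM) * var;
      }
      Z = xhat;
      Z.each_row() %= P[bn + "_gamma"].row(0);
      Z.each_row() += P[bn + "_beta"].row(0);
      if (cache_block) { bc.xhat = std::move(xhat); bc.invstd = invstd; }
    }
    if (cache_block) bc.act_in = Z;
    // leaky ReLU
    A = Z;
    A.transform([&s](double v) { return v >= 0 ? v : s.alpha * v; });
    if (s.pools[i] > 0) {
      A = avgpool(A, B, T, s.pools[i]);
      T /= s.pools[i];
    }
    if (cache_block) cache->blocks.push_back(std::move(bc));
  }
  if (bn_stats) return vec();   // stats pass: conv stack only

  // LSTM input dropout: one mask per sample/feature, shared across timesteps
  int C = s.lstm_C, U = s.lstm_units, Tl = s.lstm_T;
  mat drop_mask;
  if (training && s.lstm_dropout > 0) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    drop_mask.set_size(B, C);
    double keep = 1.0 - s.lstm_dropout;
    for (uword jj = 0; jj < drop_mask.n_cols; ++jj)
      for (uword ii = 0; ii < drop_mask.n_rows; ++ii)
        drop_mask(ii, jj) = (u(*rng) < keep) ? 1.0 / keep : 0.0;
    for (int b = 0; b < B; ++b)
      A.rows((uword)b * Tl, (uword)(b + 1) * Tl - 1).each_row() %= drop_mask.row(b);
  }
  // reorganise sample-major (B*Tl x C) -> time-major (Tl*B x C) so each
  // timestep is a contiguous row block and the input projection is one GEMM
  mat Xt((uword)Tl * B, (uword)C);
  for (int cidx = 0; cidx < C; ++cidx) {
    const float* src = A.colptr(cidx);
    float* dst = Xt.colptr(cidx);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tl; ++t)
        dst[(uword)t * B + b] = src[(uword)b * Tl + t];
  }
  if (cache) { cache->lstm_in_tm = Xt; cache->lstm_drop_mask = drop_mask; }

  // bidirectional LSTM, sum merge of the last outputs
  mat h_merged(B, U, arma::fill::zeros);
  for (std::string d : {"fw", "bw"}) {
    const mat& Wx = P["lstm_" + d + "_Wx"];
    const mat& Wh = P["lstm_" + d + "_Wh"];
    const rowvec bvec = P["lstm_" + d + "_b"].row(0);
    LstmCache lc;
    mat Gx = Xt * Wx;            // all input projections at once
    mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
    for (int step = 0; step < Tl; ++step) {
      int t = (d == "fw") ? step : (Tl - 1 - step);
      mat Z = Gx.rows((uword)t * B, (uword)(t + 1) * B - 1) + h * Wh;
      Z.each_row() += bvec;
      mat gi = sigmoid_m(Z.cols(0, U - 1));
      mat gf = sigmoid_m(Z.cols(U, 2 * U - 1));
      mat gg = arma::tanh(Z.cols(2 * U, 3 * U - 1));
      mat go = sigmoid_m(Z.cols(3 * U, 4 * U - 1));
      if (cache) { lc.h_prev.push_back(h); lc.c_prev.push_back(c); }
      c = gf % c + gi % gg;
      mat tc = arma::tanh(c);
      h = go % tc;
      if (cache) {
        lc.i.push_back(gi); lc.f.push_back(gf); lc.g.push_back(gg); lc.o.push_back(go);
        lc.c.push_back(c);  lc.tanh_c.push_back(tc);
      }
    }
    h_merged += h;
    if (cache) { if (d == "fw") cache->fw = std::move(lc); else cache->bw = std::move(lc); }
  }
  if (cache) cache->h_merged = h_merged;

  // dense head
  mat Z1 = h_merged * P["dense1_W"];
  Z1.each_row() += P["dense1_b"].row(0);
  if (cache) cache->d1_act_in = Z1;
  mat A1 = Z1;
  A1.transform([&s](double v) { return v >= 0 ? v : s.alpha * v; });
  if (training && s.dense_dropout > 0) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    mat m1(A1.n_rows, A1.n_cols);
    double keep = 1.0 - s.dense_dropout;
    for (uword jj = 0; jj < m1.n_cols; ++jj)
      for (uword ii = 0; ii < m1.n_rows; ++ii)
        m1(ii, jj) = (u(*rng) < keep) ? 1.0 / keep : 0.0;
    A1 %= m1;
    if (cache) cache->d1_drop_mask = std::move(m1);
  }
  if (cache) cache->d1_out = A1;
  mat Z2 = A1 * P["dense2_W"];
  Z2.each_row() += P["dense2_b"].row(0);
  vec p = sigmoid_m(Z2).col(0);
  if (cache) cache->p = p;
  return p;
}

// Backward pass; fills grads (same layout as Params tensors).
static void backward(Params& P, const NetSpec& s, const FwdCache& cache,
                     const vec& y, std::vector<mat>& grads,
                     bool skip_conv = false) {
  int B = y.n_elem, U = s.lstm_units, C = s.lstm_C, Tl = s.lstm_T;
  for (size_t i = 0; i < P.tensors.size(); ++i)
    grads[i] = mat(P.tensors[i].n_rows, P.tensors[i].n_cols, arma::fill::zeros);

  // BCE + sigmoid
  mat dZ2(B, 1);
  dZ2.col(0) = (cache.p - y) / (double)B;

  grads[P.idx("dense2_W")] = cache.d1_out.t() * dZ2;
  grads[P.idx("dense2_b")] = arma::sum(dZ2, 0);
  mat dA1 = dZ2 * P["dense2_W"].t();
  if (cache.d1_drop_mask.n_elem > 0) dA1 %= cache.d1_drop_mask;
  mat dZ1 = dA1;
  for (uword jj = 0; jj < dZ1.n_cols; ++jj)
    for (uword ii = 0; ii < dZ1.n_rows; ++ii)
      if (cache.d1_act_in(ii, jj) < 0) dZ1(ii, jj) *= s.alpha;
  grads[P.idx("dense1_W")] = cache.h_merged.t() * dZ1;
  grads[P.idx("dense1_b")] = arma::sum(dZ1, 0);
  mat dh_final = dZ1 * P["dense1_W"].t();   // B x U, same grad for both directions

  mat dXt((uword)Tl * B, (uword)C, arma::fill::zeros);   // time-major
  for (std::string d : {"fw", "bw"}) {
    const LstmCache& lc = (d == "fw") ? cache.fw : cache.bw;
    const mat& Wx = P["lstm_" + d + "_Wx"];
    const mat& Wh = P["lstm_" + d + "_Wh"];
    mat dWh(Wh.n_rows, Wh.n_cols, arma::fill::zeros);
    mat dGx((uword)Tl * B, (uword)4 * U);   // per-timestep pre-gate grads
    mat dh = dh_final, dc(B, U, arma::fill::zeros);
    for (int step = Tl - 1; step >= 0; --step) {
      int t = (d == "fw") ? step : (Tl - 1 - step);
      const mat &gi = lc.i[step], &gf = lc.f[step], &gg = lc.g[step], &go = lc.o[step];
      const mat &tc = lc.tanh_c[step];
      mat dgo = dh % tc;
      dc += dh % go % (1.0 - arma::square(tc));
      mat dgi = dc % gg;
      mat dgf = dc % lc.c_prev[step];
      mat dgg = dc % gi;
      mat dc_prev = dc % gf;
      mat dZ(B, 4 * U);
      dZ.cols(0, U - 1)         = dgi % gi % (1.0 - gi);
      dZ.cols(U, 2 * U - 1)     = dgf % gf % (1.0 - gf);
      dZ.cols(2 * U, 3 * U - 1) = dgg % (1.0 - arma::square(gg));
      dZ.cols(3 * U, 4 * U - 1) = dgo % go % (1.0 - go);
      dWh += lc.h_prev[step].t() * dZ;
      dGx.rows((uword)t * B, (uword)(t + 1) * B - 1) = dZ;
      dh = dZ * Wh.t();
      dc = dc_prev;
    }
    grads[P.idx("lstm_" + d + "_Wx")] = cache.lstm_in_tm.t() * dGx;
    grads[P.idx("lstm_" + d + "_Wh")] = dWh;
    grads[P.idx("lstm_" + d + "_b")].row(0) = arma::sum(dGx, 0);
    dXt += dGx * Wx.t();
  }
  // back to sample-major and through the input dropout
  mat dLstmIn((uword)B * Tl, (uword)C);
  for (int cidx = 0; cidx < C; ++cidx) {
    const float* src = dXt.colptr(cidx);
    float* dst = dLstmIn.colptr(cidx);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tl; ++t)
        dst[(uword)b * Tl + t] = src[(uword)t * B + b];
  }
  if (cache.lstm_drop_mask.n_elem > 0)
    for (int b = 0; b < B; ++b)
      dLstmIn.rows((uword)b * Tl, (uword)(b + 1) * Tl - 1).each_row()
        %= cache.lstm_drop_mask.row(b);

  if (skip_conv) return;  // frozen feature extractor: no conv/BN gradients

  // conv blocks, last to first
  mat dA = dLstmIn;
  bool frozen = cache.blocks.empty() ||
                cache.blocks[0].invstd.n_elem == 0;  // inference-mode BN => frozen
  int T_after = Tl;
  for (int i = s.n_blocks - 1; i >= 0; --i) {
    const BlockCache& bc = cache.blocks[i];
    std::string cb = "conv" + std::to_string(i + 1), bn = "bn" + std::to_string(i + 1);
    int T = bc.T;
    if (s.pools[i] > 0) dA = avgpool_back(dA, B, T, s.pools[i]);
    // leaky ReLU
    for (uword jj = 0; jj < dA.n_cols; ++jj)
      for (uword ii = 0; ii < dA.n_rows; ++ii)
        if (bc.act_in(ii, jj) < 0) dA(ii, jj) *= s.alpha;
    mat dZconv;
    if (!frozen) {
      // training-mode batch-norm backward
      double N = (double)dA.n_rows;
      grads[P.idx(bn + "_gamma")].row(0) = arma::sum(dA % bc.xhat, 0);
      grads[P.idx(bn + "_beta")].row(0)  = arma::sum(dA, 0);
      mat dxhat = dA; dxhat.each_row() %= P[bn + "_gamma"].row(0);
      rowvec sum_dxhat = arma::sum(dxhat, 0);
      rowvec sum_dxhat_xhat = arma::sum(dxhat % bc.xhat, 0);
      dZconv = dxhat * N;
      dZconv.each_row() -= sum_dxhat;
      mat tmp = bc.xhat; tmp.each_row() %= sum_dxhat_xhat;
      dZconv -= tmp;
      dZconv.each_row() %= bc.invstd / N;
    } else {
      // frozen BN: affine transform only (used during transfer learning)
      rowvec invstd = 1.0 / arma::sqrt(P[bn + "_rvar"].row(0) + BN_EPS);
      dZconv = dA;
      dZconv.each_row() %= invstd % P[bn + "_gamma"].row(0);
    }
    grads[P.idx(cb + "_b")].row(0) = arma::sum(dZconv, 0);
    mat M = im2col(bc.X_in, B, T, s.kernels[i]);
    grads[P.idx(cb + "_W")] = M.t() * dZconv;
    if (i > 0) {
      mat dM = dZconv * P[cb + "_W"].t();
      dA = col2im(dM, B, T, s.kernels[i], (int)bc.X_in.n_cols);
    }
    T_after = T;
  }
  (void)T_after;
}

// ---------------------------------------------------------------------------
// Loss / metric helpers

static double bce_loss(const vec& p, const vec& y) {
  vec pc = arma::clamp(p, BCE_CLAMP, 1.0 - BCE_CLAMP);
  return arma::mean(-(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc)));
}

static double accuracy_of(const vec& p, const vec& y) {
  return arma::mean(arma::conv_to<vec>::from((p >= 0.5) == (y >= 0.5)));
}

static vec predict_all(Params& P, const NetSpec& s, const mat& X, int batch) {
  int n = X.n_rows;
  vec out(n);
  for (int start = 0; start < n; start += batch) {
    int end = std::min(n, start + batch);
    out.subvec(start, end - 1) =
      forward(P, s, X.rows(start, end - 1), false, false, nullptr, nullptr);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported functions

// [[Rcpp::export(name = ".nn_init")]]
List nn_init_cpp(List spec, int seed) {
  NetSpec s = parse_spec(spec);
  Params p = init_params(s, (unsigned int)seed);
  return params_to_list(p);
}

// [[Rcpp::export(name = ".nn_predict")]]
NumericVector nn_predict_cpp(List params, List spec, NumericMatrix X,
                             int batch_size = 512) {
  NetSpec s = parse_spec(spec);
  Params p = params_from_list(params, s);
  mat Xa = to_f(X);
  if ((int)Xa.n_cols != s.window_len)
    stop("input windows have %d samples, model expects %d",
         (int)Xa.n_cols, s.window_len);
  vec out = predict_all(p, s, Xa, batch_size);
  return wrap(arma::conv_to<arma::vec>::from(out));
}

// Loss and analytic gradients in training mode (dropout rates should be zero
// for determinism). Used by the finite-difference gradient check in the
// test suite.
// [[Rcpp::export(name = ".nn_loss_grads")]]
List nn_loss_grads_cpp(List params, List spec, NumericMatrix X_,
                       NumericVector y_, bool grads_wanted) {
  NetSpec s = parse_spec(spec);
  Params P = params_from_list(params, s);
  mat X = to_f(X_);
  vec y = to_fv(y_);
  std::mt19937 rng(0);
  FwdCache cache;
  vec p = forward(P, s, X, true, false, &rng, &cache);
  double loss = bce_loss(p, y);
  List gl;
  if (grads_wanted) {
    std::vector<mat> grads(P.tensors.size());
    backward(P, s, cache, y, grads);
    Params G = P;
    G.tensors = grads;
    gl = params_to_list(G);
  }
  return List::create(_["loss"] = loss, _["grads"] = gl);
}

// [[Rcpp::export(name = ".nn_train")]]
List nn_train_cpp(List params, List spec,
                  NumericMatrix Xtr_, NumericVector ytr_,
                  NumericMatrix Xval_, NumericVector yval_,
                  double lr, int batch_size, int max_epochs, int patience,
                  int seed, bool freeze_conv, std::string monitor,
                  bool verbose) {
  NetSpec s = parse_spec(spec);
  Params P = params_from_list(params, s);
  mat Xtr = to_f(Xtr_), Xval = to_f(Xval_);
  vec ytr = to_fv(ytr_), yval = to_fv(yval_);
  int n = Xtr.n_rows;
  std::mt19937 rng((unsigned int)seed);

  // Adam/AMSGrad state
  size_t nt = P.tensors.size();
  std::vector<mat> m(nt), v(nt), vhat(nt), grads(nt);
  std::vector<bool> upd(nt);
  for (size_t i = 0; i < nt; ++i) {
    m[i] = v[i] = vhat[i] =
      mat(P.tensors[i].n_rows, P.tensors[i].n_cols, arma::fill::zeros);
    upd[i] = P.trainable[i] && !(freeze_conv && P.conv_part[i]);
  }

  std::vector<double> h_loss, h_acc, h_vloss, h_vacc;
  std::vector<mat> best_tensors = P.tensors;
  double best_metric = monitor == "val_accuracy" ? -1.0 : arma::datum::inf;
  int best_epoch = -1, wait = 0;
  long step = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0, ep_acc = 0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(n, start + batch_size);
      int B = end - start;
      mat Xb(B, Xtr.n_cols); vec yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.row(b) = Xtr.row(order[start + b]);
        yb(b) = ytr(order[start + b]);
      }
      FwdCache cache;
      vec p = forward(P, s, Xb, true, freeze_conv, &rng, &cache);
      double loss = bce_loss(p, yb);
      if (!std::isfinite(loss))
        stop("training aborted: non-finite loss at epoch %d (diverged; "
             "check input scaling and learning rate)", epoch + 1);
      ep_loss += loss; ep_acc += accuracy_of(p, yb); ++n_batches;
      backward(P, s, cache, yb, grads, freeze_conv);
      ++step;
      double bc1 = 1.0 - std::pow(ADAM_B1, (double)step);
      double bc2 = 1.0 - std::pow(ADAM_B2, (double)step);
      double lr_t = lr * std::sqrt(bc2) / bc1;
      for (size_t i = 0; i < nt; ++i) {
        if (!upd[i]) continue;
        m[i] = ADAM_B1 * m[i] + (1.0 - ADAM_B1) * grads[i];
        v[i] = ADAM_B2 * v[i] + (1.0 - ADAM_B2) * arma::square(grads[i]);
        vhat[i] = arma::max(vhat[i], v[i]);
        P.tensors[i] -= lr_t * m[i] / (arma::sqrt(vhat[i]) + ADAM_EPS);
      }
    }
    if (!freeze_conv) {
      // re-estimate batch-norm statistics over the training set with the
      // epoch's final weights (the 0.99-momentum EMA lags badly at the few
      // dozen batches per epoch of a compact training set)
      BnStats st;
      st.init(s);
      for (int start = 0; start < n; start += batch_size) {
        int end = std::min(n, start + batch_size);
        forward(P, s, Xtr.rows(start, end - 1), false, false, nullptr, nullptr,
                &st);
      }
      for (int i = 0; i < s.n_blocks; ++i) {
        std::string bn = "bn" + std::to_string(i + 1);
        rowvec mu = st.sum[i] / st.n[i];
        P[bn + "_rmean"].row(0) = mu;
        P[bn + "_rvar"].row(0) = st.sumsq[i] / st.n[i] - arma::square(mu);
      }
    }
    vec pv = predict_all(P, s, Xval, batch_size);
    double vloss = bce_loss(pv, yval), vacc = accuracy_of(pv, yval);
    h_loss.push_back(ep_loss / n_batches);
    h_acc.push_back(ep_acc / n_batches);
    h_vloss.push_back(vloss);
    h_vacc.push_back(vacc);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << ": loss=" << h_loss.back()
                  << " acc=" << h_acc.back() << " val_loss=" << vloss
                  << " val_acc=" << vacc << std::endl;
    bool improved = (monitor == "val_accuracy") ? (vacc > best_metric)
                                                : (vloss < best_metric);
    if (improved) {
      best_metric = (monitor == "val_accuracy") ? vacc : vloss;
      best_tensors = P.tensors;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      ++epoch;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  P.tensors = best_tensors;  // restore best checkpoint
  return List::create(
    _["params"] = params_to_list(P),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(h_loss.size()),
      _["loss"] = h_loss, _["accuracy"] = h_acc,
      _["val_loss"] = h_vloss, _["val_accuracy"] = h_vacc),
    _["best_epoch"] = best_epoch + 1,
    _["epochs_run"] = (int)h_loss.size());
}
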
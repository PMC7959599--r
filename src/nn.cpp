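// Compact trainer for the package's two sequence networks:
//  - 1D CNN: embedding (or fixed one-hot channels) -> 3 x (conv width-5 ReLU,
//    "same" padding -> max-pool size 4 stride 1) -> dense stack with ReLU and
//    dropout -> sigmoid / softmax head.
//  - LSTM: embedding -> LSTM (final state) -> dense ReLU -> dropout -> head.
// Single-threaded, float32, Adam, all randomness from one std::mt19937 seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat FM;
typedef arma::Mat<int> IM;

namespace {

struct Rng {
  std::mt19937 g;
  explicit Rng(unsigned s) : g(s) {}
  float runif(float a, float b) {
    std::uniform_real_distribution<float> d(a, b);
    return d(g);
  }
};

FM glorot(int r, int c, int fan_in, int fan_out, Rng& rng) {
  float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
  FM W(r, c);
  for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = rng.runif(-lim, lim);
  return W;
}

FM uniform_mat(int r, int c, float lim, Rng& rng) {
  FM W(r, c);
  for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = rng.runif(-lim, lim);
  return W;
}

void dropout_mask(FM& M, float rate, Rng& rng) {
  float keep = 1.0f - rate;
  std::uniform_real_distribution<float> d(0.0f, 1.0f);
  for (arma::uword j = 0; j < M.n_elem; ++j)
    M(j) = (d(rng.g) < keep) ? 1.0f / keep : 0.0f;
}

// token matrix (P x B) -> stacked per-sample feature columns (d x P*B)
void embed_tokens(const IM& toks, const FM& Wemb, bool onehot, int d, FM& X0) {
  int P = toks.n_rows, B = toks.n_cols;
  X0.zeros(d, (size_t)P * B);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P; ++p) {
      int t = toks(p, b);
      if (onehot) {
        if (t > 0) X0(t - 1, (size_t)b * P + p) = 1.0f;
      } else {
        X0.col((size_t)b * P + p) = Wemb.col(t);
      }
    }
}

void embed_backward(const IM& toks, const FM& dX0, FM& gWemb) {
  int P = toks.n_rows, B = toks.n_cols;
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < P; ++p)
      gWemb.col(toks(p, b)) += dX0.col((size_t)b * P + p);
}

// "same" padded im2col over per-sample column blocks
void im2col_same(const FM& A, int C, int P, int B, int W, FM& col) {
  int pad = (W - 1) / 2;
  col.zeros((size_t)C * W, (size_t)P * B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < W; ++o) {
      int off = o - pad;
      int p_lo = std::max(0, -off), p_hi = std::min(P, P - off);
      if (p_lo >= p_hi) continue;
      col.submat((size_t)o * C, (size_t)b * P + p_lo,
                 (size_t)o * C + C - 1, (size_t)b * P + p_hi - 1) =
        A.cols((size_t)b * P + p_lo + off, (size_t)b * P + p_hi - 1 + off);
    }
}

void col2im_same(const FM& dcol, int C, int P, int B, int W, FM& dA) {
  int pad = (W - 1) / 2;
  dA.zeros(C, (size_t)P * B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < W; ++o) {
      int off = o - pad;
      int p_lo = std::max(0, -off), p_hi = std::min(P, P - off);
      if (p_lo >= p_hi) continue;
      dA.cols((size_t)b * P + p_lo + off, (size_t)b * P + p_hi - 1 + off) +=
        dcol.submat((size_t)o * C, (size_t)b * P + p_lo,
                    (size_t)o * C + C - 1, (size_t)b * P + p_hi - 1);
    }
}

void maxpool(const FM& A, int F, int P, int B, int S, int T,
             FM& out, arma::Mat<short>& arg) {
  int Q = (P - S) / T + 1;
  out.set_size(F, (size_t)Q * B);
  arg.set_size(F, (size_t)Q * B);
  for (int b = 0; b < B; ++b)
    for (int q = 0; q < Q; ++q) {
      size_t oc = (size_t)b * Q + q, base = (size_t)b * P + q * T;
      for (int f = 0; f < F; ++f) {
        float m = A(f, base);
        short am = 0;
        for (int w = 1; w < S; ++w) {
          float v = A(f, base + w);
          if (v > m) { m = v; am = (short)w; }
        }
        out(f, oc) = m;
        arg(f, oc) = am;
      }
    }
}

void maxpool_backward(const FM& dP, const arma::Mat<short>& arg,
                      int F, int P, int B, int S, int T, FM& dA) {
  int Q = (P - S) / T + 1;
  dA.zeros(F, (size_t)P * B);
  for (int b = 0; b < B; ++b)
    for (int q = 0; q < Q; ++q) {
      size_t oc = (size_t)b * Q + q, base = (size_t)b * P + q * T;
      for (int f = 0; f < F; ++f)
        dA(f, base + arg(f, oc)) += dP(f, oc);
    }
}

void softmax_cols(FM& Z) {
  arma::frowvec mx = arma::max(Z, 0);
  Z.each_row() -= mx;
  Z = arma::exp(Z);
  arma::frowvec s = arma::sum(Z, 0);
  Z.each_row() /= s;
}

double head_loss(const FM& probs, const std::vector<int>& y, int nout) {
  const float eps = 1e-7f;
  double L = 0.0;
  int B = probs.n_cols;
  for (int b = 0; b < B; ++b) {
    if (nout == 1) {
      float p = std::min(std::max(probs(0, b), eps), 1.0f - eps);
      L -= y[b] ? std::log(p) : std::log(1.0f - p);
    } else {
      float p = std::max(probs(y[b], b), eps);
      L -= std::log(p);
    }
  }
  return L / B;
}

// ------------------------------------------------------------------ CNN ----

struct CnnModel {
  bool onehot;
  int V, d, P, F, Wf, S, T, nout;
  std::vector<int> dense;
  std::vector<int> Cin, Pin, Pq;  // per conv block: in channels, in len, pooled len
  int m;                          // flatten size
  FM Wemb;
  std::vector<FM> Wc, bc, Wd, bd;
  FM Wo, bo;
  float drop;
};

void cnn_dims(CnnModel& M) {
  M.Cin.assign(3, M.F);
  M.Cin[0] = M.d;
  M.Pin.resize(3);
  M.Pq.resize(3);
  int p = M.P;
  for (int l = 0; l < 3; ++l) {
    M.Pin[l] = p;
    if (p < M.S)
      stop("sequence too short for the conv/pool stack (length %d at block %d)", p, l + 1);
    p = (p - M.S) / M.T + 1;
    M.Pq[l] = p;
  }
  M.m = M.F * M.Pq[2];
}

CnnModel cnn_from_spec(List spec) {
  CnnModel M;
  M.onehot = as<bool>(spec["onehot"]);
  M.V = as<int>(spec["vocab_size"]);
  M.d = M.onehot ? M.V : as<int>(spec["embedding_dim"]);
  M.P = as<int>(spec["n_positions"]);
  M.F = as<int>(spec["n_filters"]);
  M.Wf = as<int>(spec["filter_width"]);
  M.S = as<int>(spec["pool_size"]);
  M.T = as<int>(spec["pool_stride"]);
  int n_classes = as<int>(spec["n_classes"]);
  M.nout = (n_classes == 2) ? 1 : n_classes;
  M.dense = as<std::vector<int>>(spec["dense_units"]);
  M.drop = as<float>(spec["dropout"]);
  if (M.P < M.Wf) stop("n_positions (%d) < filter width (%d)", M.P, M.Wf);
  cnn_dims(M);
  return M;
}

void cnn_load_weights(CnnModel& M, List w) {
  if (!M.onehot) M.Wemb = as<FM>(w["Wemb"]);
  M.Wc.resize(3); M.bc.resize(3);
  for (int l = 0; l < 3; ++l) {
    M.Wc[l] = as<FM>(w["Wc" + std::to_string(l + 1)]);
    M.bc[l] = as<FM>(w["bc" + std::to_string(l + 1)]);
  }
  int nd = M.dense.size();
  M.Wd.resize(nd); M.bd.resize(nd);
  for (int l = 0; l < nd; ++l) {
    M.Wd[l] = as<FM>(w["Wd" + std::to_string(l + 1)]);
    M.bd[l] = as<FM>(w["bd" + std::to_string(l + 1)]);
  }
  M.Wo = as<FM>(w["Wo"]);
  M.bo = as<FM>(w["bo"]);
}

List cnn_dump_weights(const CnnModel& M) {
  List w;
  if (!M.onehot) w["Wemb"] = M.Wemb;
  for (int l = 0; l < 3; ++l) {
    w["Wc" + std::to_string(l + 1)] = M.Wc[l];
    w["bc" + std::to_string(l + 1)] = M.bc[l];
  }
  for (size_t l = 0; l < M.Wd.size(); ++l) {
    w["Wd" + std::to_string(l + 1)] = M.Wd[l];
    w["bd" + std::to_string(l + 1)] = M.bd[l];
  }
  w["Wo"] = M.Wo;
  w["bo"] = M.bo;
  return w;
}

struct CnnCache {
  FM X0;
  std::vector<FM> col, A, Pl;           // conv: im2col, relu output, pooled
  std::vector<arma::Mat<short>> arg;
  std::vector<FM> Ad, Md;               // dense relu outputs, dropout masks
  FM probs;
};

void cnn_forward(const CnnModel& M, const IM& toks, bool training, Rng* rng,
                 CnnCache& C) {
  int B = toks.n_cols;
  embed_tokens(toks, M.Wemb, M.onehot, M.d, C.X0);
  C.col.resize(3); C.A.resize(3); C.Pl.resize(3); C.arg.resize(3);
  const FM* in = &C.X0;
  for (int l = 0; l < 3; ++l) {
    im2col_same(*in, M.Cin[l], M.Pin[l], B, M.Wf, C.col[l]);
    C.A[l] = M.Wc[l] * C.col[l];
    C.A[l].each_col() += M.bc[l].col(0);
    C.A[l].transform([](float x) { return x > 0.0f ? x : 0.0f; });
    maxpool(C.A[l], M.F, M.Pin[l], B, M.S, M.T, C.Pl[l], C.arg[l]);
    in = &C.Pl[l];
  }
  // flatten is a zero-copy view: per-sample columns are contiguous
  FM flat(const_cast<float*>(C.Pl[2].memptr()), M.m, B, false, true);
  int nd = M.dense.size();
  C.Ad.resize(nd); C.Md.resize(nd);
  const FM* h = &flat;
  for (int l = 0; l < nd; ++l) {
    C.Ad[l] = M.Wd[l] * (*h);
    C.Ad[l].each_col() += M.bd[l].col(0);
    C.Ad[l].transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (training && M.drop > 0.0f) {
      C.Md[l].set_size(C.Ad[l].n_rows, C.Ad[l].n_cols);
      dropout_mask(C.Md[l], M.drop, *rng);
      C.Ad[l] %= C.Md[l];
    }
    h = &C.Ad[l];
  }
  C.probs = M.Wo * (*h);
  C.probs.each_col() += M.bo.col(0);
  if (M.nout == 1)
    C.probs.transform([](float z) { return 1.0f / (1.0f + std::exp(-z)); });
  else
    softmax_cols(C.probs);
}

struct CnnGrads {
  FM gWemb;
  std::vector<FM> gWc, gbc, gWd, gbd;
  FM gWo, gbo;
};

void cnn_backward(const CnnModel& M, const IM& toks, const std::vector<int>& y,
                  bool training, CnnCache& C, CnnGrads& G) {
  int B = toks.n_cols;
  int nd = M.dense.size();
  FM dZ = C.probs;  // nout x B
  if (M.nout == 1) {
    for (int b = 0; b < B; ++b) dZ(0, b) -= (float)y[b];
  } else {
    for (int b = 0; b < B; ++b) dZ(y[b], b) -= 1.0f;
  }
  dZ /= (float)B;

  FM flat(const_cast<float*>(C.Pl[2].memptr()), M.m, B, false, true);
  const FM* hlast = nd > 0 ? &C.Ad[nd - 1] : &flat;
  G.gWo = dZ * hlast->t();
  G.gbo.zeros(M.bo.n_rows, 1);
  G.gbo.col(0) = arma::sum(dZ, 1);
  FM dh = M.Wo.t() * dZ;

  G.gWd.resize(nd); G.gbd.resize(nd);
  for (int l = nd - 1; l >= 0; --l) {
    if (training && M.drop > 0.0f) dh %= C.Md[l];
    dh %= arma::conv_to<FM>::from(C.Ad[l] > 0.0f);
    const FM* in = (l == 0) ? &flat : &C.Ad[l - 1];
    G.gWd[l] = dh * in->t();
    G.gbd[l].zeros(M.bd[l].n_rows, 1);
    G.gbd[l].col(0) = arma::sum(dh, 1);
    dh = M.Wd[l].t() * dh;
  }
  // dh is now dflat (m x B) -> view as F x (Pq3 * B)
  FM dPl(dh.memptr(), M.F, (size_t)M.Pq[2] * B, false, true);
  G.gWc.resize(3); G.gbc.resize(3);
  FM dA, dcol, dIn;
  FM dPool = dPl;
  for (int l = 2; l >= 0; --l) {
    maxpool_backward(dPool, C.arg[l], M.F, M.Pin[l], B, M.S, M.T, dA);
    dA %= arma::conv_to<FM>::from(C.A[l] > 0.0f);
    G.gWc[l] = dA * C.col[l].t();
    G.gbc[l].zeros(M.bc[l].n_rows, 1);
    G.gbc[l].col(0) = arma::sum(dA, 1);
    dcol = M.Wc[l].t() * dA;
    col2im_same(dcol, M.Cin[l], M.Pin[l], B, M.Wf, dIn);
    dPool = dIn;
  }
  if (!M.onehot) {
    G.gWemb.zeros(M.Wemb.n_rows, M.Wemb.n_cols);
    embed_backward(toks, dPool, G.gWemb);
  }
}

// --------------------------------------------------------------- Adam ------

struct Adam {
  std::vector<FM> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7, lr;
  long t = 0;
  void init(const std::vector<FM*>& params, double lr_) {
    lr = lr_;
    m.resize(params.size());
    v.resize(params.size());
    for (size_t i = 0; i < params.size(); ++i) {
      m[i].zeros(params[i]->n_rows, params[i]->n_cols);
      v[i].zeros(params[i]->n_rows, params[i]->n_cols);
    }
  }
  void step(std::vector<FM*>& params, const std::vector<FM*>& grads) {
    ++t;
    float c1 = 1.0f - std::pow((float)b1, (float)t);
    float c2 = 1.0f - std::pow((float)b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = (float)b1 * m[i] + (1.0f - (float)b1) * (*grads[i]);
      v[i] = (float)b2 * v[i] + (1.0f - (float)b2) * arma::square(*grads[i]);
      *params[i] -= (float)lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + (float)eps);
    }
  }
};

std::vector<FM*> cnn_param_ptrs(CnnModel& M) {
  std::vector<FM*> p;
  if (!M.onehot) p.push_back(&M.Wemb);
  for (int l = 0; l < 3; ++l) { p.push_back(&M.Wc[l]); p.push_back(&M.bc[l]); }
  for (size_t l = 0; l < M.Wd.size(); ++l) { p.push_back(&M.Wd[l]); p.push_back(&M.bd[l]); }
  p.push_back(&M.Wo); p.push_back(&M.bo);
  return p;
}

std::vector<FM*> cnn_grad_ptrs(CnnModel& M, CnnGrads& G) {
  std::vector<FM*> p;
  if (!M.onehot) p.push_back(&G.gWemb);
  for (int l = 0; l < 3; ++l) { p.push_back(&G.gWc[l]); p.push_back(&G.gbc[l]); }
  for (size_t l = 0; l < G.gWd.size(); ++l) { p.push_back(&G.gWd[l]); p.push_back(&G.gbd[l]); }
  p.push_back(&G.gWo); p.push_back(&G.gbo);
  return p;
}

IM to_tokmat(const IntegerMatrix& toks) {
  // R gives samples in rows; internally we use positions x samples
  int n = toks.nrow(), P = toks.ncol();
  IM T(P, n);
  for (int i = 0; i < n; ++i)
    for (int p = 0; p < P; ++p) T(p, i) = toks(i, p);
  return T;
}

// ------------------------------------------------------------------ LSTM ---

struct LstmModel {
  bool onehot;
  int V, d, P, H, nd, nout;
  float drop;
  FM Wemb, Wx, Wh, b, Wd, bd, Wo, bo;
};

LstmModel lstm_from_spec(List spec) {
  LstmModel M;
  M.onehot = as<bool>(spec["onehot"]);
  M.V = as<int>(spec["vocab_size"]);
  M.d = M.onehot ? M.V : as<int>(spec["embedding_dim"]);
  M.P = as<int>(spec["n_positions"]);
  M.H = as<int>(spec["lstm_units"]);
  M.nd = as<int>(spec["dense_units"]);
  int n_classes = as<int>(spec["n_classes"]);
  M.nout = (n_classes == 2) ? 1 : n_classes;
  M.drop = as<float>(spec["dropout"]);
  if (M.P < 1) stop("n_positions must be >= 1");
  return M;
}

void lstm_load_weights(LstmModel& M, List w) {
  if (!M.onehot) M.Wemb = as<FM>(w["Wemb"]);
  M.Wx = as<FM>(w["Wx"]); M.Wh = as<FM>(w["Wh"]); M.b = as<FM>(w["b"]);
  M.Wd = as<FM>(w["Wd"]); M.bd = as<FM>(w["bd"]);
  M.Wo = as<FM>(w["Wo"]); M.bo = as<FM>(w["bo"]);
}

List lstm_dump_weights(const LstmModel& M) {
  List w;
  if (!M.onehot) w["Wemb"] = M.Wemb;
  w["Wx"] = M.Wx; w["Wh"] = M.Wh; w["b"] = M.b;
  w["Wd"] = M.Wd; w["bd"] = M.bd; w["Wo"] = M.Wo; w["bo"] = M.bo;
  return w;
}

struct LstmCache {
  std::vector<FM> I, F, G, O, Ct, Tc, Hs;  // Hs[t] = h after step t (Hs[0] = 0)
  FM Ad, Md, probs;
};

inline FM sigm(const FM& Z) {
  FM R = Z;
  R.transform([](float z) { return 1.0f / (1.0f + std::exp(-z)); });
  return R;
}

void lstm_forward(const LstmModel& M, const IM& toks, bool training, Rng* rng,
                  LstmCache& C) {
  int B = toks.n_cols, H = M.H, P = M.P;
  C.I.resize(P); C.F.resize(P); C.G.resize(P); C.O.resize(P);
  C.Ct.resize(P); C.Tc.resize(P); C.Hs.resize(P + 1);
  C.Hs[0].zeros(H, B);
  FM c(H, B, arma::fill::zeros), Xt(M.d, B);
  for (int t = 0; t < P; ++t) {
    Xt.zeros();
    for (int bcol = 0; bcol < B; ++bcol) {
      int tok = toks(t, bcol);
      if (M.onehot) { if (tok > 0) Xt(tok - 1, bcol) = 1.0f; }
      else Xt.col(bcol) = M.Wemb.col(tok);
    }
    FM Gm = M.Wx * Xt + M.Wh * C.Hs[t];
    Gm.each_col() += M.b.col(0);
    C.I[t] = sigm(Gm.rows(0, H - 1));
    C.F[t] = sigm(Gm.rows(H, 2 * H - 1));
    C.G[t] = arma::tanh(Gm.rows(2 * H, 3 * H - 1));
    C.O[t] = sigm(Gm.rows(3 * H, 4 * H - 1));
    c = C.F[t] % c + C.I[t] % C.G[t];
    C.Ct[t] = c;
    C.Tc[t] = arma::tanh(c);
    C.Hs[t + 1] = C.O[t] % C.Tc[t];
  }
  C.Ad = M.Wd * C.Hs[P];
  C.Ad.each_col() += M.bd.col(0);
  C.Ad.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  if (training && M.drop > 0.0f) {
    C.Md.set_size(C.Ad.n_rows, C.Ad.n_cols);
    dropout_mask(C.Md, M.drop, *rng);
    C.Ad %= C.Md;
  }
  C.probs = M.Wo * C.Ad;
  C.probs.each_col() += M.bo.col(0);
  if (M.nout == 1)
    C.probs.transform([](float z) { return 1.0f / (1.0f + std::exp(-z)); });
  else
    softmax_cols(C.probs);
}

struct LstmGrads {
  FM gWemb, gWx, gWh, gb, gWd, gbd, gWo, gbo;
};

void lstm_backward(const LstmModel& M, const IM& toks, const std::vector<int>& y,
                   bool training, LstmCache& C, LstmGrads& G) {
  int B = toks.n_cols, H = M.H, P = M.P;
  FM dZ = C.probs;
  if (M.nout == 1) {
    for (int b = 0; b < B; ++b) dZ(0, b) -= (float)y[b];
  } else {
    for (int b = 0; b < B; ++b) dZ(y[b], b) -= 1.0f;
  }
  dZ /= (float)B;
  G.gWo = dZ * C.Ad.t();
  G.gbo.zeros(M.bo.n_rows, 1);
  G.gbo.col(0) = arma::sum(dZ, 1);
  FM dAd = M.Wo.t() * dZ;
  if (training && M.drop > 0.0f) dAd %= C.Md;
  dAd %= arma::conv_to<FM>::from(C.Ad > 0.0f);
  G.gWd = dAd * C.Hs[P].t();
  G.gbd.zeros(M.bd.n_rows, 1);
  G.gbd.col(0) = arma::sum(dAd, 1);

  G.gWx.zeros(M.Wx.n_rows, M.Wx.n_cols);
  G.gWh.zeros(M.Wh.n_rows, M.Wh.n_cols);
  G.gb.zeros(M.b.n_rows, 1);
  if (!M.onehot) G.gWemb.zeros(M.Wemb.n_rows, M.Wemb.n_cols);

  FM dh = M.Wd.t() * dAd;
  FM dc(H, B, arma::fill::zeros), Xt(M.d, B), dG(4 * H, B);
  for (int t = P - 1; t >= 0; --t) {
    FM dO = dh % C.Tc[t];
    dc += dh % C.O[t] % (1.0f - arma::square(C.Tc[t]));
    FM dI = dc % C.G[t];
    FM dGg = dc % C.I[t];
    FM cprev = (t == 0) ? FM(H, B, arma::fill::zeros) : C.Ct[t - 1];
    FM dF = dc % cprev;
    dG.rows(0, H - 1)         = dI % C.I[t] % (1.0f - C.I[t]);
    dG.rows(H, 2 * H - 1)     = dF % C.F[t] % (1.0f - C.F[t]);
    dG.rows(2 * H, 3 * H - 1) = dGg % (1.0f - arma::square(C.G[t]));
    dG.rows(3 * H, 4 * H - 1) = dO % C.O[t] % (1.0f - C.O[t]);
    Xt.zeros();
    for (int bcol = 0; bcol < B; ++bcol) {
      int tok = toks(t, bcol);
      if (M.onehot) { if (tok > 0) Xt(tok - 1, bcol) = 1.0f; }
      else Xt.col(bcol) = M.Wemb.col(tok);
    }
    G.gWx += dG * Xt.t();
    G.gWh += dG * C.Hs[t].t();
    G.gb.col(0) += arma::sum(dG, 1);
    if (!M.onehot) {
      FM dX = M.Wx.t() * dG;
      for (int bcol = 0; bcol < B; ++bcol)
        G.gWemb.col(toks(t, bcol)) += dX.col(bcol);
    }
    dh = M.Wh.t() * dG;
    dc %= C.F[t];
  }
}

std::vector<FM*> lstm_param_ptrs(LstmModel& M) {
  std::vector<FM*> p;
  if (!M.onehot) p.push_back(&M.Wemb);
  p.push_back(&M.Wx); p.push_back(&M.Wh); p.push_back(&M.b);
  p.push_back(&M.Wd); p.push_back(&M.bd); p.push_back(&M.Wo); p.push_back(&M.bo);
  return p;
}

std::vector<FM*> lstm_grad_ptrs(LstmModel& M, LstmGrads& G) {
  std::vector<FM*> p;
  if (!M.onehot) p.push_back(&G.gWemb);
  p.push_back(&G.gWx); p.push_back(&G.gWh); p.push_back(&G.gb);
  p.push_back(&G.gWd); p.push_back(&G.gbd); p.push_back(&G.gWo); p.push_back(&G.gbo);
  return p;
}

// ---------------------------------------------------- shared training ------

template <typename Model, typename Cache, typename Grads>
struct Ops;  // forward/backward dispatch

struct CnnOps {
  typedef CnnModel Model; typedef CnnCache Cache; typedef CnnGrads Grads;
  static void fwd(const Model& M, const IM& t, bool tr, Rng* r, Cache& C) { cnn_forward(M, t, tr, r, C); }
  static void bwd(const Model& M, const IM& t, const std::vector<int>& y, bool tr, Cache& C, Grads& G) { cnn_backward(M, t, y, tr, C, G); }
  static std::vector<FM*> pptr(Model& M) { return cnn_param_ptrs(M); }
  static std::vector<FM*> gptr(Model& M, Grads& G) { return cnn_grad_ptrs(M, G); }
  static List dump(const Model& M) { return cnn_dump_weights(M); }
};

struct LstmOps {
  typedef LstmModel Model; typedef LstmCache Cache; typedef LstmGrads Grads;
  static void fwd(const Model& M, const IM& t, bool tr, Rng* r, Cache& C) { lstm_forward(M, t, tr, r, C); }
  static void bwd(const Model& M, const IM& t, const std::vector<int>& y, bool tr, Cache& C, Grads& G) { lstm_backward(M, t, y, tr, C, G); }
  static std::vector<FM*> pptr(Model& M) { return lstm_param_ptrs(M); }
  static std::vector<FM*> gptr(Model& M, Grads& G) { return lstm_grad_ptrs(M, G); }
  static List dump(const Model& M) { return lstm_dump_weights(M); }
};

template <typename OPS>
double eval_loss_acc(typename OPS::Model& M, const IM& toks,
                     const std::vector<int>& y, int nout, double* acc) {
  int n = toks.n_cols, chunk = 256;
  double L = 0.0;
  long correct = 0;
  typename OPS::Cache C;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    IM bt = toks.cols(s, e - 1);
    std::vector<int> by(y.begin() + s, y.begin() + e);
    OPS::fwd(M, bt, false, nullptr, C);
    L += head_loss(C.probs, by, nout) * (e - s);
    for (int b = 0; b < e - s; ++b) {
      int pred;
      if (nout == 1) pred = C.probs(0, b) >= 0.5f ? 1 : 0;
      else pred = (int)arma::index_max(C.probs.col(b));
      if (pred == by[b]) ++correct;
    }
  }
  if (acc) *acc = (double)correct / n;
  return L / n;
}

template <typename OPS>
List train_loop(typename OPS::Model& M, const IntegerMatrix& tokens,
                const IntegerVector& y, Nullable<IntegerMatrix> vtokens,
                Nullable<IntegerVector> vy, List config, int seed) {
  IM T = to_tokmat(tokens);
  std::vector<int> yv = as<std::vector<int>>(y);
  bool has_val = vtokens.isNotNull();
  IM VT;
  std::vector<int> vyv;
  if (has_val) {
    VT = to_tokmat(vtokens.get());
    vyv = as<std::vector<int>>(IntegerVector(vy.get()));
  }
  int epochs = as<int>(config["epochs"]);
  int batch = as<int>(config["batch_size"]);
  double lr = as<double>(config["lr"]);
  int patience = as<int>(config["patience"]);
  bool early = as<bool>(config["early_stopping"]) && has_val;

  Rng rng((unsigned)seed);
  std::vector<FM*> params = OPS::pptr(M);
  Adam opt;
  opt.init(params, lr);

  int n = T.n_cols;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> tr_loss, val_loss, val_acc;
  double best = std::numeric_limits<double>::infinity();
  int wait = 0, epochs_run = 0;
  std::vector<FM> best_w;

  typename OPS::Cache C;
  typename OPS::Grads G;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng.g);
    double L = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      int B = e - s;
      IM bt(T.n_rows, B);
      std::vector<int> by(B);
      for (int b = 0; b < B; ++b) { bt.col(b) = T.col(idx[s + b]); by[b] = yv[idx[s + b]]; }
      OPS::fwd(M, bt, true, &rng, C);
      L += head_loss(C.probs, by, M.nout);
      ++nb;
      OPS::bwd(M, bt, by, true, C, G);
      std::vector<FM*> g = OPS::gptr(M, G);
      opt.step(params, g);
    }
    tr_loss.push_back(L / nb);
    epochs_run = ep + 1;
    if (has_val) {
      double acc;
      double vl = eval_loss_acc<OPS>(M, VT, vyv, M.nout, &acc);
      val_loss.push_back(vl);
      val_acc.push_back(acc);
      if (early) {
        if (vl < best - 1e-6) {
          best = vl;
          wait = 0;
          best_w.clear();
          for (auto* p : params) best_w.push_back(*p);
        } else if (++wait >= patience) {
          break;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (early && !best_w.empty())
    for (size_t i = 0; i < params.size(); ++i) *params[i] = best_w[i];

  return List::create(
    _["weights"] = OPS::dump(M),
    _["history"] = List::create(_["loss"] = tr_loss, _["val_loss"] = val_loss,
                                _["val_acc"] = val_acc),
    _["epochs_run"] = epochs_run);
}

template <typename OPS>
NumericMatrix predict_probs(typename OPS::Model& M, const IntegerMatrix& tokens) {
  IM T = to_tokmat(tokens);
  int n = T.n_cols, chunk = 256;
  NumericMatrix out(n, M.nout);
  typename OPS::Cache C;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    IM bt = T.cols(s, e - 1);
    OPS::fwd(M, bt, false, nullptr, C);
    for (int b = 0; b < e - s; ++b)
      for (int o = 0; o < M.nout; ++o) out(s + b, o) = C.probs(o, b);
  }
  return out;
}

}  // namespace

// --------------------------------------------------------------- exports ---

// [[Rcpp::export]]
List cpp_cnn_init(List spec, int seed) {
  CnnModel M = cnn_from_spec(spec);
  Rng rng((unsigned)seed);
  if (!M.onehot) M.Wemb = uniform_mat(M.d, M.V + 1, 0.05f, rng);
  M.Wc.resize(3); M.bc.resize(3);
  for (int l = 0; l < 3; ++l) {
    int fin = M.Cin[l] * M.Wf, fout = M.F * M.Wf;
    M.Wc[l] = glorot(M.F, M.Cin[l] * M.Wf, fin, fout, rng);
    M.bc[l].zeros(M.F, 1);
  }
  int nd = M.dense.size();
  M.Wd.resize(nd); M.bd.resize(nd);
  int in = M.m;
  for (int l = 0; l < nd; ++l) {
    M.Wd[l] = glorot(M.dense[l], in, in, M.dense[l], rng);
    M.bd[l].zeros(M.dense[l], 1);
    in = M.dense[l];
  }
  M.Wo = glorot(M.nout, in, in, M.nout, rng);
  M.bo.zeros(M.nout, 1);
  return cnn_dump_weights(M);
}

// [[Rcpp::export]]
List cpp_cnn_train(IntegerMatrix tokens, IntegerVector y,
                   Nullable<IntegerMatrix> vtokens, Nullable<IntegerVector> vy,
                   List weights, List spec, List config, int seed) {
  CnnModel M = cnn_from_spec(spec);
  cnn_load_weights(M, weights);
  return train_loop<CnnOps>(M, tokens, y, vtokens, vy, config, seed);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(IntegerMatrix tokens, List weights, List spec) {
  CnnModel M = cnn_from_spec(spec);
  cnn_load_weights(M, weights);
  return predict_probs<CnnOps>(M, tokens);
}

// [[Rcpp::export]]
List cpp_cnn_loss_grad(IntegerMatrix tokens, IntegerVector y, List weights,
                       List spec) {
  CnnModel M = cnn_from_spec(spec);
  cnn_load_weights(M, weights);
  IM T = to_tokmat(tokens);
  std::vector<int> yv = as<std::vector<int>>(y);
  CnnCache C;
  cnn_forward(M, T, false, nullptr, C);
  double L = head_loss(C.probs, yv, M.nout);
  CnnGrads G;
  cnn_backward(M, T, yv, false, C, G);
  List g;
  if (!M.onehot) g["Wemb"] = G.gWemb;
  for (int l = 0; l < 3; ++l) {
    g["Wc" + std::to_string(l + 1)] = G.gWc[l];
    g["bc" + std::to_string(l + 1)] = G.gbc[l];
  }
  for (size_t l = 0; l < G.gWd.size(); ++l) {
    g["Wd" + std::to_string(l + 1)] = G.gWd[l];
    g["bd" + std::to_string(l + 1)] = G.gbd[l];
  }
  g["Wo"] = G.gWo;
  g["bo"] = G.gbo;
  return List::create(_["loss"] = L, _["grads"] = g);
}

// [[Rcpp::export]]
List cpp_lstm_init(List spec, int seed) {
  LstmModel M = lstm_from_spec(spec);
  Rng rng((unsigned)seed);
  int H = M.H;
  if (!M.onehot) M.Wemb = uniform_mat(M.d, M.V + 1, 0.05f, rng);
  M.Wx = glorot(4 * H, M.d, M.d, 4 * H, rng);
  M.Wh = glorot(4 * H, H, H, 4 * H, rng);
  M.b.zeros(4 * H, 1);
  M.b.submat(H, 0, 2 * H - 1, 0).fill(1.0f);  // forget-gate bias
  M.Wd = glorot(M.nd, H, H, M.nd, rng);
  M.bd.zeros(M.nd, 1);
  M.Wo = glorot(M.nout, M.nd, M.nd, M.nout, rng);
  M.bo.zeros(M.nout, 1);
  return lstm_dump_weights(M);
}

// [[Rcpp::export]]
List cpp_lstm_train(IntegerMatrix tokens, IntegerVector y,
                    Nullable<IntegerMatrix> vtokens, Nullable<IntegerVector> vy,
                    List weights, List spec, List config, int seed) {
  LstmModel M = lstm_from_spec(spec);
  lstm_load_weights(M, weights);
  return train_loop<LstmOps>(M, tokens, y, vtokens, vy, config, seed);
}

// [[Rcpp::export]]
NumericMatrix cpp_lstm_predict(IntegerMatrix tokens, List weights, List spec) {
  LstmModel M = lstm_from_spec(spec);
  lstm_load_weights(M, weights);
  return predict_probs<LstmOps>(M, tokens);
}

// [[Rcpp::export]]
List cpp_lstm_loss_grad(IntegerMatrix tokens, IntegerVector y, List weights,
                        List spec) {
  LstmModel M = lstm_from_spec(spec);
  lstm_load_weights(M, weights);
  IM T = to_tokmat(tokens);
  std::vector<int> yv = as<std::vector<int>>(y);
  LstmCache C;
  lstm_forward(M, T, false, nullptr, C);
  double L = head_loss(C.probs, yv, M.nout);
  LstmGrads G;
  lstm_backward(M, T, yv, false, C, G);
  List g;
  if (!M.onehot) g["Wemb"] = G.gWemb;
  g["Wx"] = G.gWx; g["Wh"] = G.gWh; g["b"] = G.gb;
  g["Wd"] = G.gWd; g["bd"] = G.gbd; g["Wo"] = G.gWo; g["bo"] = G.gbo;
  return List::create(_["loss"] = L, _["grads"] = g);
}
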
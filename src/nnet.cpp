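// Sequence-pair interaction network: embedding -> 1-D CNN (same padding,
// ReLU, max-pool) -> masked BiLSTM -> multi-head mutual attention
// (miRNA queries, mRNA keys/values) -> masked mean pooling -> BP fusion of
// sequence and node features -> sigmoid. Forward and backward passes are
// hand-derived; training uses Adam on binary cross-entropy. Single-threaded
// and deterministic for a fixed seed.
#include <RcppArmadillo.h>
#include <random>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// single precision for the training core: the workload is BLAS-bound and
// float GEMM doubles throughput on one CPU; the standalone attention entry
// point below is instantiated in double as well
typedef arma::fmat mat;
typedef arma::fcube cube;
typedef arma::fvec vec;
typedef arma::frowvec rowvec;

// ---------------------------------------------------------------- config ---

struct Cfg {
  int V, De, Tmi, Tm, F, kernel, pool, H, heads, ablation, fusion, dn;
  bool bidir, m_maxpool;
  double dropout, node_dropout, crop_min, lr;
  int epochs, batch;
  // ablation: 0 full, 1 noatt, 2 unidirectional lstm, 3 nolstm
  // fusion: 0 concat_bp, 1 add, 2 average, 3 dnn, 4 no_bp
  int d() const { return ablation == 3 ? F : (ablation == 2 ? H : 2 * H); }
  int Tmi_p() const { return Tmi / pool; }
  int Tm_p() const { return Tm / pool; }
  int zdim() const {
    return (fusion == 1 || fusion == 2) ? d() : 2 * d() + 2 * dn;
  }
};

static Cfg cfg_from_list(List L) {
  Cfg c;
  c.V = L["vocab_size"]; c.De = L["embed_dim"];
  c.Tmi = L["mirna_len"]; c.Tm = L["mrna_len"];
  c.F = L["cnn_filters"]; c.kernel = L["cnn_kernel"]; c.pool = L["pool"];
  c.H = L["lstm_hidden"]; c.heads = L["heads"];
  c.ablation = L["ablation_code"]; c.fusion = L["fusion_code"];
  c.bidir = as<bool>(L["att_bidirectional"]);
  c.m_maxpool = as<std::string>(L["mrna_summary"]) == "max";
  c.dn = L["node_dim"];
  c.dropout = L["dropout"]; c.node_dropout = L["node_dropout"];
  c.crop_min = L["augment_crop"];
  c.lr = L["lr"];
  c.epochs = L["epochs"]; c.batch = L["batch"];
  if (c.kernel % 2 == 0) stop("cnn_kernel must be odd");
  if (c.ablation != 3 && c.d() % c.heads != 0)
    stop("attention dim not divisible by heads");
  return c;
}

// ------------------------------------------------------------ parameters ---

struct Params {
  std::vector<std::string> names;
  std::vector<mat> M;
  int find(const std::string& n) const {
    for (size_t i = 0; i < names.size(); ++i)
      if (names[i] == n) return (int)i;
    return -1;
  }
  bool has(const std::string& n) const { return find(n) >= 0; }
  mat& operator[](const std::string& n) {
    int i = find(n);
    if (i < 0) stop("missing parameter '" + n + "'");
    return M[i];
  }
  const mat& at(const std::string& n) const {
    int i = find(n);
    if (i < 0) stop("missing parameter '" + n + "'");
    return M[i];
  }
  Params zeros_like() const {
    Params g; g.names = names; g.M.resize(M.size());
    for (size_t i = 0; i < M.size(); ++i)
      g.M[i] = mat(M[i].n_rows, M[i].n_cols, arma::fill::zeros);
    return g;
  }
};

static Params params_from_list(List L) {
  Params p;
  CharacterVector nm = L.names();
  for (int i = 0; i < L.size(); ++i) {
    p.names.push_back(as<std::string>(nm[i]));
    p.M.push_back(as<mat>(L[i]));
  }
  return p;
}

static List params_to_list(const Params& p) {
  List L(p.M.size());
  L.names() = wrap(p.names);
  for (size_t i = 0; i < p.M.size(); ++i) L[i] = p.M[i];
  return L;
}

static int n_fusion_layers(const Params& p) {
  int n = 0;
  while (p.has("fus_W" + std::to_string(n + 1))) ++n;
  return n;
}

// ----------------------------------------------------------- activations ---

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ------------------------------------------------------------- encoder -----

struct DirCache { cube Gi, Gf, Gg, Go, C, Hs; };

struct SideCache {
  int B, T, Tp, d;
  std::vector<mat> Y;        // per sample: T x F, post-ReLU conv output
  std::vector<arma::umat> am;// per sample: Tp x F argmax source row
  std::vector<mat> P;        // per sample: Tp x F pooled features
  mat mask;                  // B x Tp pooled-position validity
  vec nval;                  // valid pooled positions per sample
  std::vector<int> tok_start, tok_len;  // crop window actually encoded
  DirCache fw, bw;
  cube Hseq;                 // B x d x Tp encoder output
};

static mat im2col_tokens(const mat& emb, const std::vector<int>& tok,
                         int T, int kernel, int De) {
  const int pad = (kernel - 1) / 2;
  mat Mt(T, kernel * De, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int kk = 0; kk < kernel; ++kk) {
      const int s = t + kk - pad;
      if (s < 0 || s >= T) continue;
      const int w = tok[s];
      if (w < 0) continue;
      Mt(t, arma::span(kk * De, kk * De + De - 1)) = emb.row(w);
    }
  return Mt;
}

static void lstm_dir_forward(const Cfg& cfg, const std::vector<mat>& P,
                             const mat& mask, const mat& W, const mat& b,
                             bool forward_dir, DirCache& dc) {
  const int B = (int)P.size(), Tp = (int)P[0].n_rows, H = cfg.H,
            F = (int)P[0].n_cols;
  const mat Wx = W.rows(0, F - 1);         // F x 4H
  const mat Wh = W.rows(F, F + H - 1);     // H x 4H
  cube XP(B, 4 * H, Tp);
  for (int i = 0; i < B; ++i) {
    mat xp = P[i] * Wx;                    // Tp x 4H
    xp.each_row() += b.row(0);
    for (int t = 0; t < Tp; ++t) XP.slice(t).row(i) = xp.row(t);
  }
  dc.Gi.set_size(B, H, Tp); dc.Gf.set_size(B, H, Tp);
  dc.Gg.set_size(B, H, Tp); dc.Go.set_size(B, H, Tp);
  dc.C.set_size(B, H, Tp); dc.Hs.set_size(B, H, Tp);
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (int idx = 0; idx < Tp; ++idx) {
    const int t = forward_dir ? idx : Tp - 1 - idx;
    mat G4 = XP.slice(t) + h * Wh;
    mat gi = sigm(G4.cols(0, H - 1));
    mat gf = sigm(G4.cols(H, 2 * H - 1));
    mat gg = arma::tanh(G4.cols(2 * H, 3 * H - 1));
    mat go = sigm(G4.cols(3 * H, 4 * H - 1));
    mat cn = gf % c + gi % gg;
    mat hn = go % arma::tanh(cn);
    const vec m = mask.col(t);
    const vec im = 1.0 - m;
    mat cmix = cn.each_col() % m;
    cmix += c.each_col() % im;
    c = cmix;
    mat hmix = hn.each_col() % m;
    hmix += h.each_col() % im;
    h = hmix;
    dc.Gi.slice(t) = gi; dc.Gf.slice(t) = gf;
    dc.Gg.slice(t) = gg; dc.Go.slice(t) = go;
    dc.C.slice(t) = c; dc.Hs.slice(t) = h;
  }
}

// Backward through one masked LSTM direction. dH: B x H x Tp gradient w.r.t.
// the (masked) hidden output at each step. Accumulates dW, db; adds input
// gradients into dP.
static void lstm_dir_backward(const Cfg& cfg, const std::vector<mat>& P,
                              const mat& mask, const mat& W,
                              bool forward_dir, const DirCache& dc,
                              const cube& dH, mat& dW, mat& db,
                              std::vector<mat>& dP) {
  const int B = (int)P.size(), Tp = (int)P[0].n_rows, H = cfg.H,
            F = (int)P[0].n_cols;
  const mat Wx = W.rows(0, F - 1);
  const mat Wh = W.rows(F, F + H - 1);
  mat dWx(F, 4 * H, arma::fill::zeros), dWh(H, 4 * H, arma::fill::zeros);
  rowvec dbl(4 * H, arma::fill::zeros);
  cube dXP(B, 4 * H, Tp, arma::fill::zeros);
  mat dh(B, H, arma::fill::zeros), dcc(B, H, arma::fill::zeros);
  for (int idx = Tp - 1; idx >= 0; --idx) {
    const int t = forward_dir ? idx : Tp - 1 - idx;
    const int tprev = forward_dir ? t - 1 : t + 1;
    const bool has_prev = idx > 0;
    const vec m = mask.col(t);
    mat dh_tot = dH.slice(t) + dh;
    const mat& gi = dc.Gi.slice(t); const mat& gf = dc.Gf.slice(t);
    const mat& gg = dc.Gg.slice(t); const mat& go = dc.Go.slice(t);
    const mat& ct = dc.C.slice(t);
    mat c_prev = has_prev ? dc.C.slice(tprev)
                          : mat(B, H, arma::fill::zeros);
    mat th = arma::tanh(ct);
    mat dcn = dh_tot % go % (1.0 - th % th) + dcc;
    mat dgo = dh_tot % th % go % (1.0 - go);
    mat dgi = dcn % gg % gi % (1.0 - gi);
    mat dgf = dcn % c_prev % gf % (1.0 - gf);
    mat dgg = dcn % gi % (1.0 - gg % gg);
    mat dG4 = arma::join_rows(dgi, dgf, dgg, dgo);
    dG4.each_col() %= m;
    dXP.slice(t) = dG4;
    mat h_prev = has_prev ? dc.Hs.slice(tprev)
                          : mat(B, H, arma::fill::zeros);
    dWh += h_prev.t() * dG4;
    dbl += arma::sum(dG4, 0);
    const vec im = 1.0 - m;
    mat dh_new = dG4 * Wh.t();
    dh_new += dh_tot.each_col() % im;
    dh = dh_new;
    mat dcf = dcn % gf;
    mat dcc_new = dcf.each_col() % m;
    dcc_new += dcc.each_col() % im;
    dcc = dcc_new;
  }
  for (int i = 0; i < B; ++i) {
    mat dxp(Tp, 4 * H);
    for (int t = 0; t < Tp; ++t) dxp.row(t) = dXP.slice(t).row(i);
    dWx += P[i].t() * dxp;
    dP[i] += dxp * Wx.t();
  }
  dW.rows(0, F - 1) += dWx;
  dW.rows(F, F + H - 1) += dWh;
  db.row(0) += dbl;
}

// Full per-side encoder forward: tokens -> conv -> pool -> (Bi)LSTM.
// crop_start / crop_len (indexed by sequence row) restrict the encoded
// window; null means the full sequence from position 0
static void side_forward(Params& p, const Cfg& cfg, const IntegerMatrix& X,
                         const IntegerVector& len,
                         const std::vector<int>& rows, bool is_mi,
                         SideCache& sc,
                         const std::vector<int>* crop_start = nullptr,
                         const std::vector<int>* crop_len = nullptr) {
  const int T = is_mi ? cfg.Tmi : cfg.Tm;
  const int Tp = T / cfg.pool;
  const int B = (int)rows.size();
  const std::string side = is_mi ? "mi" : "m";
  const mat& cW = p["conv_" + side + "_W"];
  const mat& cb = p["conv_" + side + "_b"];
  sc.B = B; sc.T = T; sc.Tp = Tp; sc.d = cfg.d();
  sc.Y.resize(B); sc.am.resize(B); sc.P.resize(B);
  sc.mask.set_size(B, Tp); sc.nval.set_size(B);
  sc.tok_start.resize(B); sc.tok_len.resize(B);
  std::vector<int> tok(T);
  for (int b = 0; b < B; ++b) {
    const int r = rows[b];
    const int st = crop_start ? (*crop_start)[r] : 0;
    int L = crop_len ? (*crop_len)[r] : (int)len[r];
    L = std::min(L, T);
    sc.tok_start[b] = st; sc.tok_len[b] = L;
    for (int t = 0; t < T; ++t)
      tok[t] = (t < L && st + t < X.ncol()) ? X(r, st + t) : -1;
    mat Mt = im2col_tokens(p["emb"], tok, T, cfg.kernel, cfg.De);
    mat Y = Mt * cW;
    Y.each_row() += cb.row(0);
    Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    // non-overlapping max-pool along time
    mat Pb(Tp, cfg.F);
    arma::umat am(Tp, cfg.F);
    for (int t = 0; t < Tp; ++t)
      for (int f = 0; f < cfg.F; ++f) {
        int best = t * cfg.pool;
        double bv = Y(best, f);
        for (int u = 1; u < cfg.pool; ++u)
          if (Y(t * cfg.pool + u, f) > bv) {
            best = t * cfg.pool + u; bv = Y(best, f);
          }
        Pb(t, f) = bv; am(t, f) = best;
      }
    sc.Y[b] = std::move(Y); sc.am[b] = std::move(am);
    sc.P[b] = std::move(Pb);
    const int nv = std::min(Tp, L / cfg.pool);
    sc.nval(b) = nv;
    for (int t = 0; t < Tp; ++t) sc.mask(b, t) = t < nv ? 1.0 : 0.0;
  }
  if (cfg.ablation == 3) {  // no LSTM: encoder output is the pooled CNN map
    sc.Hseq.set_size(B, cfg.F, Tp);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tp; ++t)
        sc.Hseq.slice(t).row(b) = sc.P[b].row(t);
    return;
  }
  lstm_dir_forward(cfg, sc.P, sc.mask, p["lstm_" + side + "_fw_W"],
                   p["lstm_" + side + "_fw_b"], true, sc.fw);
  if (cfg.ablation != 2)
    lstm_dir_forward(cfg, sc.P, sc.mask, p["lstm_" + side + "_bw_W"],
                     p["lstm_" + side + "_bw_b"], false, sc.bw);
  const int d = sc.d, H = cfg.H;
  sc.Hseq.set_size(B, d, Tp);
  for (int t = 0; t < Tp; ++t) {
    sc.Hseq.slice(t).cols(0, H - 1) = sc.fw.Hs.slice(t);
    if (cfg.ablation != 2)
      sc.Hseq.slice(t).cols(H, 2 * H - 1) = sc.bw.Hs.slice(t);
  }
}

static void side_backward(Params& p, const Cfg& cfg, const IntegerMatrix& X,
                          const std::vector<int>& rows, bool is_mi,
                          SideCache& sc, const cube& dHseq, Params& g) {
  const int B = sc.B, T = sc.T, Tp = sc.Tp, H = cfg.H;
  const std::string side = is_mi ? "mi" : "m";
  std::vector<mat> dP(B, mat(Tp, cfg.F, arma::fill::zeros));
  if (cfg.ablation == 3) {
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Tp; ++t)
        dP[b].row(t) = dHseq.slice(t).row(b);
  } else {
    cube dfw(B, H, Tp), dbw(B, H, Tp);
    for (int t = 0; t < Tp; ++t) {
      dfw.slice(t) = dHseq.slice(t).cols(0, H - 1);
      if (cfg.ablation != 2)
        dbw.slice(t) = dHseq.slice(t).cols(H, 2 * H - 1);
    }
    lstm_dir_backward(cfg, sc.P, sc.mask, p["lstm_" + side + "_fw_W"], true,
                      sc.fw, dfw, g["lstm_" + side + "_fw_W"],
                      g["lstm_" + side + "_fw_b"], dP);
    if (cfg.ablation != 2)
      lstm_dir_backward(cfg, sc.P, sc.mask, p["lstm_" + side + "_bw_W"],
                        false, sc.bw, dbw, g["lstm_" + side + "_bw_W"],
                        g["lstm_" + side + "_bw_b"], dP);
  }
  const mat& cW = p["conv_" + side + "_W"];
  mat& gcW = g["conv_" + side + "_W"];
  mat& gcb = g["conv_" + side + "_b"];
  mat& gemb = g["emb"];
  const int pad = (cfg.kernel - 1) / 2;
  std::vector<int> tok(T);
  for (int b = 0; b < B; ++b) {
    mat dY(T, cfg.F, arma::fill::zeros);
    for (int t = 0; t < Tp; ++t)
      for (int f = 0; f < cfg.F; ++f)
        dY(sc.am[b](t, f), f) += dP[b](t, f);
    // ReLU gate (stored post-activation)
    dY.elem(arma::find(sc.Y[b] <= 0.0)).zeros();
    const int r = rows[b];
    const int st = sc.tok_start[b], L = sc.tok_len[b];
    for (int t = 0; t < T; ++t)
      tok[t] = (t < L && st + t < X.ncol()) ? X(r, st + t) : -1;
    mat Mt = im2col_tokens(p["emb"], tok, T, cfg.kernel, cfg.De);
    gcW += Mt.t() * dY;
    gcb.row(0) += arma::sum(dY, 0);
    mat dM = dY * cW.t();  // T x kernel*De
    for (int t = 0; t < T; ++t)
      for (int kk = 0; kk < cfg.kernel; ++kk) {
        const int s = t + kk - pad;
        if (s < 0 || s >= T) continue;
        const int w = tok[s];
        if (w < 0) continue;
        gemb.row(w) +=
          dM(t, arma::span(kk * cfg.De, kk * cfg.De + cfg.De - 1));
      }
  }
}

// ------------------------------------------------------------- attention ---

template <typename eT>
struct AttCacheT {
  arma::Mat<eT> Hq, Hkv;              // query-side and key/value-side inputs
  arma::Mat<eT> Q, K, Vv;             // heads packed along columns
  std::vector<arma::Mat<eT>> alpha;   // per head: Tq x Tkv
  arma::Mat<eT> O;                    // Tq x d
};
typedef AttCacheT<float> AttCache;

// Multi-head cross attention: Q from Hq, K/V from Hkv; columns of the score
// matrix beyond nval_kv are masked to -inf before the row softmax.
template <typename eT>
static void attention_forward(const arma::Mat<eT>& Hq,
                              const arma::Mat<eT>& Hkv,
                              const arma::Mat<eT>& Wq,
                              const arma::Mat<eT>& Wk,
                              const arma::Mat<eT>& Wv, int heads,
                              int nval_kv, AttCacheT<eT>& ac) {
  const int d = (int)Wq.n_cols, dk = d / heads;
  const int Tq = (int)Hq.n_rows, Tkv = (int)Hkv.n_rows;
  ac.Hq = Hq; ac.Hkv = Hkv;
  ac.Q = Hq * Wq; ac.K = Hkv * Wk; ac.Vv = Hkv * Wv;
  ac.alpha.assign(heads, arma::Mat<eT>());
  ac.O.set_size(Tq, d);
  const eT scale = (eT)(1.0 / std::sqrt((double)dk));
  for (int h = 0; h < heads; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    arma::Mat<eT> A = ac.Q.cols(cs) * ac.K.cols(cs).t() * scale;
    if (nval_kv < Tkv)
      A.cols(nval_kv, Tkv - 1).fill((eT)-1e30);
    A.each_col() -= arma::max(A, 1);
    arma::Mat<eT> E = arma::exp(A);
    arma::Col<eT> Z = arma::sum(E, 1);
    arma::Mat<eT> al = E.each_col() / Z;
    ac.alpha[h] = al;
    ac.O.cols(cs) = al * ac.Vv.cols(cs);
  }
}

static void attention_backward(const AttCache& ac, const mat& Wq,
                               const mat& Wk, const mat& Wv, int heads,
                               const mat& dO, mat& dHq, mat& dHkv,
                               mat& gWq, mat& gWk, mat& gWv) {
  const int d = (int)Wq.n_cols, dk = d / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dQ(ac.Q.n_rows, d, arma::fill::zeros);
  mat dK(ac.K.n_rows, d, arma::fill::zeros);
  mat dV(ac.Vv.n_rows, d, arma::fill::zeros);
  for (int h = 0; h < heads; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    const mat& al = ac.alpha[h];
    mat dal = dO.cols(cs) * ac.Vv.cols(cs).t();       // Tq x Tkv
    dV.cols(cs) = al.t() * dO.cols(cs);
    vec s = arma::sum(dal % al, 1);
    mat dA = al % (dal.each_col() - s);
    dQ.cols(cs) = dA * ac.K.cols(cs) * scale;
    dK.cols(cs) = dA.t() * ac.Q.cols(cs) * scale;
  }
  gWq += ac.Hq.t() * dQ;
  gWk += ac.Hkv.t() * dK;
  gWv += ac.Hkv.t() * dV;
  dHq += dQ * Wq.t();
  dHkv += dK * Wk.t() + dV * Wv.t();
}

// ---------------------------------------------------------------- fusion ---

struct FuseCache {
  std::vector<mat> a;  // layer inputs: a[0] = (possibly dropped-out) z
  mat drop;            // dropout mask applied to z (empty if none)
};

static vec fusion_forward(Params& p, const Cfg& cfg, const mat& Z,
                          FuseCache& fc, bool training, std::mt19937* rng) {
  const int nl = n_fusion_layers(p);
  mat a = Z;
  if (training && cfg.dropout > 0.0 && rng) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    fc.drop.set_size(a.n_rows, a.n_cols);
    for (arma::uword i = 0; i < a.n_elem; ++i)
      fc.drop(i) = u(*rng) < cfg.dropout ? 0.0 : 1.0 / (1.0 - cfg.dropout);
    a %= fc.drop;
  }
  fc.a.clear();
  for (int l = 1; l <= nl; ++l) {
    fc.a.push_back(a);
    mat z = a * p["fus_W" + std::to_string(l)];
    z.each_row() += p["fus_b" + std::to_string(l)].row(0);
    if (l < nl) {
      z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      a = z;
    } else {
      return arma::vectorise(sigm(z));  // final layer: sigmoid scalar
    }
  }
  stop("fusion network has no layers");
}

// dlogit: gradient w.r.t. the pre-sigmoid output (B). Returns dZ.
static mat fusion_backward(Params& p, const Cfg& cfg, const FuseCache& fc,
                           const vec& dlogit, Params& g) {
  const int nl = n_fusion_layers(p);
  mat da = mat(dlogit);
  for (int l = nl; l >= 1; --l) {
    const mat& a = fc.a[l - 1];
    if (l < nl) {
      // ReLU gate: recompute layer pre-activation sign from next input
      mat z = a * p["fus_W" + std::to_string(l)];
      z.each_row() += p["fus_b" + std::to_string(l)].row(0);
      da.elem(arma::find(z <= 0.0)).zeros();
    }
    g["fus_W" + std::to_string(l)] += a.t() * da;
    g["fus_b" + std::to_string(l)].row(0) += arma::sum(da, 0);
    da = da * p["fus_W" + std::to_string(l)].t();
  }
  if (!fc.drop.is_empty()) da %= fc.drop;
  return da;
}

// ---------------------------------------------------------- full network ---

struct BatchCache {
  SideCache mi, m;
  std::vector<int> loc_mi, loc_m;  // pair -> local slot in the side caches
  std::vector<AttCache> att;    // per pair (mi queries m)
  std::vector<AttCache> att2;   // per pair (m queries mi), bidirectional
  std::vector<arma::uvec> m_amax;  // argmax rows of the mRNA max summary
  mat Z;                        // B x zdim fused input
  FuseCache fc;
  vec scores;
};

// Map each pair in the chunk to a deduplicated list of sequence rows, so a
// sequence shared by many pairs is encoded (and back-propagated through)
// once per batch.
static std::vector<int> dedup_rows(const IntegerVector& idx_of_pair,
                                   const std::vector<int>& rows,
                                   std::vector<int>& loc) {
  std::vector<int> uniq;
  std::unordered_map<int, int> seen;
  loc.resize(rows.size());
  for (size_t b = 0; b < rows.size(); ++b) {
    const int sid = idx_of_pair[rows[b]];
    auto it = seen.find(sid);
    if (it == seen.end()) {
      seen.emplace(sid, (int)uniq.size());
      loc[b] = (int)uniq.size();
      uniq.push_back(sid);
    } else {
      loc[b] = it->second;
    }
  }
  return uniq;
}

static mat sample_matrix(const cube& Hseq, int b) {
  const int d = (int)Hseq.n_cols, Tp = (int)Hseq.n_slices;
  mat H(Tp, d);
  for (int t = 0; t < Tp; ++t) H.row(t) = Hseq.slice(t).row(b);
  return H;
}

static vec masked_mean(const mat& H, int nval) {
  if (nval <= 0) return vec((int)H.n_cols, arma::fill::zeros);
  return arma::mean(H.rows(0, nval - 1), 0).t();
}

// column-wise max over the valid rows, remembering the argmax rows so the
// backward pass can route gradients
static vec masked_max(const mat& H, int nval, arma::uvec& amax) {
  const int d = (int)H.n_cols;
  amax.set_size(d);
  if (nval <= 0) { amax.zeros(); return vec(d, arma::fill::zeros); }
  vec out(d);
  for (int j = 0; j < d; ++j) {
    arma::uword best = 0;
    float bv = H(0, j);
    for (int t = 1; t < nval; ++t)
      if (H(t, j) > bv) { bv = H(t, j); best = t; }
    out(j) = bv; amax(j) = best;
  }
  return out;
}

static void batch_forward(Params& p, const Cfg& cfg, const IntegerMatrix& Xmi,
                          const IntegerMatrix& Xm, const IntegerVector& lmi,
                          const IntegerVector& lm, const IntegerVector& imi,
                          const IntegerVector& im, const NumericMatrix& Nmi,
                          const NumericMatrix& Nm,
                          const std::vector<int>& rows, bool training,
                          std::mt19937* rng, BatchCache& bc,
                          const std::vector<int>* mcrop_start = nullptr,
                          const std::vector<int>* mcrop_len = nullptr) {
  const int B = (int)rows.size(), d = cfg.d(), dn = cfg.dn;
  std::vector<int> umi = dedup_rows(imi, rows, bc.loc_mi);
  std::vector<int> um = dedup_rows(im, rows, bc.loc_m);
  side_forward(p, cfg, Xmi, lmi, umi, true, bc.mi);
  side_forward(p, cfg, Xm, lm, um, false, bc.m, mcrop_start, mcrop_len);
  const bool use_att = cfg.ablation != 1;
  if (use_att) {
    bc.att.assign(B, AttCache());
    if (cfg.bidir) bc.att2.assign(B, AttCache());
  }
  bc.m_amax.assign(B, arma::uvec());
  mat Z(B, cfg.zdim());
  for (int b = 0; b < B; ++b) {
    const int bmi = bc.loc_mi[b], bm = bc.loc_m[b];
    mat Hmi = sample_matrix(bc.mi.Hseq, bmi);
    mat Hm = sample_matrix(bc.m.Hseq, bm);
    vec seq_mi, seq_m;
    if (use_att) {
      attention_forward(Hmi, Hm, p["att_Wq"], p["att_Wk"], p["att_Wv"],
                        cfg.heads, (int)bc.m.nval(bm), bc.att[b]);
      seq_mi = masked_mean(bc.att[b].O, (int)bc.mi.nval(bmi));
      if (cfg.bidir) {
        attention_forward(Hm, Hmi, p["att2_Wq"], p["att2_Wk"], p["att2_Wv"],
                          cfg.heads, (int)bc.mi.nval(bmi), bc.att2[b]);
        seq_m = cfg.m_maxpool
          ? masked_max(bc.att2[b].O, (int)bc.m.nval(bm), bc.m_amax[b])
          : masked_mean(bc.att2[b].O, (int)bc.m.nval(bm));
      } else {
        seq_m = cfg.m_maxpool
          ? masked_max(Hm, (int)bc.m.nval(bm), bc.m_amax[b])
          : masked_mean(Hm, (int)bc.m.nval(bm));
      }
    } else {
      seq_mi = masked_mean(Hmi, (int)bc.mi.nval(bmi));
      seq_m = cfg.m_maxpool
        ? masked_max(Hm, (int)bc.m.nval(bm), bc.m_amax[b])
        : masked_mean(Hm, (int)bc.m.nval(bm));
    }
    vec nmi(dn), nm(dn);
    for (int j = 0; j < dn; ++j) {
      nmi(j) = Nmi(rows[b], j);
      nm(j) = Nm(rows[b], j);
    }
    // node-feature dropout: training-fold positives are, by construction,
    // edges of the embedded graph, so raw node features can shortcut the
    // labels; stochastically hiding the pair's node view forces the
    // sequence pathway to carry the decision too (inverted scaling keeps
    // the test-time expectation unchanged)
    if (training && cfg.node_dropout > 0.0 && rng) {
      std::uniform_real_distribution<double> u01(0.0, 1.0);
      if (u01(*rng) < cfg.node_dropout) {
        nmi.zeros(); nm.zeros();
      } else {
        const float sc = (float)(1.0 / (1.0 - cfg.node_dropout));
        nmi *= sc; nm *= sc;
      }
    }
    if (cfg.fusion == 1 || cfg.fusion == 2) {
      vec z = seq_mi + seq_m + nmi + nm;
      if (cfg.fusion == 2) z /= 4.0;
      Z.row(b) = z.t();
    } else {
      Z.row(b) = arma::join_cols(arma::join_cols(seq_mi, seq_m),
                                 arma::join_cols(nmi, nm)).t();
    }
  }
  bc.Z = Z;
  bc.scores = fusion_forward(p, cfg, Z, bc.fc, training, rng);
}

static void batch_backward(Params& p, const Cfg& cfg,
                           const IntegerMatrix& Xmi, const IntegerMatrix& Xm,
                           const IntegerVector& imi, const IntegerVector& im,
                           const std::vector<int>& rows, const vec& dlogit,
                           BatchCache& bc, Params& g) {
  const int B = (int)rows.size(), d = cfg.d();
  mat dZ = fusion_backward(p, cfg, bc.fc, dlogit, g);
  const bool use_att = cfg.ablation != 1;
  cube dHmi(bc.mi.B, d, bc.mi.Tp, arma::fill::zeros);
  cube dHm(bc.m.B, d, bc.m.Tp, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int bmi = bc.loc_mi[b], bm = bc.loc_m[b];
    vec dseq_mi, dseq_m;
    if (cfg.fusion == 1 || cfg.fusion == 2) {
      vec dz = dZ.row(b).t();
      if (cfg.fusion == 2) dz /= 4.0;
      dseq_mi = dz; dseq_m = dz;
    } else {
      dseq_mi = dZ(b, arma::span(0, d - 1)).t();
      dseq_m = dZ(b, arma::span(d, 2 * d - 1)).t();
    }
    const int nv_mi = (int)bc.mi.nval(bmi), nv_m = (int)bc.m.nval(bm);
    mat dHmi_b(bc.mi.Tp, d, arma::fill::zeros);
    mat dHm_b(bc.m.Tp, d, arma::fill::zeros);
    if (use_att) {
      if (nv_mi > 0) {
        mat dO(bc.att[b].O.n_rows, d, arma::fill::zeros);
        for (int t = 0; t < nv_mi; ++t) dO.row(t) = dseq_mi.t() / nv_mi;
        attention_backward(bc.att[b], p["att_Wq"], p["att_Wk"], p["att_Wv"],
                           cfg.heads, dO, dHmi_b, dHm_b, g["att_Wq"],
                           g["att_Wk"], g["att_Wv"]);
      }
      if (cfg.bidir) {
        if (nv_m > 0) {
          mat dO2(bc.att2[b].O.n_rows, d, arma::fill::zeros);
          if (cfg.m_maxpool) {
            for (int j = 0; j < d; ++j)
              dO2(bc.m_amax[b](j), j) += dseq_m(j);
          } else {
            for (int t = 0; t < nv_m; ++t) dO2.row(t) = dseq_m.t() / nv_m;
          }
          attention_backward(bc.att2[b], p["att2_Wq"], p["att2_Wk"],
                             p["att2_Wv"], cfg.heads, dO2, dHm_b, dHmi_b,
                             g["att2_Wq"], g["att2_Wk"], g["att2_Wv"]);
        }
      } else if (nv_m > 0) {
        if (cfg.m_maxpool) {
          for (int j = 0; j < d; ++j)
            dHm_b(bc.m_amax[b](j), j) += dseq_m(j);
        } else {
          for (int t = 0; t < nv_m; ++t) dHm_b.row(t) += dseq_m.t() / nv_m;
        }
      }
    } else {
      if (nv_mi > 0)
        for (int t = 0; t < nv_mi; ++t) dHmi_b.row(t) += dseq_mi.t() / nv_mi;
      if (nv_m > 0) {
        if (cfg.m_maxpool) {
          for (int j = 0; j < d; ++j)
            dHm_b(bc.m_amax[b](j), j) += dseq_m(j);
        } else {
          for (int t = 0; t < nv_m; ++t) dHm_b.row(t) += dseq_m.t() / nv_m;
        }
      }
    }
    for (int t = 0; t < bc.mi.Tp; ++t)
      dHmi.slice(t).row(bmi) += dHmi_b.row(t);
    for (int t = 0; t < bc.m.Tp; ++t)
      dHm.slice(t).row(bm) += dHm_b.row(t);
  }
  std::vector<int> umi = dedup_rows(imi, rows, bc.loc_mi);
  std::vector<int> um = dedup_rows(im, rows, bc.loc_m);
  side_backward(p, cfg, Xmi, umi, true, bc.mi, dHmi, g);
  side_backward(p, cfg, Xm, um, false, bc.m, dHm, g);
}

// ----------------------------------------------------------------- adam ----

struct Adam {
  std::vector<mat> m, v;
  long t = 0;
  void init(const Params& p) {
    m.resize(p.M.size()); v.resize(p.M.size());
    for (size_t i = 0; i < p.M.size(); ++i) {
      m[i] = mat(p.M[i].n_rows, p.M[i].n_cols, arma::fill::zeros);
      v[i] = m[i];
    }
  }
  void step(Params& p, const Params& g, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < p.M.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * g.M[i];
      v[i] = b2 * v[i] + (1.0 - b2) * (g.M[i] % g.M[i]);
      p.M[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// ------------------------------------------------------------- exports -----

static std::vector<int> to_rows(const IntegerVector& r) {
  return std::vector<int>(r.begin(), r.end());
}

// [[Rcpp::export]]
NumericVector cpp_nn_forward(List params, List cfgL, IntegerMatrix Xmi,
                             IntegerMatrix Xm, IntegerVector lmi,
                             IntegerVector lm, IntegerVector imi,
                             IntegerVector im, NumericMatrix Nmi,
                             NumericMatrix Nm, IntegerVector rows) {
  Cfg cfg = cfg_from_list(cfgL);
  Params p = params_from_list(params);
  std::vector<int> rws = to_rows(rows);
  // score in mRNA-sorted chunks: shared sequences are encoded once per chunk
  std::stable_sort(rws.begin(), rws.end(),
                   [&](int a, int b) { return im[a] < im[b]; });
  NumericVector out(rows.size());
  std::unordered_map<int, int> orig;
  for (int i = 0; i < rows.size(); ++i) orig[rows[i]] = i;
  const size_t CH = 512;
  for (size_t off = 0; off < rws.size(); off += CH) {
    std::vector<int> chunk(
      rws.begin() + off,
      rws.begin() + std::min(rws.size(), off + CH));
    BatchCache bc;
    batch_forward(p, cfg, Xmi, Xm, lmi, lm, imi, im, Nmi, Nm, chunk, false,
                  nullptr, bc);
    for (size_t i = 0; i < chunk.size(); ++i)
      out[orig[chunk[i]]] = bc.scores(i);
  }
  return out;
}

static double bce(const vec& s, const vec& y) {
  const double e = 1e-12;
  return arma::mean(-y % arma::log(s + e) -
                    (1.0 - y) % arma::log(1.0 - s + e));
}

// [[Rcpp::export]]
List cpp_nn_train(List params, List cfgL, IntegerMatrix Xmi, IntegerMatrix Xm,
                  IntegerVector lmi, IntegerVector lm, IntegerVector imi,
                  IntegerVector im, NumericMatrix Nmi,
                  NumericMatrix Nm, NumericVector y, IntegerVector train_rows,
                  IntegerVector val_rows, int seed, bool verbose) {
  Cfg cfg = cfg_from_list(cfgL);
  Params p = params_from_list(params);
  Adam opt; opt.init(p);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> tr = to_rows(train_rows), va = to_rows(val_rows);
  NumericMatrix history(cfg.epochs, 2);
  Params best = p;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0;
  int n_m_unique = 0;
  for (int i = 0; i < im.size(); ++i) n_m_unique = std::max(n_m_unique,
                                                            im[i] + 1);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  for (int ep = 0; ep < cfg.epochs; ++ep) {
    // random-crop augmentation of the mRNA windows: transcript-identity
    // features become unstable across epochs while local binding-site
    // content survives, which discourages pair memorization
    std::vector<int> cst, cln;
    const bool crop = cfg.crop_min < 1.0;
    if (crop) {
      cst.resize(Xm.nrow()); cln.resize(Xm.nrow());
      for (int r = 0; r < Xm.nrow(); ++r) {
        const int L = lm[r];
        const double frac = cfg.crop_min + (1.0 - cfg.crop_min) * u01(rng);
        int Lc = std::max(cfg.pool, (int)std::lround(L * frac));
        Lc = std::min(Lc, L);
        cst[r] = (L > Lc) ? (int)(u01(rng) * (L - Lc + 1)) : 0;
        cln[r] = Lc;
      }
    }
    // shuffle pairs, then group by mRNA (in randomized mRNA order) so each
    // minibatch encodes every distinct mRNA once
    std::shuffle(tr.begin(), tr.end(), rng);
    std::vector<int> rank(n_m_unique);
    for (int i = 0; i < n_m_unique; ++i) rank[i] = i;
    std::shuffle(rank.begin(), rank.end(), rng);
    std::stable_sort(tr.begin(), tr.end(),
                     [&](int a, int b) { return rank[im[a]] < rank[im[b]]; });
    double tot = 0.0; long nseen = 0;
    for (size_t off = 0; off < tr.size(); off += cfg.batch) {
      std::vector<int> chunk(
        tr.begin() + off,
        tr.begin() + std::min(tr.size(), off + (size_t)cfg.batch));
      const int B = (int)chunk.size();
      BatchCache bc;
      batch_forward(p, cfg, Xmi, Xm, lmi, lm, imi, im, Nmi, Nm, chunk, true,
                    &rng, bc, crop ? &cst : nullptr, crop ? &cln : nullptr);
      vec yy(B);
      for (int i = 0; i < B; ++i) yy(i) = y[chunk[i]];
      tot += bce(bc.scores, yy) * B;
      nseen += B;
      vec dlogit = (bc.scores - yy) / B;
      Params g = p.zeros_like();
      batch_backward(p, cfg, Xmi, Xm, imi, im, chunk, dlogit, bc, g);
      opt.step(p, g, cfg.lr);
    }
    history(ep, 0) = tot / nseen;
    double vloss = NA_REAL;
    if (!va.empty()) {
      double vt = 0.0; long vn = 0;
      for (size_t off = 0; off < va.size(); off += 512) {
        std::vector<int> chunk(
          va.begin() + off, va.begin() + std::min(va.size(), off + 512));
        BatchCache bc;
        batch_forward(p, cfg, Xmi, Xm, lmi, lm, imi, im, Nmi, Nm, chunk,
                      false, nullptr, bc);
        vec yy(chunk.size());
        for (size_t i = 0; i < chunk.size(); ++i) yy(i) = y[chunk[i]];
        vt += bce(bc.scores, yy) * chunk.size();
        vn += chunk.size();
      }
      vloss = vt / vn;
      if (vloss < best_val) {
        best_val = vloss; best = p; best_epoch = ep + 1;
      }
    }
    history(ep, 1) = vloss;
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " train " << history(ep, 0)
                  << " val " << vloss << "\n";
    Rcpp::checkUserInterrupt();
  }
  if (va.empty()) { best = p; best_epoch = cfg.epochs; }
  return List::create(_["params"] = params_to_list(best),
                      _["history"] = history,
                      _["best_epoch"] = best_epoch);
}

// Encoder output for a set of sequences on one side (list of Tp x d
// matrices plus valid pooled lengths).
// [[Rcpp::export]]
List cpp_nn_encode(List params, List cfgL, IntegerMatrix X, IntegerVector len,
                   bool is_mi) {
  Cfg cfg = cfg_from_list(cfgL);
  Params p = params_from_list(params);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  SideCache sc;
  side_forward(p, cfg, X, len, rows, is_mi, sc);
  List H(sc.B);
  IntegerVector nv(sc.B);
  for (int b = 0; b < sc.B; ++b) {
    H[b] = sample_matrix(sc.Hseq, b);
    nv[b] = (int)sc.nval(b);
  }
  return List::create(_["H"] = H, _["n_valid"] = nv);
}

// Standalone mutual attention (all key/value rows valid unless nval_kv
// says otherwise). Returns the concatenated head output and each head's
// attention weight matrix.
// [[Rcpp::export]]
List cpp_attention(arma::mat Hq, arma::mat Hkv, arma::mat Wq, arma::mat Wk,
                   arma::mat Wv, int heads, int nval_kv) {
  AttCacheT<double> ac;
  attention_forward<double>(Hq, Hkv, Wq, Wk, Wv, heads, nval_kv, ac);
  List al(heads);
  for (int h = 0; h < heads; ++h) al[h] = ac.alpha[h];
  return List::create(_["O"] = ac.O, _["alpha"] = al);
}

// Fusion head forward on explicit feature vectors (no dropout).
// [[Rcpp::export]]
NumericVector cpp_fusion(List params, List cfgL, arma::mat Z) {
  Cfg cfg = cfg_from_list(cfgL);
  Params p = params_from_list(params);
  FuseCache fc;
  mat Zf = arma::conv_to<mat>::from(Z);
  vec s = fusion_forward(p, cfg, Zf, fc, false, nullptr);
  return wrap(arma::conv_to<arma::vec>::from(s));
}

// Mean loss and parameter gradients on one batch (for gradient checking).
// [[Rcpp::export]]
List cpp_nn_loss_grad(List params, List cfgL, IntegerMatrix Xmi,
                      IntegerMatrix Xm, IntegerVector lmi, IntegerVector lm,
                      IntegerVector imi, IntegerVector im,
                      NumericMatrix Nmi, NumericMatrix Nm, NumericVector y,
                      IntegerVector rows) {
  Cfg cfg = cfg_from_list(cfgL);
  Params p = params_from_list(params);
  std::vector<int> rws = to_rows(rows);
  BatchCache bc;
  batch_forward(p, cfg, Xmi, Xm, lmi, lm, imi, im, Nmi, Nm, rws, false,
                nullptr, bc);
  vec yy(rws.size());
  for (size_t i = 0; i < rws.size(); ++i) yy(i) = y[rws[i]];
  double loss = bce(bc.scores, yy);
  vec dlogit = (bc.scores - yy) / (double)rws.size();
  Params g = p.zeros_like();
  batch_backward(p, cfg, Xmi, Xm, imi, im, rws, dlogit, bc, g);
  return List::create(_["loss"] = loss, _["grad"] = params_to_list(g));
}
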
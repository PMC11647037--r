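// Training core of the minimal causal-masked encoder-decoder transformer:
// forward pass, analytic backpropagation, and AdamW minibatch loop.
// Mirrors the R forward() exactly (post-norm residual blocks, ReLU FFN,
// layer-norm eps 1e-5); the R side cross-checks losses and gradients.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

struct AttnP { mat Wq, Wk, Wv, Wo; rowvec bq, bk, bv, bo; };
struct LNP   { rowvec g, b; };
struct FFNP  { mat W1, W2; rowvec b1, b2; };

struct Params {
  AttnP enc_att, dec_att, x_att;
  LNP enc_ln1, enc_ln2, dec_ln1, dec_ln2, dec_ln3;
  FFNP enc_ffn, dec_ffn;
  vec head_w;
  double head_b;
};

// Enumerate parameter tensors as flat vectors in a fixed canonical order,
// matching the R-side parameter list.
static void collect(Params& p, std::vector<mat*>& Ms, std::vector<rowvec*>& Vs,
                    std::vector<int>& kind) {
  // kind: 0 = mat (in Ms), 1 = rowvec (in Vs); order mirrors the R list
  auto attn = [&](AttnP& a) {
    Ms.push_back(&a.Wq); kind.push_back(0); Vs.push_back(&a.bq); kind.push_back(1);
    Ms.push_back(&a.Wk); kind.push_back(0); Vs.push_back(&a.bk); kind.push_back(1);
    Ms.push_back(&a.Wv); kind.push_back(0); Vs.push_back(&a.bv); kind.push_back(1);
    Ms.push_back(&a.Wo); kind.push_back(0); Vs.push_back(&a.bo); kind.push_back(1);
  };
  auto ln = [&](LNP& l) {
    Vs.push_back(&l.g); kind.push_back(1); Vs.push_back(&l.b); kind.push_back(1);
  };
  auto ffn = [&](FFNP& f) {
    Ms.push_back(&f.W1); kind.push_back(0); Vs.push_back(&f.b1); kind.push_back(1);
    Ms.push_back(&f.W2); kind.push_back(0); Vs.push_back(&f.b2); kind.push_back(1);
  };
  attn(p.enc_att); ln(p.enc_ln1); ffn(p.enc_ffn); ln(p.enc_ln2);
  attn(p.dec_att); ln(p.dec_ln1);
  attn(p.x_att);   ln(p.dec_ln2);
  ffn(p.dec_ffn);  ln(p.dec_ln3);
}

static const char* PARAM_NAMES[] = {
  "enc_Wq","enc_bq","enc_Wk","enc_bk","enc_Wv","enc_bv","enc_Wo","enc_bo",
  "enc_ln1_g","enc_ln1_b","enc_W1","enc_b1","enc_W2","enc_b2",
  "enc_ln2_g","enc_ln2_b",
  "dec_Wq","dec_bq","dec_Wk","dec_bk","dec_Wv","dec_bv","dec_Wo","dec_bo",
  "dec_ln1_g","dec_ln1_b",
  "x_Wq","x_bq","x_Wk","x_bk","x_Wv","x_bv","x_Wo","x_bo",
  "dec_ln2_g","dec_ln2_b",
  "dec_W1","dec_b1","dec_W2","dec_b2","dec_ln3_g","dec_ln3_b",
  "head_w","head_b"
};

static Params params_from_list(const Rcpp::List& lst) {
  Params p;
  auto getM = [&](const char* nm) { return Rcpp::as<mat>(lst[nm]); };
  auto getV = [&](const char* nm) { return Rcpp::as<rowvec>(lst[nm]); };
  auto attn = [&](AttnP& a, const std::string& pre) {
    a.Wq = getM((pre + "Wq").c_str()); a.bq = getV((pre + "bq").c_str());
    a.Wk = getM((pre + "Wk").c_str()); a.bk = getV((pre + "bk").c_str());
    a.Wv = getM((pre + "Wv").c_str()); a.bv = getV((pre + "bv").c_str());
    a.Wo = getM((pre + "Wo").c_str()); a.bo = getV((pre + "bo").c_str());
  };
  auto lnp = [&](LNP& l, const std::string& nm) {
    l.g = getV((nm + "_g").c_str()); l.b = getV((nm + "_b").c_str());
  };
  auto ffn = [&](FFNP& f, const std::string& pre) {
    f.W1 = getM((pre + "W1").c_str()); f.b1 = getV((pre + "b1").c_str());
    f.W2 = getM((pre + "W2").c_str()); f.b2 = getV((pre + "b2").c_str());
  };
  attn(p.enc_att, "enc_"); lnp(p.enc_ln1, "enc_ln1");
  ffn(p.enc_ffn, "enc_");  lnp(p.enc_ln2, "enc_ln2");
  attn(p.dec_att, "dec_"); lnp(p.dec_ln1, "dec_ln1");
  attn(p.x_att, "x_");     lnp(p.dec_ln2, "dec_ln2");
  ffn(p.dec_ffn, "dec_");  lnp(p.dec_ln3, "dec_ln3");
  p.head_w = Rcpp::as<vec>(lst["head_w"]);
  p.head_b = Rcpp::as<double>(lst["head_b"]);
  return p;
}

static Rcpp::List params_to_list(Params& p) {
  std::vector<mat*> Ms; std::vector<rowvec*> Vs; std::vector<int> kind;
  collect(p, Ms, Vs, kind);
  Rcpp::List out;
  size_t mi = 0, vi = 0, ni = 0;
  for (int k : kind) {
    if (k == 0) out[PARAM_NAMES[ni++]] = Rcpp::wrap(*Ms[mi++]);
    else out[PARAM_NAMES[ni++]] = Rcpp::wrap(conv_to<std::vector<double>>::from(*Vs[vi++]));
  }
  out["head_w"] = Rcpp::wrap(p.head_w);
  out["head_b"] = p.head_b;
  return out;
}

static Params zeros_like(const Params& p) {
  Params g = p;
  std::vector<mat*> Ms; std::vector<rowvec*> Vs; std::vector<int> kind;
  collect(g, Ms, Vs, kind);
  for (auto* m : Ms) m->zeros();
  for (auto* v : Vs) v->zeros();
  g.head_w.zeros();
  g.head_b = 0.0;
  return g;
}

// ---- forward/backward primitives -----------------------------------------

struct AttnCache { mat Q, K, V, P, C; };
struct LNCache   { mat xin, xhat; vec inv; };
struct FFNCache  { mat xin, H; };  // H = pre-activation

static mat attn_fwd(const mat& Xq, const mat& Xkv, const AttnP& a,
                    bool causal, AttnCache& c) {
  c.Q = Xq * a.Wq; c.Q.each_row() += a.bq;
  c.K = Xkv * a.Wk; c.K.each_row() += a.bk;
  c.V = Xkv * a.Wv; c.V.each_row() += a.bv;
  const double s = std::sqrt((double)c.K.n_cols);
  mat S = c.Q * c.K.t() / s;
  const uword n = S.n_rows, m = S.n_cols;
  c.P.zeros(n, m);
  for (uword i = 0; i < n; ++i) {
    uword lim = causal ? std::min<uword>(i + 1, m) : m;
    if (lim == 0) continue;
    rowvec row = S.row(i).head(lim);
    double mx = row.max();
    rowvec e = exp(row - mx);
    c.P.row(i).head(lim) = e / accu(e);
  }
  c.C = c.P * c.V;
  mat O = c.C * a.Wo; O.each_row() += a.bo;
  return O;
}

static void attn_bwd(const mat& dO, const mat& Xq, const mat& Xkv,
                     const AttnP& a, const AttnCache& c,
                     AttnP& g, mat& dXq, mat& dXkv) {
  const double s = std::sqrt((double)c.K.n_cols);
  g.Wo += c.C.t() * dO; g.bo += sum(dO, 0);
  mat dC = dO * a.Wo.t();
  mat dP = dC * c.V.t();
  mat dV = c.P.t() * dC;
  mat dS(size(dP));
  for (uword i = 0; i < dP.n_rows; ++i) {
    rowvec p = c.P.row(i);
    rowvec dp = dP.row(i);
    dS.row(i) = p % (dp - dot(dp, p));
  }
  mat dQ = dS * c.K / s;
  mat dK = dS.t() * c.Q / s;
  g.Wq += Xq.t() * dQ;  g.bq += sum(dQ, 0);
  g.Wk += Xkv.t() * dK; g.bk += sum(dK, 0);
  g.Wv += Xkv.t() * dV; g.bv += sum(dV, 0);
  dXq  += dQ * a.Wq.t();
  dXkv += dK * a.Wk.t() + dV * a.Wv.t();
}

static mat ln_fwd(const mat& X, const LNP& l, LNCache& c) {
  c.xin = X;
  vec mu = mean(X, 1);
  vec va = mean(square(X.each_col() - mu), 1);
  c.inv = 1.0 / sqrt(va + LN_EPS);
  c.xhat = (X.each_col() - mu).each_col() % c.inv;
  mat Y = c.xhat; Y.each_row() %= l.g; Y.each_row() += l.b;
  return Y;
}

static mat ln_bwd(const mat& dY, const LNP& l, const LNCache& c, LNP& g) {
  g.g += sum(dY % c.xhat, 0);
  g.b += sum(dY, 0);
  mat dxh = dY; dxh.each_row() %= l.g;
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % c.xhat, 1);
  mat dX = (dxh.each_col() - m1) - (c.xhat.each_col() % m2);
  dX.each_col() %= c.inv;
  return dX;
}

static mat relu(const mat& X) {
  mat R = X;
  R.elem(find(R < 0)).zeros();
  return R;
}

static mat ffn_fwd(const mat& X, const FFNP& f, FFNCache& c) {
  c.xin = X;
  c.H = X * f.W1; c.H.each_row() += f.b1;
  mat R = relu(c.H);
  mat Y = R * f.W2; Y.each_row() += f.b2;
  return Y;
}

static mat ffn_bwd(const mat& dY, const FFNP& f, const FFNCache& c, FFNP& g) {
  mat R = relu(c.H);
  g.W2 += R.t() * dY; g.b2 += sum(dY, 0);
  mat dR = dY * f.W2.t();
  mat dH = dR % conv_to<mat>::from(c.H > 0);
  g.W1 += c.xin.t() * dH; g.b1 += sum(dH, 0);
  return dH * f.W1.t();
}

// Full forward + (optionally) backward for one sample; gradients accumulate
// into g. Returns the masked L2 loss; predictions optionally exported.
static double sample_pass(const Params& p, const mat& Xr, const mat& Xd,
                          const vec& y, const uvec& msk, bool causal,
                          Params* g, vec* pred_out) {
  AttnCache ca1, ca2, ca3;
  LNCache cl1, cl2, cl3, cl4, cl5;
  FFNCache cf1, cf2;

  mat O1 = attn_fwd(Xr, Xr, p.enc_att, causal, ca1);
  mat H1 = ln_fwd(Xr + O1, p.enc_ln1, cl1);
  mat F1 = ffn_fwd(H1, p.enc_ffn, cf1);
  mat E  = ln_fwd(H1 + F1, p.enc_ln2, cl2);

  mat O2 = attn_fwd(Xd, Xd, p.dec_att, causal, ca2);
  mat H2 = ln_fwd(Xd + O2, p.dec_ln1, cl3);
  mat O3 = attn_fwd(H2, E, p.x_att, causal, ca3);
  mat H3 = ln_fwd(H2 + O3, p.dec_ln2, cl4);
  mat F2 = ffn_fwd(H3, p.dec_ffn, cf2);
  mat H4 = ln_fwd(H3 + F2, p.dec_ln3, cl5);

  vec pred = H4 * p.head_w + p.head_b;
  if (pred_out) *pred_out = pred;

  uvec mi = find(msk);
  if (mi.n_elem == 0) return 0.0;
  vec r = pred.elem(mi) - y.elem(mi);
  double loss = dot(r, r) / mi.n_elem;
  if (!g) return loss;

  vec dpred(pred.n_elem, fill::zeros);
  dpred.elem(mi) = 2.0 * r / (double)mi.n_elem;

  g->head_w += H4.t() * dpred;
  g->head_b += accu(dpred);
  mat dH4 = dpred * p.head_w.t();

  mat dA5 = ln_bwd(dH4, p.dec_ln3, cl5, g->dec_ln3);
  mat dH3 = dA5;
  dH3 += ffn_bwd(dA5, p.dec_ffn, cf2, g->dec_ffn);

  mat dA4 = ln_bwd(dH3, p.dec_ln2, cl4, g->dec_ln2);
  mat dH2 = dA4;
  mat dE(size(E), fill::zeros);
  attn_bwd(dA4, H2, E, p.x_att, ca3, g->x_att, dH2, dE);

  mat dA3 = ln_bwd(dH2, p.dec_ln1, cl3, g->dec_ln1);
  mat dXd = dA3;  // residual path; input grads unused
  attn_bwd(dA3, Xd, Xd, p.dec_att, ca2, g->dec_att, dXd, dXd);

  mat dA2 = ln_bwd(dE, p.enc_ln2, cl2, g->enc_ln2);
  mat dH1 = dA2;
  dH1 += ffn_bwd(dA2, p.enc_ffn, cf1, g->enc_ffn);

  mat dA1 = ln_bwd(dH1, p.enc_ln1, cl1, g->enc_ln1);
  mat dXr = dA1;
  attn_bwd(dA1, Xr, Xr, p.enc_att, ca1, g->enc_att, dXr, dXr);

  return loss;
}

// ---- AdamW ----------------------------------------------------------------

struct Adam {
  Params m, v;
  double b1, b2, eps, lr, wd;
  long t = 0;
  Adam(const Params& p, double lr_, double wd_, double b1_, double b2_, double eps_)
    : m(zeros_like(const_cast<Params&>(p))), v(zeros_like(const_cast<Params&>(p))),
      b1(b1_), b2(b2_), eps(eps_), lr(lr_), wd(wd_) {}

  void step(Params& p, Params& g) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    std::vector<mat*> pM, gM, mM, vM;
    std::vector<rowvec*> pV, gV, mV, vV;
    std::vector<int> kind;
    collect(p, pM, pV, kind);
    { std::vector<int> k2; collect(g, gM, gV, k2); }
    { std::vector<int> k2; collect(m, mM, mV, k2); }
    { std::vector<int> k2; collect(v, vM, vV, k2); }
    for (size_t i = 0; i < pM.size(); ++i) {
      *mM[i] = b1 * (*mM[i]) + (1 - b1) * (*gM[i]);
      *vM[i] = b2 * (*vM[i]) + (1 - b2) * square(*gM[i]);
      *pM[i] -= lr * ((*mM[i] / c1) / (sqrt(*vM[i] / c2) + eps) + wd * (*pM[i]));
    }
    for (size_t i = 0; i < pV.size(); ++i) {
      *mV[i] = b1 * (*mV[i]) + (1 - b1) * (*gV[i]);
      *vV[i] = b2 * (*vV[i]) + (1 - b2) * square(*gV[i]);
      *pV[i] -= lr * ((*mV[i] / c1) / (sqrt(*vV[i] / c2) + eps) + wd * (*pV[i]));
    }
    m.head_w = b1 * m.head_w + (1 - b1) * g.head_w;
    v.head_w = b2 * v.head_w + (1 - b2) * square(g.head_w);
    p.head_w -= lr * ((m.head_w / c1) / (sqrt(v.head_w / c2) + eps) + wd * p.head_w);
    m.head_b = b1 * m.head_b + (1 - b1) * g.head_b;
    v.head_b = b2 * v.head_b + (1 - b2) * g.head_b * g.head_b;
    p.head_b -= lr * ((m.head_b / c1) / (std::sqrt(v.head_b / c2) + eps) + wd * p.head_b);
  }
};

static void scale_grads(Params& g, double s) {
  std::vector<mat*> Ms; std::vector<rowvec*> Vs; std::vector<int> kind;
  collect(g, Ms, Vs, kind);
  for (auto* m : Ms) (*m) *= s;
  for (auto* v : Vs) (*v) *= s;
  g.head_w *= s;
  g.head_b *= s;
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
Rcpp::List tf_loss_grad(Rcpp::List params, arma::mat rad, arma::mat drug,
                        arma::vec target, arma::uvec mask, bool causal = true) {
  Params p = params_from_list(params);
  Params g = zeros_like(p);
  double loss = sample_pass(p, rad, drug, target, mask, causal, &g, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(g));
}

// [[Rcpp::export]]
Rcpp::List tf_eval(Rcpp::List params, arma::cube rad, arma::cube drug,
                   arma::mat targets, arma::umat mask, bool causal = true) {
  Params p = params_from_list(params);
  const uword n = rad.n_slices;
  vec losses(n);
  mat preds(targets.n_rows, n);
  for (uword i = 0; i < n; ++i) {
    vec pr;
    losses(i) = sample_pass(p, rad.slice(i), drug.slice(i), targets.col(i),
                            conv_to<uvec>::from(mask.col(i)), causal, nullptr, &pr);
    preds.col(i) = pr;
  }
  return Rcpp::List::create(Rcpp::Named("losses") = losses,
                            Rcpp::Named("predictions") = preds);
}

// [[Rcpp::export]]
Rcpp::List tf_train(Rcpp::List params,
                    arma::cube rad, arma::cube drug,
                    arma::mat targets, arma::umat mask,
                    arma::cube rad_val, arma::cube drug_val,
                    arma::mat targets_val, arma::umat mask_val,
                    int epochs, int batch_size,
                    double lr, double weight_decay,
                    double beta1, double beta2, double epsilon,
                    bool causal, int seed) {
  Params p = params_from_list(params);
  const uword n = rad.n_slices;
  if (n == 0) Rcpp::stop("empty training set");
  const uword nval = rad_val.n_slices;
  bool any_mask = accu(mask) > 0;
  if (!any_mask) Rcpp::stop("empty mask across the whole training set");

  Adam opt(p, lr, weight_decay, beta1, beta2, epsilon);
  std::mt19937 rng(seed);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  vec train_hist(std::max(epochs, 0), fill::zeros);
  vec val_hist(std::max(epochs, 0), fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    uword done = 0;
    while (done < n) {
      uword bs = std::min<uword>(batch_size, n - done);
      Params g = zeros_like(p);
      double batch_loss = 0.0;
      for (uword k = 0; k < bs; ++k) {
        uword i = idx[done + k];
        batch_loss += sample_pass(p, rad.slice(i), drug.slice(i),
                                  targets.col(i),
                                  conv_to<uvec>::from(mask.col(i)),
                                  causal, &g, nullptr);
      }
      scale_grads(g, 1.0 / bs);
      opt.step(p, g);
      ep_loss += batch_loss;
      done += bs;
    }
    train_hist(ep) = ep_loss / n;
    if (nval > 0) {
      double vl = 0.0;
      for (uword i = 0; i < nval; ++i) {
        vl += sample_pass(p, rad_val.slice(i), drug_val.slice(i),
                          targets_val.col(i),
                          conv_to<uvec>::from(mask_val.col(i)),
                          causal, nullptr, nullptr);
      }
      val_hist(ep) = vl / nval;
    } else {
      val_hist(ep) = datum::nan;
    }
    if (ep % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p),
                            Rcpp::Named("train_loss") = train_hist,
                            Rcpp::Named("val_loss") = val_hist);
}
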
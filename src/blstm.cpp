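// Framewise breathing-boundary detector: two bidirectional LSTM layers, two
// fully-connected layers, softmax over {no boundary, boundary}. Trained by
// full backpropagation-through-time with Adam, one clip per step, weighted
// cross-entropy. All randomness (initial weights, clip order, channel
// permutations) is supplied by the caller so training is bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmDir {            // one direction of one BLSTM layer
  mat W, U;                 // 4H x Din, 4H x H (gate order: i, f, g, o)
  vec b;                    // 4H
};

struct LstmCache {
  mat X;                    // input Din x T
  mat I, F, G, O, C, H;     // gate activations / cell / hidden, H x T
};

// forward one direction; reverse = scan right-to-left (output aligned to t)
static mat lstm_forward(const LstmDir& p, const mat& X, bool reverse,
                        LstmCache* cache) {
  const int T = X.n_cols, H = p.U.n_cols;
  mat I(H, T), F(H, T), G(H, T), O(H, T), C(H, T), Hs(H, T);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  mat Zx = p.W * X;                       // input projections, all timesteps
  Zx.each_col() += p.b;
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    vec z = Zx.col(t) + p.U * h;
    vec gi = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
    vec gf = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
    vec gg = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    vec go = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    I.col(t) = gi; F.col(t) = gf; G.col(t) = gg; O.col(t) = go;
    C.col(t) = c; Hs.col(t) = h;
  }
  if (cache) { cache->X = X; cache->I = I; cache->F = F; cache->G = G;
               cache->O = O; cache->C = C; cache->H = Hs; }
  return Hs;
}

// backward through one direction; returns dX, accumulates parameter grads
static mat lstm_backward(const LstmDir& p, const LstmCache& cc, const mat& dH,
                         bool reverse, mat& dW, mat& dU, vec& db) {
  const int T = cc.X.n_cols, H = p.U.n_cols;
  mat dX(cc.X.n_rows, T, arma::fill::zeros);
  vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    int tp = reverse ? t + 1 : t - 1;     // previous step in scan order
    vec c_prev = (s == 0) ? vec(H, arma::fill::zeros) : vec(cc.C.col(tp));
    vec h_prev = (s == 0) ? vec(H, arma::fill::zeros) : vec(cc.H.col(tp));
    vec tc = arma::tanh(cc.C.col(t));
    vec dh = dH.col(t) + dh_next;
    vec dc = dc_next + dh % cc.O.col(t) % (1.0 - tc % tc);
    vec da(4 * H);
    vec go = cc.O.col(t), gi = cc.I.col(t), gf = cc.F.col(t), gg = cc.G.col(t);
    da.subvec(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    da.subvec(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    da.subvec(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    da.subvec(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
    dW += da * cc.X.col(t).t();
    dU += da * h_prev.t();
    db += da;
    dX.col(t) = p.W.t() * da;
    dh_next = p.U.t() * da;
    dc_next = dc % gf;
  }
  return dX;
}

struct Net {
  LstmDir l1f, l1b, l2f, l2b;
  mat fc1_W, fc2_W;
  vec fc1_b, fc2_b;
};

static Net net_from_list(const List& w) {
  Net n;
  n.l1f = { as<mat>(w["l1f_W"]), as<mat>(w["l1f_U"]), as<vec>(w["l1f_b"]) };
  n.l1b = { as<mat>(w["l1b_W"]), as<mat>(w["l1b_U"]), as<vec>(w["l1b_b"]) };
  n.l2f = { as<mat>(w["l2f_W"]), as<mat>(w["l2f_U"]), as<vec>(w["l2f_b"]) };
  n.l2b = { as<mat>(w["l2b_W"]), as<mat>(w["l2b_U"]), as<vec>(w["l2b_b"]) };
  n.fc1_W = as<mat>(w["fc1_W"]); n.fc1_b = as<vec>(w["fc1_b"]);
  n.fc2_W = as<mat>(w["fc2_W"]); n.fc2_b = as<vec>(w["fc2_b"]);
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(
    _["l1f_W"] = n.l1f.W, _["l1f_U"] = n.l1f.U, _["l1f_b"] = n.l1f.b,
    _["l1b_W"] = n.l1b.W, _["l1b_U"] = n.l1b.U, _["l1b_b"] = n.l1b.b,
    _["l2f_W"] = n.l2f.W, _["l2f_U"] = n.l2f.U, _["l2f_b"] = n.l2f.b,
    _["l2b_W"] = n.l2b.W, _["l2b_U"] = n.l2b.U, _["l2b_b"] = n.l2b.b,
    _["fc1_W"] = n.fc1_W, _["fc1_b"] = n.fc1_b,
    _["fc2_W"] = n.fc2_W, _["fc2_b"] = n.fc2_b);
}

// full forward pass; returns softmax class-1 probabilities (length T)
static arma::rowvec net_forward(const Net& n, const mat& X,
                                LstmCache* c1f, LstmCache* c1b,
                                LstmCache* c2f, LstmCache* c2b,
                                mat* Y1_out, mat* Y2_out, mat* A1_out,
                                mat* P_out) {
  mat h1f = lstm_forward(n.l1f, X, false, c1f);
  mat h1b = lstm_forward(n.l1b, X, true, c1b);
  mat Y1 = arma::join_cols(h1f, h1b);
  mat h2f = lstm_forward(n.l2f, Y1, false, c2f);
  mat h2b = lstm_forward(n.l2b, Y1, true, c2b);
  mat Y2 = arma::join_cols(h2f, h2b);
  mat A1 = n.fc1_W * Y2;
  A1.each_col() += n.fc1_b;
  mat R1 = arma::clamp(A1, 0.0, arma::datum::inf);   // ReLU
  mat logits = n.fc2_W * R1;
  logits.each_col() += n.fc2_b;
  mat mx = arma::max(logits, 0);
  mat e = arma::exp(logits.each_row() - mx);
  mat P = e.each_row() / arma::sum(e, 0);
  if (Y1_out) *Y1_out = Y1;
  if (Y2_out) *Y2_out = Y2;
  if (A1_out) *A1_out = A1;
  if (P_out) *P_out = P;
  return P.row(1);
}

// [[Rcpp::export(name = ".blstm_predict_cpp")]]
NumericVector blstm_predict_cpp(List weights, arma::mat X) {
  Net n = net_from_list(weights);
  arma::rowvec p1 = net_forward(n, X, nullptr, nullptr, nullptr, nullptr,
                                nullptr, nullptr, nullptr, nullptr);
  return NumericVector(p1.begin(), p1.end());
}

struct Adam {
  std::vector<mat*> params;
  std::vector<mat> m, v;
  long step = 0;
  void add(mat* p) { params.push_back(p);
                     m.emplace_back(arma::size(*p), arma::fill::zeros);
                     v.emplace_back(arma::size(*p), arma::fill::zeros); }
  void update(const std::vector<mat>& g, double lr, double clip) {
    double nrm2 = 0;
    for (auto& gi : g) nrm2 += arma::accu(gi % gi);
    double scale = 1.0;
    double nrm = std::sqrt(nrm2);
    if (clip > 0 && nrm > clip) scale = clip / nrm;
    ++step;
    double b1c = 1.0 - std::pow(0.9, (double)step);
    double b2c = 1.0 - std::pow(0.999, (double)step);
    for (size_t k = 0; k < params.size(); ++k) {
      mat gk = g[k] * scale;
      m[k] = 0.9 * m[k] + 0.1 * gk;
      v[k] = 0.999 * v[k] + 0.001 * (gk % gk);
      *params[k] -= lr * (m[k] / b1c) / (arma::sqrt(v[k] / b2c) + 1e-8);
    }
  }
};

// [[Rcpp::export(name = ".blstm_train_cpp")]]
List blstm_train_cpp(List X_list, List y_list, List init_weights,
                     double lr, int epochs, double w0, double w1,
                     IntegerMatrix order, List perm_list, double clip_norm) {
  Net n = net_from_list(init_weights);
  const int nclip = X_list.size();
  if (nclip == 0) stop("empty dataset");

  // parameter/gradient bookkeeping: biases handled as 1-column mats
  mat l1f_b(n.l1f.b), l1b_b(n.l1b.b), l2f_b(n.l2f.b), l2b_b(n.l2b.b);
  mat fc1_b(n.fc1_b), fc2_b(n.fc2_b);
  std::vector<mat*> ps = { &n.l1f.W, &n.l1f.U, &l1f_b,
                           &n.l1b.W, &n.l1b.U, &l1b_b,
                           &n.l2f.W, &n.l2f.U, &l2f_b,
                           &n.l2b.W, &n.l2b.U, &l2b_b,
                           &n.fc1_W, &fc1_b, &n.fc2_W, &fc2_b };
  Adam opt;
  for (auto* p : ps) opt.add(p);

  NumericVector loss_hist(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0, ep_wsum = 0;
    for (int c = 0; c < nclip; ++c) {
      int ci = order(ep, c) - 1;
      mat X = as<mat>(X_list[ci]);
      IntegerVector yv = y_list[ci];
      const int T = X.n_cols;
      if ((int)yv.size() != T) stop("label/feature length mismatch");

      // frequency-permutation augmentation (channel shuffle), if provided
      List ep_perms = perm_list[ep];
      if (ep_perms.size() > 0) {
        IntegerVector pm = ep_perms[ci];
        arma::uvec idx(pm.size());
        for (int r = 0; r < (int)pm.size(); ++r) idx[r] = pm[r] - 1;
        X = X.rows(idx);
      }
      n.l1f.b = l1f_b.col(0); n.l1b.b = l1b_b.col(0);
      n.l2f.b = l2f_b.col(0); n.l2b.b = l2b_b.col(0);
      n.fc1_b = fc1_b.col(0); n.fc2_b = fc2_b.col(0);

      LstmCache c1f, c1b, c2f, c2b;
      mat Y1, Y2, A1, P;
      net_forward(n, X, &c1f, &c1b, &c2f, &c2b, &Y1, &Y2, &A1, &P);

      // weighted cross-entropy, normalized by the total weight
      vec w(T), loss_t(T);
      mat dlogits(2, T);
      for (int t = 0; t < T; ++t) {
        int y = yv[t];
        double wt = (y == 1) ? w1 : w0;
        w[t] = wt;
        loss_t[t] = -wt * std::log(std::max(P(y, t), 1e-12));
        dlogits.col(t) = wt * P.col(t);
        dlogits(y, t) -= wt;
      }
      double wsum = arma::accu(w);
      double loss = arma::accu(loss_t) / wsum;
      dlogits /= wsum;
      ep_loss += arma::accu(loss_t); ep_wsum += wsum;

      // backward: FC stack
      mat R1 = arma::clamp(A1, 0.0, arma::datum::inf);
      mat g_fc2W = dlogits * R1.t();
      vec g_fc2b = arma::sum(dlogits, 1);
      mat dR1 = n.fc2_W.t() * dlogits;
      dR1.elem(arma::find(A1 <= 0)).zeros();
      mat g_fc1W = dR1 * Y2.t();
      vec g_fc1b = arma::sum(dR1, 1);
      mat dY2 = n.fc1_W.t() * dR1;

      const int H2 = n.l2f.U.n_cols;
      mat g_l2fW(arma::size(n.l2f.W), arma::fill::zeros),
          g_l2fU(arma::size(n.l2f.U), arma::fill::zeros);
      vec g_l2fb(4 * H2, arma::fill::zeros);
      mat g_l2bW(arma::size(n.l2b.W), arma::fill::zeros),
          g_l2bU(arma::size(n.l2b.U), arma::fill::zeros);
      vec g_l2bb(4 * H2, arma::fill::zeros);
      mat dY1 = lstm_backward(n.l2f, c2f, dY2.rows(0, H2 - 1), false,
                              g_l2fW, g_l2fU, g_l2fb);
      dY1 += lstm_backward(n.l2b, c2b, dY2.rows(H2, 2 * H2 - 1), true,
                           g_l2bW, g_l2bU, g_l2bb);

      const int H1 = n.l1f.U.n_cols;
      mat g_l1fW(arma::size(n.l1f.W), arma::fill::zeros),
          g_l1fU(arma::size(n.l1f.U), arma::fill::zeros);
      vec g_l1fb(4 * H1, arma::fill::zeros);
      mat g_l1bW(arma::size(n.l1b.W), arma::fill::zeros),
          g_l1bU(arma::size(n.l1b.U), arma::fill::zeros);
      vec g_l1bb(4 * H1, arma::fill::zeros);
      lstm_backward(n.l1f, c1f, dY1.rows(0, H1 - 1), false,
                    g_l1fW, g_l1fU, g_l1fb);
      lstm_backward(n.l1b, c1b, dY1.rows(H1, 2 * H1 - 1), true,
                    g_l1bW, g_l1bU, g_l1bb);

      std::vector<mat> grads = { g_l1fW, g_l1fU, mat(g_l1fb),
                                 g_l1bW, g_l1bU, mat(g_l1bb),
                                 g_l2fW, g_l2fU, mat(g_l2fb),
                                 g_l2bW, g_l2bU, mat(g_l2bb),
                                 g_fc1W, mat(g_fc1b), g_fc2W, mat(g_fc2b) };
      opt.update(grads, lr, clip_norm);
      (void)loss;
    }
    loss_hist[ep] = ep_loss / ep_wsum;
    Rcpp::checkUserInterrupt();
  }
  n.l1f.b = l1f_b.col(0); n.l1b.b = l1b_b.col(0);
  n.l2f.b = l2f_b.col(0); n.l2b.b = l2b_b.col(0);
  n.fc1_b = fc1_b.col(0); n.fc2_b = fc2_b.col(0);
  return List::create(_["weights"] = net_to_list(n),
                      _["loss"] = loss_hist);
}
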
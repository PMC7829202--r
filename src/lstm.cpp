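// Stacked (bi)directional LSTM sequence classifier: forward pass, per-step
// softmax cross-entropy, and analytic backpropagation through time.
//
// Parameter layout (mirrored between R and C++):
//   layers[[l]]$dirs[[d]]$W  4H x H   recurrent weights (gates i,f,a,o)
//   layers[[l]]$dirs[[d]]$U  4H x D   input weights
//   layers[[l]]$dirs[[d]]$b  4H       bias
//   head$V  2 x Hout, head$c  2
// dirs has one element (forward) for unidirectional layers, two
// (forward, backward-in-time) for bidirectional ones; their hidden states
// are concatenated before the next layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct DirCache {
  cube i, f, a, o, c, h;  // each H x B x T
};

static void dir_forward(const mat& W, const mat& U, const vec& b,
                        const cube& X, bool reverse, DirCache& cc) {
  const int B = X.n_cols, T = X.n_slices;
  const int H = W.n_cols;
  cc.i.set_size(H, B, T); cc.f.set_size(H, B, T); cc.a.set_size(H, B, T);
  cc.o.set_size(H, B, T); cc.c.set_size(H, B, T); cc.h.set_size(H, B, T);
  mat hprev(H, B, arma::fill::zeros), cprev(H, B, arma::fill::zeros);
  // input contribution for all steps in one GEMM
  const mat Xflat(const_cast<double*>(X.memptr()), X.n_rows, B * T, false, true);
  const mat UX = U * Xflat;  // 4H x (B*T), column c + t*B
  for (int s = 0; s < T; ++s) {
    const int t = reverse ? (T - 1 - s) : s;
    mat Z = W * hprev + UX.cols(t * B, t * B + B - 1);
    Z.each_col() += b;
    const mat gi = sigm(Z.rows(0, H - 1));
    const mat gf = sigm(Z.rows(H, 2 * H - 1));
    const mat ga = arma::tanh(Z.rows(2 * H, 3 * H - 1));
    const mat go = sigm(Z.rows(3 * H, 4 * H - 1));
    const mat ct = gf % cprev + gi % ga;
    const mat ht = go % arma::tanh(ct);
    cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.a.slice(t) = ga;
    cc.o.slice(t) = go; cc.c.slice(t) = ct; cc.h.slice(t) = ht;
    hprev = ht; cprev = ct;
  }
}

static void dir_backward(const mat& W, const mat& U, const cube& X,
                         bool reverse, const DirCache& cc, const cube& dH,
                         mat& dW, mat& dU, vec& db, cube& dX) {
  const int B = X.n_cols, T = X.n_slices;
  const int H = W.n_cols;
  dW.zeros(4 * H, H);
  dU.zeros(4 * H, X.n_rows);
  db.zeros(4 * H);
  mat dh_carry(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = reverse ? (T - 1 - s) : s;
    const mat dh = dH.slice(t) + dh_carry;
    const mat tc = arma::tanh(cc.c.slice(t));
    const mat dcc = dc + dh % cc.o.slice(t) % (1.0 - tc % tc);
    const mat do_ = dh % tc;
    mat hprev(H, B, arma::fill::zeros), cprev(H, B, arma::fill::zeros);
    if (s > 0) {
      const int tp = reverse ? (T - s) : (s - 1);
      hprev = cc.h.slice(tp);
      cprev = cc.c.slice(tp);
    }
    const mat di = dcc % cc.a.slice(t);
    const mat df = dcc % cprev;
    const mat da = dcc % cc.i.slice(t);
    mat dZ(4 * H, B);
    dZ.rows(0, H - 1)         = di % cc.i.slice(t) % (1.0 - cc.i.slice(t));
    dZ.rows(H, 2 * H - 1)     = df % cc.f.slice(t) % (1.0 - cc.f.slice(t));
    dZ.rows(2 * H, 3 * H - 1) = da % (1.0 - cc.a.slice(t) % cc.a.slice(t));
    dZ.rows(3 * H, 4 * H - 1) = do_ % cc.o.slice(t) % (1.0 - cc.o.slice(t));
    dW += dZ * hprev.t();
    dU += dZ * X.slice(t).t();
    db += arma::sum(dZ, 1);
    dX.slice(t) += U.t() * dZ;
    dh_carry = W.t() * dZ;
    dc = dcc % cc.f.slice(t);
  }
}

// Runs the stack; fills per-layer input cubes and caches.
static cube stack_forward(const List& layers, const mat& X,
                          std::vector<cube>& inputs,
                          std::vector<std::vector<DirCache> >& caches) {
  const int T = X.n_rows, B = X.n_cols;
  cube cur(1, B, T);
  for (int t = 0; t < T; ++t) cur.slice(t) = X.row(t);
  const int L = layers.size();
  inputs.resize(L);
  caches.resize(L);
  for (int l = 0; l < L; ++l) {
    inputs[l] = cur;
    List dirs = as<List>(as<List>(layers[l])["dirs"]);
    const int nd = dirs.size();
    caches[l].resize(nd);
    int H = 0;
    for (int d = 0; d < nd; ++d) {
      List dl = as<List>(dirs[d]);
      const mat W = as<mat>(dl["W"]);
      const mat U = as<mat>(dl["U"]);
      const vec b = as<vec>(dl["b"]);
      dir_forward(W, U, b, cur, d == 1, caches[l][d]);
      H = W.n_cols;
    }
    cube out(nd * H, B, T);
    for (int t = 0; t < T; ++t) {
      out.slice(t).rows(0, H - 1) = caches[l][0].h.slice(t);
      if (nd == 2) out.slice(t).rows(H, 2 * H - 1) = caches[l][1].h.slice(t);
    }
    cur = out;
  }
  return cur;
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_loss_grad(Rcpp::List layers, Rcpp::List head,
                            const arma::mat& X, const arma::mat& Y,
                            bool want_grad) {
  const int T = X.n_rows, B = X.n_cols;
  const mat V = as<mat>(head["V"]);
  const vec cb = as<vec>(head["c"]);
  std::vector<cube> inputs;
  std::vector<std::vector<DirCache> > caches;
  cube top = stack_forward(layers, X, inputs, caches);
  const int Hout = top.n_rows;

  double loss = 0.0;
  cube dTop;
  mat dV;
  vec dc;
  if (want_grad) {
    dTop.zeros(Hout, B, T);
    dV.zeros(2, Hout);
    dc.zeros(2);
  }
  const double scale = 1.0 / double(T * B);
  for (int t = 0; t < T; ++t) {
    mat logits = V * top.slice(t);          // 2 x B
    logits.each_col() += cb;
    const arma::rowvec mx = arma::max(logits, 0);
    logits.each_row() -= mx;
    const mat ex = arma::exp(logits);
    const arma::rowvec Zs = arma::sum(ex, 0);
    mat P = ex;
    P.each_row() /= Zs;
    for (int j = 0; j < B; ++j) {
      const int y = (int)Y(t, j);
      loss -= std::log(std::max(P(y, j), 1e-12)) * scale;
    }
    if (want_grad) {
      mat dL = P;
      for (int j = 0; j < B; ++j) dL((int)Y(t, j), j) -= 1.0;
      dL *= scale;
      dV += dL * top.slice(t).t();
      dc += arma::sum(dL, 1);
      dTop.slice(t) = V.t() * dL;
    }
  }

  List out;
  out["loss"] = loss;
  if (!want_grad) return out;

  const int L = layers.size();
  List glayers(L);
  cube dCur = dTop;
  for (int l = L - 1; l >= 0; --l) {
    List dirs = as<List>(as<List>(layers[l])["dirs"]);
    const int nd = dirs.size();
    const int H = as<mat>(as<List>(dirs[0])["W"]).n_cols;
    cube dX(inputs[l].n_rows, B, T, arma::fill::zeros);
    List gdirs(nd);
    for (int d = 0; d < nd; ++d) {
      List dl = as<List>(dirs[d]);
      const mat W = as<mat>(dl["W"]);
      const mat U = as<mat>(dl["U"]);
      cube dH(H, B, T);
      for (int t = 0; t < T; ++t) {
        dH.slice(t) = (d == 0) ? dCur.slice(t).rows(0, H - 1)
                               : dCur.slice(t).rows(H, 2 * H - 1);
      }
      mat dW, dU;
      vec db;
      dir_backward(W, U, inputs[l], d == 1, caches[l][d], dH, dW, dU, db, dX);
      gdirs[d] = List::create(Named("W") = dW, Named("U") = dU,
                              Named("b") = db);
    }
    glayers[l] = List::create(Named("dirs") = gdirs);
    dCur = dX;
  }
  out["grads"] = List::create(
      Named("layers") = glayers,
      Named("head") = List::create(Named("V") = dV, Named("c") = dc));
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_nn_predict(Rcpp::List layers, Rcpp::List head,
                         const arma::mat& X) {
  const int T = X.n_rows, B = X.n_cols;
  const mat V = as<mat>(head["V"]);
  const vec cb = as<vec>(head["c"]);
  std::vector<cube> inputs;
  std::vector<std::vector<DirCache> > caches;
  cube top = stack_forward(layers, X, inputs, caches);
  mat P1(T, B);
  for (int t = 0; t < T; ++t) {
    mat logits = V * top.slice(t);
    logits.each_col() += cb;
    const arma::rowvec mx = arma::max(logits, 0);
    logits.each_row() -= mx;
    const mat ex = arma::exp(logits);
    P1.row(t) = ex.row(1) / (ex.row(0) + ex.row(1));
  }
  return P1;
}

// Hidden-state sequence of a single (uni- or bidirectional) layer on a
// single sequence; exposed for the dual-route equivalence checks against
// the pure-R reference cell.
// [[Rcpp::export]]
arma::mat cpp_layer_hidden(Rcpp::List layer, const arma::mat& X,
                           bool reverse) {
  const int T = X.n_rows;
  const int D = X.n_cols;
  cube Xc(D, 1, T);
  for (int t = 0; t < T; ++t) Xc.slice(t) = X.row(t).t();
  List dl = as<List>(layer);
  const mat W = as<mat>(dl["W"]);
  const mat U = as<mat>(dl["U"]);
  const vec b = as<vec>(dl["b"]);
  DirCache cc;
  dir_forward(W, U, b, Xc, reverse, cc);
  const int H = W.n_cols;
  mat out(T, H);
  for (int t = 0; t < T; ++t) out.row(t) = cc.h.slice(t).t();
  return out;
}
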
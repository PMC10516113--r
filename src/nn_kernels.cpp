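// Dense network kernels used by the sequential autoencoder.  All layers are
// fully connected; activations are ReLU (act = 0) or tanh (act = 1) on the
// hidden layers, with a linear output layer.  Backward passes implement plain
// reverse-mode accumulation and return gradients in the same shapes as the
// parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::rowvec;

static inline mat apply_act(const mat& a, const int act) {
  if (act == 0) return arma::clamp(a, 0.0, arma::datum::inf);
  return arma::tanh(a);
}

// derivative of the activation expressed through the activated value h
static inline mat act_deriv(const mat& h, const int act) {
  if (act == 0) return arma::conv_to<mat>::from(h > 0);
  return 1.0 - arma::square(h);
}

// [[Rcpp::export]]
List cpp_mlp_forward(const arma::mat& X, const List& W, const List& b,
                     const int act) {
  const int L = W.size();
  List hidden(std::max(L - 1, 0));
  mat h = X;
  for (int l = 0; l < L; ++l) {
    const mat Wl = as<mat>(W[l]);
    const rowvec bl = as<rowvec>(b[l]);
    mat a = h * Wl;
    a.each_row() += bl;
    if (l < L - 1) {
      h = apply_act(a, act);
      hidden[l] = h;
    } else {
      h = a;
    }
  }
  return List::create(_["out"] = h, _["hidden"] = hidden);
}

// [[Rcpp::export]]
List cpp_mlp_backward(const arma::mat& X, const List& hidden, const List& W,
                      const arma::mat& grad_out, const int act,
                      const bool need_dx) {
  const int L = W.size();
  List dW(L), db(L);
  mat g = grad_out;
  mat dX;
  for (int l = L - 1; l >= 0; --l) {
    const mat inp = (l == 0) ? X : as<mat>(hidden[l - 1]);
    dW[l] = inp.t() * g;
    db[l] = arma::sum(g, 0);
    const mat Wl = as<mat>(W[l]);
    if (l > 0) {
      g = (g * Wl.t()) % act_deriv(as<mat>(hidden[l - 1]), act);
    } else if (need_dx) {
      dX = g * Wl.t();
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Single-direction GRU over a sequence.  X is a cube (batch x inputs x time);
// W (inputs x 3h), U (h x 3h) and the two bias rows follow the usual
// [reset | update | candidate] gate layout.  Only the final hidden state is
// consumed downstream, so the forward pass returns h_T plus the per-step
// caches needed for truncated-free BPTT.
// [[Rcpp::export]]
List cpp_gru_forward(const arma::cube& X, const arma::mat& W,
                     const arma::mat& U, const arma::rowvec& bi,
                     const arma::rowvec& bh) {
  const int B = X.n_rows, T = X.n_slices;
  const int H = U.n_rows;
  mat h(B, H, arma::fill::zeros);
  cube r_c(B, H, T), z_c(B, H, T), n_c(B, H, T), ghn_c(B, H, T),
      hprev_c(B, H, T);
  for (int t = 0; t < T; ++t) {
    mat gi = X.slice(t) * W;
    gi.each_row() += bi;
    mat gh = h * U;
    gh.each_row() += bh;
    const mat r = 1.0 / (1.0 + arma::exp(-(gi.cols(0, H - 1) + gh.cols(0, H - 1))));
    const mat z = 1.0 / (1.0 + arma::exp(-(gi.cols(H, 2 * H - 1) + gh.cols(H, 2 * H - 1))));
    const mat ghn = gh.cols(2 * H, 3 * H - 1);
    const mat n = arma::tanh(gi.cols(2 * H, 3 * H - 1) + r % ghn);
    hprev_c.slice(t) = h;
    h = (1.0 - z) % n + z % h;
    r_c.slice(t) = r;
    z_c.slice(t) = z;
    n_c.slice(t) = n;
    ghn_c.slice(t) = ghn;
  }
  return List::create(_["hT"] = h, _["r"] = r_c, _["z"] = z_c, _["n"] = n_c,
                      _["ghn"] = ghn_c, _["hprev"] = hprev_c);
}

// [[Rcpp::export]]
List cpp_gru_backward(const arma::cube& X, const arma::cube& r_c,
                      const arma::cube& z_c, const arma::cube& n_c,
                      const arma::cube& ghn_c, const arma::cube& hprev_c,
                      const arma::mat& W, const arma::mat& U,
                      const arma::mat& dhT) {
  const int T = X.n_slices;
  const int H = U.n_rows;
  const int D = W.n_rows;
  mat dW(D, 3 * H, arma::fill::zeros), dU(H, 3 * H, arma::fill::zeros);
  rowvec dbi(3 * H, arma::fill::zeros), dbh(3 * H, arma::fill::zeros);
  mat dh = dhT;
  for (int t = T - 1; t >= 0; --t) {
    const mat& r = r_c.slice(t);
    const mat& z = z_c.slice(t);
    const mat& n = n_c.slice(t);
    const mat& ghn = ghn_c.slice(t);
    const mat& hprev = hprev_c.slice(t);
    const mat da_z = dh % (hprev - n) % z % (1.0 - z);
    const mat dn = dh % (1.0 - z) % (1.0 - arma::square(n));
    const mat da_r = dn % ghn % r % (1.0 - r);
    mat dgi(dh.n_rows, 3 * H), dgh(dh.n_rows, 3 * H);
    dgi.cols(0, H - 1) = da_r;
    dgi.cols(H, 2 * H - 1) = da_z;
    dgi.cols(2 * H, 3 * H - 1) = dn;
    dgh.cols(0, H - 1) = da_r;
    dgh.cols(H, 2 * H - 1) = da_z;
    dgh.cols(2 * H, 3 * H - 1) = dn % r;
    dW += X.slice(t).t() * dgi;
    dU += hprev.t() * dgh;
    dbi += arma::sum(dgi, 0);
    dbh += arma::sum(dgh, 0);
    dh = dh % z + dgh * U.t();
  }
  return List::create(_["dW"] = dW, _["dU"] = dU, _["dbi"] = dbi,
                      _["dbh"] = dbh);
}
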
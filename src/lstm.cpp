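// LSTM forward/backward kernels. The R-level tape handles everything else
// (convolutions are BLAS matmuls after im2col); only the sequential recurrence
// needs a compiled loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// X: B x F x T cube (slice t = inputs at time t), Wx: F x 4U, Wh: U x 4U,
// b: 1 x 4U. Gate order: input, forget, candidate, output.
// [[Rcpp::export]]
List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::rowvec& b) {
  const int B = X.n_rows, T = X.n_slices;
  const int U = Wh.n_rows;
  arma::cube Acts(B, 4 * U, T);  // post-nonlinearity gate activations
  arma::cube Cs(B, U, T);
  arma::cube Hs(B, U, T);
  arma::mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat z = X.slice(t) * Wx + h * Wh;
    z.each_row() += b;
    arma::mat i = sigm(z.cols(0, U - 1));
    arma::mat f = sigm(z.cols(U, 2 * U - 1));
    arma::mat g = arma::tanh(z.cols(2 * U, 3 * U - 1));
    arma::mat o = sigm(z.cols(3 * U, 4 * U - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    Acts.slice(t) = arma::join_rows(arma::join_rows(i, f), arma::join_rows(g, o));
    Cs.slice(t) = c;
    Hs.slice(t) = h;
  }
  return List::create(_["h_last"] = h, _["acts"] = Acts, _["cells"] = Cs,
                      _["hiddens"] = Hs);
}

// Backprop through time from the gradient of the final hidden state.
// [[Rcpp::export]]
List lstm_backward_cpp(const arma::cube& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::cube& Acts,
                       const arma::cube& Cs, const arma::cube& Hs,
                       const arma::mat& dH_last) {
  const int B = X.n_rows, T = X.n_slices;
  const int U = Wh.n_rows;
  arma::cube dX(B, X.n_cols, T, arma::fill::zeros);
  arma::mat dWx(Wx.n_rows, Wx.n_cols, arma::fill::zeros);
  arma::mat dWh(Wh.n_rows, Wh.n_cols, arma::fill::zeros);
  arma::rowvec db(4 * U, arma::fill::zeros);
  arma::mat dh = dH_last;
  arma::mat dc(B, U, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat i = Acts.slice(t).cols(0, U - 1);
    arma::mat f = Acts.slice(t).cols(U, 2 * U - 1);
    arma::mat g = Acts.slice(t).cols(2 * U, 3 * U - 1);
    arma::mat o = Acts.slice(t).cols(3 * U, 4 * U - 1);
    arma::mat tc = arma::tanh(Cs.slice(t));
    arma::mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    arma::mat c_prev = (t > 0) ? Cs.slice(t - 1)
                               : arma::mat(B, U, arma::fill::zeros);
    arma::mat h_prev = (t > 0) ? Hs.slice(t - 1)
                               : arma::mat(B, U, arma::fill::zeros);
    arma::mat di = dc % g;
    arma::mat df = dc % c_prev;
    arma::mat dg = dc % i;
    arma::mat dzi = di % i % (1.0 - i);
    arma::mat dzf = df % f % (1.0 - f);
    arma::mat dzg = dg % (1.0 - g % g);
    arma::mat dzo = do_ % o % (1.0 - o);
    arma::mat dz = arma::join_rows(arma::join_rows(dzi, dzf),
                                   arma::join_rows(dzg, dzo));
    dWx += X.slice(t).t() * dz;
    dWh += h_prev.t() * dz;
    db += arma::sum(dz, 0);
    dX.slice(t) = dz * Wx.t();
    dh = dz * Wh.t();
    dc = dc % f;
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
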
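// Fused LSTM forward + BPTT pass for the proximity classifier.
// Mirrors the plain-R implementation (lstm_bce_pass); the R gradient-check
// tests verify both against central finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X_all: (T*n) x U input slices stacked oldest-first; y: n x U binary labels.
// Gates are ordered [i, f, g, o] along the 4*nh columns of Wx / Wh / b.
// [[Rcpp::export(name = ".lstm_bce_pass_cpp")]]
Rcpp::List lstm_bce_pass_cpp(const arma::mat& Wx, const arma::mat& Wh,
                             const arma::rowvec& b, const arma::mat& Wo,
                             const arma::rowvec& bo, const arma::mat& X_all,
                             const arma::mat& y, int t_len) {
  const int n = y.n_rows;
  const int nh = Wh.n_rows;

  mat Zx = X_all * Wx;
  std::vector<mat> hs(t_len + 1), cs(t_len + 1), gi(t_len), gf(t_len),
      gg(t_len), go(t_len);
  hs[0] = zeros<mat>(n, nh);
  cs[0] = zeros<mat>(n, nh);

  for (int t = 0; t < t_len; ++t) {
    mat z = Zx.rows(t * n, (t + 1) * n - 1) + hs[t] * Wh;
    z.each_row() += b;
    gi[t] = 1.0 / (1.0 + exp(-z.cols(0, nh - 1)));
    gf[t] = 1.0 / (1.0 + exp(-z.cols(nh, 2 * nh - 1)));
    gg[t] = tanh(z.cols(2 * nh, 3 * nh - 1));
    go[t] = 1.0 / (1.0 + exp(-z.cols(3 * nh, 4 * nh - 1)));
    cs[t + 1] = gf[t] % cs[t] + gi[t] % gg[t];
    hs[t + 1] = go[t] % tanh(cs[t + 1]);
  }

  mat zo = hs[t_len] * Wo;
  zo.each_row() += bo;
  // binary cross entropy summed over outputs, averaged over rows
  double loss = accu(max(zo, zeros<mat>(n, zo.n_cols)) - zo % y +
                     log1p(exp(-abs(zo)))) / n;

  mat dz = (1.0 / (1.0 + exp(-zo)) - y) / n;
  mat dWo = hs[t_len].t() * dz;
  rowvec dbo = sum(dz, 0);
  mat dh = dz * Wo.t();
  mat dc = zeros<mat>(n, nh);
  mat dWh = zeros<mat>(size(Wh));
  mat DZ(t_len * n, 4 * nh);

  for (int t = t_len - 1; t >= 0; --t) {
    mat tc = tanh(cs[t + 1]);
    dc += dh % go[t] % (1.0 - tc % tc);
    mat dzg(n, 4 * nh);
    dzg.cols(0, nh - 1) = (dc % gg[t]) % gi[t] % (1.0 - gi[t]);
    dzg.cols(nh, 2 * nh - 1) = (dc % cs[t]) % gf[t] % (1.0 - gf[t]);
    dzg.cols(2 * nh, 3 * nh - 1) = (dc % gi[t]) % (1.0 - gg[t] % gg[t]);
    dzg.cols(3 * nh, 4 * nh - 1) = (dh % tc) % go[t] % (1.0 - go[t]);
    DZ.rows(t * n, (t + 1) * n - 1) = dzg;
    dWh += hs[t].t() * dzg;
    dh = dzg * Wh.t();
    dc = dc % gf[t];
  }

  mat dWx = X_all.t() * DZ;
  rowvec db = sum(DZ, 0);

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db,
      Rcpp::Named("dWo") = dWo, Rcpp::Named("dbo") = dbo);
}
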
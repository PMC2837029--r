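#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// mean negative binomial log-likelihood, probabilities clipped to [eps, 1-eps]
static double neg_loglik(const arma::vec& f, const arma::vec& y1, double eps) {
  const arma::uword n = f.n_elem;
  double s = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double pi = 1.0 / (1.0 + std::exp(-f(i)));
    if (pi < eps) pi = eps;
    if (pi > 1.0 - eps) pi = 1.0 - eps;
    s += (y1(i) > 0.5) ? std::log(pi) : std::log1p(-pi);
  }
  return -s / static_cast<double>(n);
}

// Componentwise linear least squares boosting on the binomial log-likelihood
// loss, starting from a fixed per-sample offset.
//
// X   : n x p working matrix (any centering/standardization already applied)
// mu  : column means of X
// ssq : centered column sums of squares of X
// y1  : response as 0/1
// offset : fixed linear-predictor offset, length n
//
// Per iteration m: u = y1 - expit(f); OLS of u on (1, X_j) for every j; the
// column with the smallest RSS wins (ties -> smallest index, which is what
// index_max delivers on the equivalent score (X_j'u_c)^2 / ssq_j); update
// f <- f + nu * (a + b * X_j*), accumulating a into beta0 and b into beta_j*.
// Zero-variance columns score 0 and can never win unless every column is
// constant (degenerate flag; base fit reduces to the intercept).
//
// When track_df is true the aggregated hat operator
//   B_m = B_{m-1} + nu * H_{j*} (I - B_{m-1}),  H_j = J/n + xc_j xc_j' / ssq_j
// is maintained and df(m) = trace(B_m) recorded.
// [[Rcpp::export]]
List cwlls_boost(const arma::mat& X, const arma::vec& mu, const arma::vec& ssq,
                 const arma::vec& y1, const arma::vec& offset,
                 int mstop, double nu, double eps, bool track_df) {
  const arma::uword n = X.n_rows, p = X.n_cols;

  arma::vec f = offset;
  arma::vec beta(p, arma::fill::zeros);
  double beta0 = 0.0;
  arma::ivec sel(std::max(mstop, 0));
  arma::vec loss(mstop + 1);
  arma::vec df(mstop + 1, arma::fill::zeros);
  loss(0) = neg_loglik(f, y1, eps);

  const bool all_const = !arma::any(ssq > 0.0);
  arma::mat B;
  if (track_df) B.zeros(n, n);

  for (int m = 1; m <= mstop; ++m) {
    arma::vec u = y1 - 1.0 / (1.0 + arma::exp(-f));
    const double ubar = arma::mean(u);
    arma::vec uc = u - ubar;
    arma::vec sc = X.t() * uc;           // equals centered cross product
    arma::vec score(p, arma::fill::zeros);
    for (arma::uword j = 0; j < p; ++j)
      if (ssq(j) > 0.0) score(j) = sc(j) * sc(j) / ssq(j);

    arma::uword j = score.index_max();   // first max: smallest-index tie-break
    double b = (ssq(j) > 0.0) ? sc(j) / ssq(j) : 0.0;
    double a = ubar - b * mu(j);

    f += nu * (a + b * X.col(j));
    beta0 += nu * a;
    beta(j) += nu * b;
    sel(m - 1) = static_cast<int>(j) + 1;
    loss(m) = neg_loglik(f, y1, eps);

    if (track_df) {
      arma::mat IB = -B;
      IB.diag() += 1.0;
      arma::rowvec cs = arma::sum(IB, 0) / static_cast<double>(n);
      if (ssq(j) > 0.0) {
        arma::vec xc = X.col(j) - mu(j);
        arma::rowvec v = (xc.t() * IB) / ssq(j);
        B += nu * (arma::ones<arma::vec>(n) * cs + xc * v);
      } else {
        B += nu * (arma::ones<arma::vec>(n) * cs);
      }
      df(m) = arma::trace(B);
    }
  }

  return List::create(
    _["beta0"] = beta0, _["beta"] = beta, _["selection"] = sel,
    _["loss"] = loss, _["df"] = df, _["f"] = f,
    _["degenerate"] = all_const && mstop > 0);
}
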
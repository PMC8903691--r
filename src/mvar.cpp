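#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

//' MVAR recursion over a pre-drawn innovation sequence
//'
//' Runs x_t = sum_k A_k x_{t-k} + e_t with zero initial conditions.
//' Innovations are drawn in R so the result is deterministic under R's RNG.
//'
//' @param coefs d x d x p array of lag coefficient matrices (lag k in slice k).
//' @param innovations d x n matrix of innovations, one column per time step.
//' @return d x n matrix of the process realization.
//' @keywords internal
// [[Rcpp::export]]
arma::mat mvar_recurse(const arma::cube& coefs, const arma::mat& innovations) {
  const arma::uword d = innovations.n_rows;
  const arma::uword n = innovations.n_cols;
  const arma::uword p = coefs.n_slices;
  arma::mat x(d, n, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    arma::vec acc = innovations.col(t);
    for (arma::uword k = 0; k < p && k < t + 1; ++k) {
      if (t >= k + 1) acc += coefs.slice(k) * x.col(t - k - 1);
    }
    x.col(t) = acc;
  }
  return x;
}
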
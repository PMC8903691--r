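#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

//' Direct-form II transposed IIR filter
//'
//' Applies the difference equation a(1)y(n) = b(1)x(n) + ... -
//' a(2)y(n-1) - ... along each row of x. Coefficients as from
//' signal::butter.
//'
//' @param b,a filter numerator / denominator coefficient vectors.
//' @param x matrix filtered along rows.
//' @return Filtered matrix, same shape.
//' @keywords internal
// [[Rcpp::export]]
arma::mat iir_filter_rows(const arma::vec& b, const arma::vec& a,
                          const arma::mat& x) {
  const arma::uword nb = b.n_elem, na = a.n_elem;
  const arma::uword nz = std::max(nb, na) - 1;
  arma::vec bn = b / a(0), an = a / a(0);
  bn.resize(nz + 1); an.resize(nz + 1);
  arma::mat y(x.n_rows, x.n_cols);
  for (arma::uword r = 0; r < x.n_rows; ++r) {
    arma::vec z(nz, arma::fill::zeros);
    for (arma::uword n = 0; n < x.n_cols; ++n) {
      double xn = x(r, n);
      double yn = bn(0) * xn + z(0);
      for (arma::uword k = 1; k < nz; ++k) {
        z(k - 1) = bn(k) * xn + z(k) - an(k) * yn;
      }
      z(nz - 1) = bn(nz) * xn - an(nz) * yn;
      y(r, n) = yn;
    }
  }
  return y;
}
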
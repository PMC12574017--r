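// Causal direct-form-II-transposed IIR filtering of a multichannel matrix.
// Coefficient design stays in R (signal::butter and the biquad notch); this
// kernel only evaluates the difference equation column by column, which is
// what keeps minute-long 32-channel recordings cheap to preprocess.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat cpp_iir_filter(const arma::mat& x, const arma::vec& b,
                         const arma::vec& a) {
  if (a.n_elem < 1 || a[0] == 0.0) Rcpp::stop("a[1] must be nonzero");
  const arma::vec bn = b / a[0];
  const arma::vec an = a / a[0];
  const int nb = bn.n_elem, na = an.n_elem;
  const int ns = std::max(nb, na);      // states w[0..ns-2], w[ns-1] kept 0
  const int n = x.n_rows, nc = x.n_cols;
  arma::mat y(n, nc);
  std::vector<double> w(ns, 0.0);
  for (int c = 0; c < nc; ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int i = 0; i < n; ++i) {
      const double xi = xc[i];
      const double yi = bn[0] * xi + w[0];
      for (int k = 1; k < ns; ++k) {
        double v = w[k];
        if (k < nb) v += bn[k] * xi;
        if (k < na) v -= an[k] * yi;
        w[k - 1] = v;
      }
      w[ns - 1] = 0.0;
      yc[i] = yi;
    }
  }
  return y;
}
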
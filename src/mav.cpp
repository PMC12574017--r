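// Fused sliding-window mean-absolute-value extraction for single-ended
// channels and all pairwise differential recordings. The differential
// signals are never materialised at the EMG rate: window sums are maintained
// incrementally as the trailing window slides, so a 32-channel recording
// yields the 528-feature series in one pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_mav_pairwise(const arma::mat& v, double fs, double rate_hz,
                           double window_s) {
  const int n = v.n_rows;
  const int nc = v.n_cols;
  if (n < 1) stop("empty input");
  // small epsilon guards against floating floor landing one sample short
  // when the true frame boundary is an exact integer
  const int K = (int)std::floor((double)n / fs * rate_hz + 1e-9);
  if (K < 1) stop("recording shorter than one frame");
  const int w = (int)std::floor(window_s * fs + 1e-9);
  const int npair = nc * (nc - 1) / 2;
  const int p = nc + npair;

  arma::mat out(K, p);
  arma::vec sums(p, arma::fill::zeros);
  int cur_s = 1, cur_e = 0; // current window [cur_s, cur_e], 1-based, empty

  // add (+1) or remove (-1) sample row i (0-based) from the running sums
  auto apply_sample = [&](int i, double sign) {
    const double* row = v.colptr(0); // column-major access below
    int idx = nc;
    for (int c = 0; c < nc; ++c) sums[c] += sign * std::fabs(v(i, c));
    for (int a = 0; a < nc - 1; ++a) {
      const double va = v(i, a);
      for (int b = a + 1; b < nc; ++b, ++idx) {
        sums[idx] += sign * std::fabs(va - v(i, b));
      }
    }
    (void)row;
  };

  for (int k = 1; k <= K; ++k) {
    int e = std::min(n, (int)std::floor((double)k / rate_hz * fs + 1e-9));
    int s = std::max(1, e - w + 1);
    // slide: remove samples cur_s..s-1, add samples cur_e+1..e
    for (int i = cur_e + 1; i <= e; ++i) apply_sample(i - 1, +1.0);
    for (int i = cur_s; i <= s - 1; ++i) apply_sample(i - 1, -1.0);
    cur_s = s; cur_e = e;
    const double len = (double)(e - s + 1);
    for (int j = 0; j < p; ++j) out(k - 1, j) = sums[j] / len;
  }
  return out;
}
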
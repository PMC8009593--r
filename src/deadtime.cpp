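#include <Rcpp.h>

// Non-paralyzable dead-time filter: an arrival is counted only if at least
// `tau` seconds elapsed since the last *counted* arrival. The recursion on
// the last counted time cannot be vectorized, hence this kernel.
// [[Rcpp::export]]
Rcpp::LogicalVector nonparalyzable_keep(Rcpp::NumericVector times, double tau) {
  R_xlen_t n = times.size();
  Rcpp::LogicalVector keep(n);
  double last = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (times[i] - last > tau) {
      keep[i] = true;
      last = times[i];
    }
  }
  return keep;
}
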
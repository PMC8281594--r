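#include <Rcpp.h>
#include <cmath>

// Fused in-place Adam update: one pass over the parameter block instead
// of a chain of allocating elementwise operations. The caller guarantees
// exclusive ownership of w, m and v (they are duplicated once when
// training starts).
// [[Rcpp::export]]
void adam_update_inplace(Rcpp::NumericVector w, Rcpp::NumericVector m,
                         Rcpp::NumericVector v, Rcpp::NumericVector g,
                         double lr, double beta1, double beta2,
                         double eps, double corr) {
  const R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    Rcpp::stop("adam_update_inplace: length mismatch");
  double *pw = w.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  const double lrc = lr * corr;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * gi * gi;
    pw[i] -= lrc * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}
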
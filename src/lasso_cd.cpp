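#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the Lasso in covariance form.
// C = X'X/n (centered), b = X'y/n (centered), d = diag(C).
// Minimizes (1/2n)||y - X beta||^2 + lambda * ||beta||_1.
// [[Rcpp::export(rng = false)]]
List cd_lasso(const NumericMatrix& C, const NumericVector& b,
              const NumericVector& d, double lambda,
              NumericVector beta, double tol, int max_iter) {
  const int p = b.size();
  NumericVector Cbeta(p);
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      for (int k = 0; k < p; ++k) Cbeta[k] += C(k, j) * beta[j];
    }
  }
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (d[j] < 1e-12) {
        if (beta[j] != 0.0) {
          for (int k = 0; k < p; ++k) Cbeta[k] -= C(k, j) * beta[j];
          beta[j] = 0.0;
        }
        continue;
      }
      double r = b[j] - Cbeta[j] + d[j] * beta[j];
      double bn = 0.0;
      if (r > lambda) bn = (r - lambda) / d[j];
      else if (r < -lambda) bn = (r + lambda) / d[j];
      double diff = bn - beta[j];
      if (diff != 0.0) {
        for (int k = 0; k < p; ++k) Cbeta[k] += C(k, j) * diff;
        double dd = d[j] * diff * diff;  // variance-scaled update size
        if (dd > delta) delta = dd;
        beta[j] = bn;
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["beta"] = beta, _["sweeps"] = it);
}
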
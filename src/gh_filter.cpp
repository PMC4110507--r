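#include <Rcpp.h>
using namespace Rcpp;

// Critically damped g-h tracking recursion.
//
// predict  x-_k = xhat_{k-1} + dt * vhat_{k-1}
// innovate r    = y_k - x-_k
// update   xhat_k = x-_k + g * r ;  vhat_k = vhat_{k-1} + (h / dt) * r
//
// The returned "voluntary" series is the one-step prediction x_{k+1,k}
// (voluntary[0] = y[0]; state initialised xhat = y[0], vhat = 0), so the
// residual y - voluntary is the real-time tremor estimate. With
// output_prediction = false the filtered update xhat_k is returned instead.
// [[Rcpp::export(name = ".gh_filter_core")]]
NumericVector gh_filter_core(NumericVector y, double g, double h, double dt,
                             bool output_prediction = true) {
  int n = y.size();
  NumericVector out(n);
  if (n == 0) return out;
  double xhat = y[0];
  double vhat = 0.0;
  out[0] = y[0];
  for (int k = 1; k < n; ++k) {
    double xpred = xhat + dt * vhat;
    double r = y[k] - xpred;
    xhat = xpred + g * r;
    vhat = vhat + (h / dt) * r;
    out[k] = output_prediction ? xpred : xhat;
  }
  return out;
}
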
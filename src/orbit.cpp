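#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Mean of ln|S'(x_t)| along an n_steps orbit of a piecewise-linear map.
// Branch lookup mirrors the R side: half-open branch domains [x_lo, x_hi),
// global domain [lo, hi) with images clipped into [lo, hi].
// [[Rcpp::export]]
double orbit_mean_log_slope(NumericVector x_lo, NumericVector slope,
                            NumericVector intercept, double lo, double hi,
                            double x0, int n_steps) {
  const int nb = x_lo.size();
  if (n_steps <= 0) stop("n_steps must be positive");
  double x = x0, acc = 0.0;
  const double top = hi - (hi - lo) * 1e-15;
  for (int t = 0; t < n_steps; ++t) {
    // last branch with x_lo <= x
    int k = int(std::upper_bound(x_lo.begin(), x_lo.end(), x) - x_lo.begin()) - 1;
    if (k < 0) k = 0;
    const double s = slope[k];
    if (s == 0.0) stop("zero-slope branch hit along the orbit; ln|S'| diverges");
    acc += std::log(std::fabs(s));
    x = s * x + intercept[k];
    if (x < lo) x = lo;
    if (x >= hi) x = top;  // keep the orbit inside the half-open domain
  }
  return acc / n_steps;
}
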
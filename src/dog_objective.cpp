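#include <Rcpp.h>
using namespace Rcpp;

// Derivative-of-Gaussian bias curve, parameterised so that alpha > 0 is
// attraction: g(x) = (x - mu) / sigma^2 * dnorm(x, mu, sigma), model
// y = alpha * g(x). For a given (mu, sigma) the least-squares alpha is
// linear and is profiled out here; the hot bootstrap loop only has to
// optimise over (mu, sigma).

// [[Rcpp::export]]
NumericVector dog_profile_rss(double mu, double sigma,
                              NumericVector x, NumericVector y,
                              double alpha_lo, double alpha_hi) {
  const int n = x.size();
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  double sgg = 0.0, sgy = 0.0, syy = 0.0;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    double z = (x[i] - mu) / sigma;
    double gi = (x[i] - mu) * inv_s2 * norm * std::exp(-0.5 * z * z);
    g[i] = gi;
    sgg += gi * gi;
    sgy += gi * y[i];
    syy += y[i] * y[i];
  }
  double alpha = (sgg > 0.0) ? sgy / sgg : 0.0;
  if (alpha < alpha_lo) alpha = alpha_lo;
  if (alpha > alpha_hi) alpha = alpha_hi;
  double rss = syy - 2.0 * alpha * sgy + alpha * alpha * sgg;
  if (rss < 0.0) rss = 0.0;  // guard against round-off
  return NumericVector::create(rss, alpha);
}

// [[Rcpp::export]]
NumericVector dog_value_cpp(NumericVector x, double mu, double sigma,
                            double alpha) {
  const int n = x.size();
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double z = (x[i] - mu) / sigma;
    out[i] = alpha * (x[i] - mu) * inv_s2 * norm * std::exp(-0.5 * z * z);
  }
  return out;
}
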
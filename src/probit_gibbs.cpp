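#include <Rcpp.h>
using namespace Rcpp;

// Albert-Chib latent-variable Gibbs sampler for a Bayesian probit
// regression with design W = [1, metagene] and prior beta ~ N(0, v I).
// Under class separation the slope chain is heavily autocorrelated, so
// the sampler runs thinned (keep every `thin`-th draw) to deliver the
// requested number of near-independent posterior draws cheaply; the
// 2x2 normal-equation algebra is closed-form. Uses R's RNG, so results
// are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix probit_gibbs_cpp(const NumericMatrix& W,
                               const IntegerVector& y, int n_mc,
                               int burn_in, int thin, double prior_var) {
  const int n = W.nrow();
  // precision and Cholesky of V = (W'W + I/v)^{-1} (2x2, closed form)
  double a = 0.0, b = 0.0, c = 0.0;  // W'W entries
  for (int i = 0; i < n; ++i) {
    a += W(i, 0) * W(i, 0);
    b += W(i, 0) * W(i, 1);
    c += W(i, 1) * W(i, 1);
  }
  a += 1.0 / prior_var;
  c += 1.0 / prior_var;
  double det = a * c - b * b;
  double V11 = c / det, V12 = -b / det, V22 = a / det;
  // lower Cholesky of V
  double L11 = std::sqrt(V11);
  double L21 = V12 / L11;
  double L22 = std::sqrt(V22 - L21 * L21);

  NumericMatrix draws(n_mc, 2);
  double b0 = 0.0, b1 = 0.0;
  std::vector<double> z(n);
  const long total = (long)burn_in + (long)n_mc * thin;
  int kept = 0;
  for (long it = 0; it < total; ++it) {
    // latent responses: truncated normal at the linear predictor
    double s0 = 0.0, s1 = 0.0;  // W' z accumulators
    for (int i = 0; i < n; ++i) {
      double eta = b0 * W(i, 0) + b1 * W(i, 1);
      double lo, hi;
      if (y[i] == 1) { lo = R::pnorm(0.0, eta, 1.0, 1, 0); hi = 1.0; }
      else           { lo = 0.0; hi = R::pnorm(0.0, eta, 1.0, 1, 0); }
      double u = R::runif(lo, hi);
      if (u < 1e-12) u = 1e-12;
      if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
      double zi = R::qnorm(u, eta, 1.0, 1, 0);
      z[i] = zi;
      s0 += W(i, 0) * zi;
      s1 += W(i, 1) * zi;
    }
    // beta | z ~ N(V W'z, V)
    double m0 = V11 * s0 + V12 * s1;
    double m1 = V12 * s0 + V22 * s1;
    double e0 = R::norm_rand(), e1 = R::norm_rand();
    b0 = m0 + L11 * e0;
    b1 = m1 + L21 * e0 + L22 * e1;
    if (it >= burn_in && ((it - burn_in + 1) % thin) == 0 && kept < n_mc) {
      draws(kept, 0) = b0;
      draws(kept, 1) = b1;
      ++kept;
    }
  }
  return draws;
}
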
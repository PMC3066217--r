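#include <Rcpp.h>
using namespace Rcpp;

// Per-gene univariate Cox screening with Breslow tie handling.
//
// X is the full samples x genes matrix; `rows` selects and orders the
// samples of the current fold by time DESCENDING (0-based indices), so
// the risk set for the sample at position j is positions 0..tieEnd[j]
// (tieEnd = last position sharing the same time). `ev` holds the event
// indicator in the same order. Genes are standardized over the used
// samples when `standardize` is true. The screening p-value is the
// efficient score test at beta = 0; coefficients of genes passing
// `alpha` are refined by damped Newton iterations on the partial
// likelihood, the rest keep the one-step estimate U/V. This is the
// inner loop of the supervised principal-component pipeline, re-run for
// every cross-validation fold and permutation, hence compiled.

// [[Rcpp::export]]
List cox_screen_cpp(const NumericMatrix& X, const IntegerVector& rows,
                    const IntegerVector& ev, const IntegerVector& tieEnd,
                    double alpha, int iter, bool standardize) {
  const int n = rows.size(), G = X.ncol();
  NumericVector coef(G), pval(G), chisq(G);
  std::vector<int> evPos, evEnd;
  for (int j = 0; j < n; ++j)
    if (ev[j] == 1) { evPos.push_back(j); evEnd.push_back(tieEnd[j]); }
  const int ne = (int)evPos.size();
  std::vector<double> x(n);

  for (int g = 0; g < G; ++g) {
    const double* col = &X(0, g);
    double mu = 0.0, sd = 1.0;
    if (standardize) {
      double s = 0.0, s2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = col[rows[j]];
        s += v; s2 += v * v;
      }
      mu = s / n;
      double var = (s2 - n * mu * mu) / (n - 1);
      sd = var > 0.0 ? std::sqrt(var) : 1.0;
    }
    const double inv = 1.0 / sd;
    for (int j = 0; j < n; ++j) x[j] = (col[rows[j]] - mu) * inv;

    // score test at beta = 0: prefix sums of x and x^2 down the risk list
    double U = 0.0, V = 0.0;
    {
      double s1 = 0.0, s2 = 0.0;
      int pos = 0;
      for (int e = 0; e < ne; ++e) {
        int end = evEnd[e];
        while (pos <= end) { s1 += x[pos]; s2 += x[pos] * x[pos]; ++pos; }
        double r = end + 1.0;
        double m = s1 / r;
        U += x[evPos[e]] - m;
        V += s2 / r - m * m;
      }
    }
    if (V <= 0.0) { coef[g] = 0.0; chisq[g] = 0.0; pval[g] = 1.0; continue; }
    chisq[g] = U * U / V;
    pval[g] = R::pchisq(chisq[g], 1.0, 0, 0);
    double beta = U / V;  // one-step estimate
    if (pval[g] < alpha) {
      for (int it = 0; it < iter; ++it) {
        double Ub = 0.0, Ib = 0.0, s0 = 0.0, s1 = 0.0, s2 = 0.0;
        int pos = 0;
        for (int e = 0; e < ne; ++e) {
          int end = evEnd[e];
          while (pos <= end) {
            double w = std::exp(beta * x[pos]);
            s0 += w; s1 += w * x[pos]; s2 += w * x[pos] * x[pos];
            ++pos;
          }
          double m = s1 / s0;
          Ub += x[evPos[e]] - m;
          Ib += s2 / s0 - m * m;
        }
        if (Ib <= 0.0) break;
        double step = Ub / Ib;
        if (step > 2.0) step = 2.0;
        if (step < -2.0) step = -2.0;  // damp wild steps
        beta += step;
        if (std::fabs(step) < 1e-9) break;
      }
      if (!std::isfinite(beta)) beta = U / V;
    }
    coef[g] = beta;
  }
  return List::create(_["coef"] = coef, _["chisq"] = chisq,
                      _["p"] = pval);
}
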
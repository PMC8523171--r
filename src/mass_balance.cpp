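#include <Rcpp.h>
using namespace Rcpp;

// Free-protein root of the sequential-binding mass balance
//   P = p + R * sum_j(j beta_j p^j) / (1 + sum_j beta_j p^j)
// solved per element by bracketed monotone bisection on the log scale
// (geometric-mean midpoints), which keeps the relative error uniform even
// when the root is many orders of magnitude below P.
// [[Rcpp::export(name = ".mass_balance_free")]]
NumericVector mass_balance_free(NumericVector protein_total,
                                NumericVector rna_total,
                                NumericVector beta,
                                double rel_tol = 1e-12,
                                int max_iter = 200) {
  const int n = protein_total.size();
  const int ns = beta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double P = protein_total[i];
    const double R = rna_total[i];
    if (P <= 0.0) { out[i] = 0.0; continue; }
    if (R <= 0.0) { out[i] = P; continue; }
    double lo = P * 1e-40, hi = P;
    int it = 0;
    for (; it < max_iter; ++it) {
      const double mid = std::sqrt(lo * hi);
      double num = 0.0, den = 1.0, pj = 1.0;
      for (int j = 0; j < ns; ++j) {
        pj *= mid;
        const double term = beta[j] * pj;
        num += (j + 1) * term;
        den += term;
      }
      if (mid + R * num / den > P) hi = mid; else lo = mid;
      if (hi - lo <= rel_tol * lo) break;
    }
    if (it == max_iter && hi - lo > rel_tol * lo) {
      stop("mass-balance root search did not converge");
    }
    out[i] = std::sqrt(lo * hi);
  }
  return out;
}
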
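// Renewal function on a uniform grid.
//
// Solves M(t) = F(t) + int_0^t M(t - s) dF(s) (F the waiting-time cdf) by a
// midpoint Riemann-Stieltjes discretization: the integral over the j-th cell
// uses the Stieltjes mass dF_j = F(t_j) - F(t_{j-1}) against the average of
// M at the cell ends. Only the cdf is evaluated, so laws whose density
// diverges at 0 (Weibull shape < 1) pose no difficulty. O(n^2).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".renewal_mass_cpp")]]
NumericVector renewal_mass_cpp(NumericVector Fgrid) {
  const int n = Fgrid.size() - 1;  // Fgrid[k] = F(k*delta), k = 0..n
  NumericVector M(n + 1);
  std::vector<double> dF(n + 1);
  for (int j = 1; j <= n; ++j) dF[j] = Fgrid[j] - Fgrid[j - 1];
  M[0] = 0.0;
  for (int k = 1; k <= n; ++k) {
    double acc = Fgrid[k] + 0.5 * M[k - 1] * dF[1];
    for (int j = 2; j <= k; ++j) {
      acc += 0.5 * (M[k - j] + M[k - j + 1]) * dF[j];
    }
    M[k] = acc / (1.0 - 0.5 * dF[1]);
  }
  return M;
}
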
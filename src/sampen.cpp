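#include <Rcpp.h>
#include <cmath>
#include <cstdlib>

// Template-match counts for sample entropy (Richman-Moorman convention):
// B = pairs of length-m templates within Chebyshev tolerance r,
// A = the subset whose length-(m+1) extensions also match.
// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return Rcpp::NumericVector::create(A, B);
}
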
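#include <Rcpp.h>
using namespace Rcpp;

// Tabular (recursive) numerator relationship matrix.
// sire/dam are 0-based indices into the ordering, or -1 for unknown.
// Requires parents to precede offspring (validated in R).
// [[Rcpp::export(name = ".amat_tabular")]]
NumericMatrix amat_tabular(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    // diagonal: 1 + F_i, F_i = A(s,d)/2
    if (s >= 0 && d >= 0) {
      A(i, i) = 1.0 + 0.5 * A(s, d);
    } else {
      A(i, i) = 1.0;
    }
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
  }
  return A;
}
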
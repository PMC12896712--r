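#include <Rcpp.h>
using namespace Rcpp;

// Tabular-method numerator relationship matrix. sire/dam are 1-based indices
// into the pedigree (0 = unknown); parents must precede offspring. Unknown
// parents are treated as unrelated, non-inbred founders.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_a(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not topologically ordered at row %d", i + 1);
    A(i, i) = 1.0 + (s >= 0 && d >= 0 ? 0.5 * A(s, d) : 0.0);
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      if (a != 0.0) { A(i, j) = a; A(j, i) = a; }
    }
  }
  return A;
}
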
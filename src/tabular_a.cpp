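#include <Rcpp.h>
using namespace Rcpp;

// Tabular method for the numerator relationship matrix with inbreeding.
// si/di are 1-based indices of sire and dam (0 = unknown), parents first.

// [[Rcpp::export(".tabular_A_cpp")]]
NumericMatrix tabular_A_cpp(IntegerVector si, IntegerVector di) {
  const int n = si.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = si[i] - 1, d = di[i] - 1;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
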
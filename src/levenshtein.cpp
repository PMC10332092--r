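#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost edit distance between two integer token sequences.
// Two-row DP; tokens are arbitrary integer codes.
// [[Rcpp::export(name = ".lev_int")]]
int lev_int(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Final DP row of edit distance of `a` against every prefix of `b`:
// element j (0-based) = lev(a, b[0..j)). Used for split (prefix/suffix)
// matching of derivative-chromosome signatures.
// [[Rcpp::export(name = ".lev_prefix_row")]]
IntegerVector lev_prefix_row(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return IntegerVector(prev.begin(), prev.end());
}
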
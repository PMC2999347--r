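// Built-in folding model: Nussinov-style maximum nested base pairing over
// AU, GC and GU (wobble) pairs with a minimum hairpin loop of `min_loop`
// unpaired bases, scored as `pair_energy` (kcal/mol, negative) per pair.
// This is a structural stand-in for a thermodynamic nearest-neighbor model:
// more pairable structure gives a lower energy, and a sequence admitting no
// pairs scores exactly 0.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// [[Rcpp::export]]
double cpp_nussinov_energy(std::string s, double pair_energy, int min_loop) {
  const int n = (int)s.size();
  if (n == 0) return 0.0;
  auto can_pair = [](char a, char b) {
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
  };
  // N[i][j] = max pairs in s[i..j]; empty/short spans are 0.
  std::vector<std::vector<int>> N(n, std::vector<int>(n, 0));
  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      const int j = i + span - 1;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int v = 1;                          // the (i, k) pair
        if (k - 1 >= i + 1) v += N[i + 1][k - 1];
        if (k + 1 <= j) v += N[k + 1][j];
        best = std::max(best, v);
      }
      N[i][j] = best;
    }
  }
  return pair_energy * N[0][n - 1];
}
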
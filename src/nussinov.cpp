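#include <Rcpp.h>
using namespace Rcpp;

// Minimum base-pair score over all nested (pseudoknot-free) secondary
// structures, Nussinov-style interval dynamic programming.
//
// Bases are encoded A=0, C=1, G=2, U/T=3. Pairing scores are negative
// (default GC -3, AU -2, GU -1); unpairable combinations score 0 and are
// disallowed. Hairpin loops shorter than min_loop are forbidden, i.e. a
// pair (i, k) requires k - i - 1 >= min_loop.

static inline double pair_score(int a, int b, double gc, double au,
                                double gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return gu;
  return 0.0;
}

// [[Rcpp::export(name = ".nussinov_min_energy")]]
double nussinov_min_energy(IntegerVector s, int min_loop, double gc,
                           double au, double gu) {
  int n = s.size();
  if (n == 0) return 0.0;
  NumericMatrix E(n, n); // zero-initialized: empty structure scores 0
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double sc = pair_score(s[i], s[k], gc, au, gu);
        if (sc >= 0.0) continue; // not a pairable combination
        double inner = (k - 1 >= i + 1) ? E(i + 1, k - 1) : 0.0;
        double right = (k + 1 <= j) ? E(k + 1, j) : 0.0;
        double cand = sc + inner + right;
        if (cand < best) best = cand;
      }
      E(i, j) = best;
    }
  }
  return E(0, n - 1);
}
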
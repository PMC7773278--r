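#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Per-window repeatability scan.
//
// codes: n x L integer matrix, one window per row, residues coded 0..n_letters-1.
// For each candidate period p in 1..floor(L/2), positions are partitioned into
// modulo classes C_j = { i : i mod p == j }. Turning the window into a perfect
// repeat of period p costs, per class, the number of positions not carrying the
// class's most frequent residue; MMPR is the minimum total cost over p.
// Partial final repeat units are allowed by construction (class sizes differ by
// at most one when p does not divide L).
//
// Returns n x 4: mmpr, best_period (smallest period attaining the minimum),
// mode_count (highest residue multiplicity), mode_code (alphabetically first
// residue attaining it).
// [[Rcpp::export]]
IntegerMatrix repeat_scan(IntegerMatrix codes, int n_letters) {
  const int n = codes.nrow(), L = codes.ncol();
  if (L < 2)
    stop("windows must have length >= 2 (no admissible repeat period)");
  const int maxp = L / 2;
  IntegerMatrix out(n, 4);
  std::vector<int> cnt;
  for (int r = 0; r < n; ++r) {
    int best = INT_MAX, bestp = 1;
    for (int p = 1; p <= maxp; ++p) {
      cnt.assign((size_t)p * n_letters, 0);
      for (int i = 0; i < L; ++i)
        ++cnt[(size_t)(i % p) * n_letters + codes(r, i)];
      int matched = 0;
      for (int j = 0; j < p; ++j) {
        int m = 0;
        const int off = j * n_letters;
        for (int a = 0; a < n_letters; ++a)
          if (cnt[off + a] > m) m = cnt[off + a];
        matched += m;
      }
      const int cost = L - matched;
      if (cost < best) { best = cost; bestp = p; }
    }
    cnt.assign(n_letters, 0);
    for (int i = 0; i < L; ++i) ++cnt[codes(r, i)];
    int mc = 0, ma = 0;
    for (int a = 0; a < n_letters; ++a)
      if (cnt[a] > mc) { mc = cnt[a]; ma = a; }
    out(r, 0) = best;
    out(r, 1) = bestp;
    out(r, 2) = mc;
    out(r, 3) = ma;
  }
  return out;
}
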
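// Brute-force affine-gap local alignment (score only): the oracle every
// lane-group engine is checked against. Row-major, no wavefront, no tricks.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// -infinity stand-in: large enough that sentinel - alpha - n*beta cannot
// underflow int (asserted in R at scheme construction).
static const int SENTINEL = INT_MIN / 4;

// H(i,j) = max(H(i-1,j-1) + sigma(q_{i-1}, s_{j-1}), E(i,j), F(i,j), 0)
// E(i,j) = max(E(i-1,j) - beta, H(i-1,j) - alpha)   (gap in subject, vertical)
// F(i,j) = max(F(i,j-1) - beta, H(i,j-1) - alpha)   (gap in query, horizontal)
// Boundaries: H(i,0) = H(0,j) = 0; E(0,j) = F(i,0) = -inf;
// E(i,0) = -alpha-(i-1)beta and F(0,j) = -alpha-(j-1)beta (never consulted by
// interior cells but kept for fidelity when full matrices are requested).

// [[Rcpp::export]]
List cpp_sw_full(IntegerVector q, IntegerVector s, IntegerMatrix sigma,
                 int alpha, int beta, bool keep = false) {
  const int m = q.size(), n = s.size();
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, SENTINEL));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, SENTINEL));
  for (int i = 1; i <= m; ++i) E[i][0] = -alpha - (i - 1) * beta;
  for (int j = 1; j <= n; ++j) F[0][j] = -alpha - (j - 1) * beta;
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(E[i - 1][j] - beta, H[i - 1][j] - alpha);
      int f = std::max(F[i][j - 1] - beta, H[i][j - 1] - alpha);
      int h = H[i - 1][j - 1] + sigma(q[i - 1], s[j - 1]);
      h = std::max(std::max(h, e), std::max(f, 0));
      E[i][j] = e; F[i][j] = f; H[i][j] = h;
      if (h > best) best = h;
    }
  }
  List out = List::create(_["score"] = best);
  if (keep) {
    IntegerMatrix Hm(m + 1, n + 1), Em(m + 1, n + 1), Fm(m + 1, n + 1);
    for (int i = 0; i <= m; ++i)
      for (int j = 0; j <= n; ++j) {
        Hm(i, j) = H[i][j]; Em(i, j) = E[i][j]; Fm(i, j) = F[i][j];
      }
    out["H"] = Hm; out["E"] = Em; out["F"] = Fm;
  }
  return out;
}

// Two-row rolling variant, O(min(m,n)) memory. Swapping Q and S is safe for
// the symmetric sigma used here; the R wrapper performs the swap.
// [[Rcpp::export]]
int cpp_sw_linear(IntegerVector q, IntegerVector s, IntegerMatrix sigma,
                  int alpha, int beta) {
  const int m = q.size(), n = s.size();
  std::vector<int> Hup(n + 1, 0), Eup(n + 1, SENTINEL);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int hdiag = 0;      // H(i-1, j-1)
    int hleft = 0;      // H(i, j-1)
    int f = SENTINEL;   // F(i, j-1) -> F(i, 0) = -inf
    for (int j = 1; j <= n; ++j) {
      int e = std::max(Eup[j] - beta, Hup[j] - alpha);
      f = std::max(f - beta, hleft - alpha);
      int h = hdiag + sigma(q[i - 1], s[j - 1]);
      h = std::max(std::max(h, e), std::max(f, 0));
      hdiag = Hup[j];
      Hup[j] = h; Eup[j] = e; hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}
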
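// Packed pairwise substitution table: a |S| x |S|^2 matrix in which entry
// (q, s1*|S| + s2) carries sigma(q, s1) and sigma(q, s2) as the low and high
// 16-bit halves of one 32-bit word, so one access yields both scores.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_build_packed(IntegerMatrix sigma) {
  const int n = sigma.nrow();
  IntegerMatrix out(n, n * n);
  for (int q = 0; q < n; ++q)
    for (int s1 = 0; s1 < n; ++s1)
      for (int s2 = 0; s2 < n; ++s2) {
        const uint32_t lo = (uint16_t)(int16_t)sigma(q, s1);
        const uint32_t hi = (uint16_t)(int16_t)sigma(q, s2);
        out(q, s1 * n + s2) = (int)(lo | (hi << 16));
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_pair(int packed) {
  IntegerVector out(2);
  out[0] = (int)(int16_t)((uint32_t)packed & 0xFFFFu);
  out[1] = (int)(int16_t)((uint32_t)packed >> 16);
  return out;
}
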
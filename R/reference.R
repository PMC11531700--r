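#' Reference Smith-Waterman score (full dynamic-programming matrix)
#'
#' Brute-force affine-gap local alignment, the ground-truth oracle for every
#' lane-group engine in the package. Computes
#' `H(i,j) = max(H(i-1,j-1) + sigma(q_i, s_j), E(i,j), F(i,j), 0)` with
#' `E(i,j) = max(E(i-1,j) - beta, H(i-1,j) - alpha)` and
#' `F(i,j) = max(F(i,j-1) - beta, H(i,j-1) - alpha)`; boundaries
#' `H(i,0) = H(0,j) = 0`, `E(i,0) = -alpha-(i-1)beta`,
#' `F(0,j) = -alpha-(j-1)beta`, remaining boundary E/F at a large negative
#' sentinel standing in for minus infinity. The score is the maximum over H;
#' no traceback is computed.
#'
#' @param Q,S residue strings or 0-based encoded integer vectors; non-empty.
#' @param scheme a [ScoringScheme-class].
#' @param keep if `TRUE` also return the full `H`, `E`, `F` matrices
#'   (rows/cols 0..m, 0..n) for debugging.
#' @return A list with `score` (non-negative integer) and, if requested,
#'   `H`, `E`, `F`.
#' @examples
#' bl62 <- loadBuiltinScheme("blosum62", 11, 1)
#' swScoreFull("AAAA", "AAAA", bl62)$score  # 16
#' @export
swScoreFull <- function(Q, S, scheme, keep = FALSE) {
  q <- asCodes(Q, scheme)
  s <- asCodes(S, scheme)
  cpp_sw_full(q, s, scheme@sigma, scheme@alpha, scheme@beta, keep)
}

#' Reference Smith-Waterman score in linear space
#'
#' Same score as [swScoreFull()] using memory proportional to `min(m, n)`
#' (the shorter sequence indexes the rolling rows; sigma symmetry makes the
#' swap safe).
#'
#' @inheritParams swScoreFull
#' @return The integer score.
#' @export
swScoreLinear <- function(Q, S, scheme) {
  q <- asCodes(Q, scheme)
  s <- asCodes(S, scheme)
  if (length(s) > length(q)) { tmp <- q; q <- s; s <- tmp }
  cpp_sw_linear(q, s, scheme@sigma, scheme@alpha, scheme@beta)
}

# Normalize a string / encoded vector to 0-based codes and reject empties.
asCodes <- function(x, scheme) {
  if (is.character(x)) x <- encodeSequence(x, scheme@alphabet)
  x <- as.integer(x)
  if (length(x) == 0L) stop("empty sequence")
  if (any(x < 0L | x > scheme@alphabet@padCode))
    stop("residue code outside the alphabet")
  x
}
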
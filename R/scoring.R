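#' Parse an NCBI-format substitution matrix file
#'
#' Reads the plain-text matrix format used by the NCBI BLAST distribution:
#' `#` comment lines, a header row of column symbols, then one labelled row
#' per symbol.
#'
#' @param path file path.
#' @return Integer matrix with symbol dimnames.
#' @export
readNcbiMatrix <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  cols <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(ln[-1]), "\\s+")
  rn <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1]))
  if (any(lengths(vals) != length(cols)))
    stop("malformed matrix file: row width does not match header")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rn, cols)
  m
}

#' Load a built-in scoring scheme
#'
#' Built-ins are `"blosum62"` and `"blosum50"`, shipped as plain-text
#' NCBI-format matrix files and parsed at load. The pad row/column is scored
#' `-(alpha + max|sigma| + 1)` against everything, so padded columns can
#' never start or extend a local alignment.
#'
#' @param name `"blosum62"` or `"blosum50"`.
#' @param alpha gap-open penalty (cost of the first gap position).
#' @param beta gap-extension penalty; a gap of length g costs
#'   `alpha + (g-1) * beta`. Require `alpha >= beta >= 1`.
#' @return A [ScoringScheme-class].
#' @examples
#' bl62 <- loadBuiltinScheme("blosum62", alpha = 11, beta = 1)
#' sigmaScore(bl62, "A", "A")  # 4
#' @export
loadBuiltinScheme <- function(name = c("blosum62", "blosum50"),
                              alpha = 11L, beta = 1L) {
  if (!is.character(name) || !name[1] %in% c("blosum62", "blosum50"))
    stop("unknown scheme '", name[1],
         "'; built-ins are: blosum62, blosum50")
  name <- name[1]
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "swWavefront", mustWork = TRUE)
  scoringScheme(name, readNcbiMatrix(path), alpha, beta)
}

#' Build a scoring scheme from a substitution matrix
#'
#' @param name scheme label.
#' @param mat integer matrix with symbol dimnames covering the canonical
#'   alphabet (extra symbols are ignored, order is normalized).
#' @inheritParams loadBuiltinScheme
#' @return A [ScoringScheme-class].
#' @export
scoringScheme <- function(name, mat, alpha, beta) {
  alpha <- as.integer(alpha); beta <- as.integer(beta)
  if (is.na(alpha) || is.na(beta) || alpha < beta || beta < 1L)
    stop("require alpha >= beta >= 1")
  ab <- aaAlphabet()
  syms <- ab@symbols
  if (!all(syms %in% rownames(mat)))
    stop("matrix must cover all alphabet symbols")
  res <- mat[syms, syms]
  ns <- length(syms)
  sigma <- matrix(0L, ns + 1L, ns + 1L)
  sigma[seq_len(ns), seq_len(ns)] <- res
  padScore <- -(alpha + max(abs(res)) + 1L)
  sigma[ns + 1L, ] <- padScore
  sigma[, ns + 1L] <- padScore
  dimnames(sigma) <- list(c(syms, "pad"), c(syms, "pad"))
  new("ScoringScheme", name = name, alphabet = ab, sigma = sigma,
      alpha = alpha, beta = beta)
}

#' Accessors for scoring schemes
#'
#' `sigmaMatrix` returns the residue-only substitution matrix;
#' `sigmaScore` the score of a residue pair; `gapOpen`/`gapExtend` the
#' affine gap parameters.
#'
#' @param scheme a [ScoringScheme-class].
#' @param a,b residue characters or 0-based codes.
#' @export
sigmaMatrix <- function(scheme) {
  ns <- length(scheme@alphabet@symbols)
  scheme@sigma[seq_len(ns), seq_len(ns)]
}

#' @rdname sigmaMatrix
#' @export
sigmaScore <- function(scheme, a, b) {
  toCode <- function(x) {
    if (is.character(x)) match(toupper(x), scheme@alphabet@symbols) - 1L
    else as.integer(x)
  }
  scheme@sigma[toCode(a) + 1L, toCode(b) + 1L]
}

#' @rdname sigmaMatrix
#' @export
gapOpen <- function(scheme) scheme@alpha

#' @rdname sigmaMatrix
#' @export
gapExtend <- function(scheme) scheme@beta

#' Build the packed pairwise substitution table
#'
#' Lays sigma out so that one lookup of a query code against a packed pair
#' of subject codes yields both scores in a single 32-bit access, as used by
#' the packed 16-bit engine modes.
#'
#' @param scheme a [ScoringScheme-class].
#' @return A [PackedSubstitutionTable-class].
#' @export
buildPackedTable <- function(scheme) {
  tab <- cpp_build_packed(scheme@sigma)
  new("PackedSubstitutionTable", table = tab, nsym = nrow(scheme@sigma))
}

#' Look up a packed score pair
#'
#' @param pt a [PackedSubstitutionTable-class].
#' @param q,s1,s2 0-based codes.
#' @return Integer vector `c(sigma[q,s1], sigma[q,s2])`.
#' @export
packedLookup <- function(pt, q, s1, s2) {
  cpp_unpack_pair(pt@table[q + 1L, packIndex(pt, s1, s2)])
}

#' @rdname packedLookup
#' @export
packIndex <- function(pt, s1, s2) s1 * pt@nsym + s2 + 1L
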
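test_that("encoding follows the canonical order and round-trips", {
  ab <- aaAlphabet()
  expect_identical(paste(alphabetSymbols(ab), collapse = ""),
                   "ARNDCQEGHILKMFPSTWYVBZX*")
  expect_identical(encodeSequence("A"), 0L)
  expect_identical(encodeSequence("AR"), c(0L, 1L))
  # unknown letters collapse to the ambiguity code X
  xcode <- match("X", alphabetSymbols(ab)) - 1L
  expect_identical(encodeSequence("AJA"), c(0L, xcode, 0L))
  expect_identical(encodeSequence("aUo"), c(0L, xcode, xcode))
  # round trip over every symbol
  all <- paste(alphabetSymbols(ab), collapse = "")
  expect_identical(decodeSequence(encodeSequence(all)), all)
  # pad codes are dropped on decode
  expect_identical(decodeSequence(c(0L, padCode(ab), 1L)), "AR")
})

test_that("encoding rejects empty and non-letter input with position", {
  expect_error(encodeSequence(""), "non-empty")
  expect_error(encodeSequence("AR1N"), "position 3")
  expect_error(encodeSequence("A N"), "position 2")
})

test_that("built-in schemes carry the standard matrices and gap parameters", {
  expect_identical(gapOpen(bl62), 11L)
  expect_identical(gapExtend(bl62), 1L)
  expect_identical(gapOpen(bl50), 13L)
  expect_identical(gapExtend(bl50), 2L)
  expect_identical(sigmaScore(bl62, "A", "A"), 4L)
  expect_identical(sigmaScore(bl62, "W", "W"), 11L)
  expect_identical(sigmaScore(bl50, "W", "W"), 15L)
  expect_error(loadBuiltinScheme("pam250"), "blosum62")
  expect_error(loadBuiltinScheme("blosum62", alpha = 1, beta = 2),
               "alpha >= beta")
})

test_that("both built-in matrices are symmetric and 8-bit", {
  for (s in list(bl62, bl50)) {
    m <- sigmaMatrix(s)
    expect_identical(m, t(m))
    expect_lte(max(abs(m)), 127L)
  }
})

test_that("built-in matrices agree with independently distributed values", {
  # Biostrings ships its own copies; BLOSUM50 matches entry for entry, and
  # BLOSUM62 matches on all standard residues (distributions differ in the
  # B/Z/X ambiguity conventions).
  bs50 <- get(data("BLOSUM50", package = "Biostrings",
                   envir = environment()))
  sy <- rownames(sigmaMatrix(bl50))
  expect_identical(unname(sigmaMatrix(bl50)),
                   unname(matrix(as.integer(bs50[sy, sy]), length(sy))))
  bs62 <- get(data("BLOSUM62", package = "Biostrings",
                   envir = environment()))
  expect_identical(unname(sigmaMatrix(bl62)[STD20, STD20]),
                   unname(matrix(as.integer(bs62[STD20, STD20]), 20)))
})

test_that("pad scores can never start or extend an alignment", {
  pad <- padCode(aaAlphabet())
  padRow <- bl62@sigma[pad + 1L, ]
  expect_true(all(padRow <= -(gapOpen(bl62) + max(abs(sigmaMatrix(bl62))))))
  # an all-pad subject scores zero
  cfg <- kernelConfig(4, 8)
  res <- cpp_lane_align(encodeSequence("ARNDW"), rep(pad, 10L), bl62@sigma,
                        pad, 11L, 1L, 4L, 8L, 0L, FALSE, FALSE)
  expect_identical(res$score, 0L)
})

test_that("packed table reproduces every sigma pair exhaustively", {
  pt <- buildPackedTable(bl62)
  ns <- pt@nsym
  # vectorized exhaustive check over all |alphabet|^3 (q, s1, s2) triples
  grid <- expand.grid(q = 0:(ns - 1L), s1 = 0:(ns - 1L), s2 = 0:(ns - 1L))
  packed <- as.numeric(pt@table[cbind(grid$q + 1L, grid$s1 * ns + grid$s2 + 1L)])
  u <- ifelse(packed < 0, packed + 2^32, packed)
  lo <- u %% 65536
  lo <- ifelse(lo >= 32768, lo - 65536, lo)
  hi <- u %/% 65536
  hi <- ifelse(hi >= 32768, hi - 65536, hi)
  expect_identical(as.integer(lo),
                   as.integer(bl62@sigma[cbind(grid$q + 1L, grid$s1 + 1L)]))
  expect_identical(as.integer(hi),
                   as.integer(bl62@sigma[cbind(grid$q + 1L, grid$s2 + 1L)]))
  # symmetry of the packing: equal halves when both subjects agree
  pair <- packedLookup(pt, 0L, 4L, 4L)
  expect_identical(pair[1], pair[2])
  expect_identical(packedLookup(pt, 0L, 0L, 1L),
                   c(sigmaScore(bl62, "A", "A"), sigmaScore(bl62, "A", "R")))
})
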
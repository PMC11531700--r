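# Background residue frequencies (Robinson-Robinson, as used for BLOSUM62
# statistics); order matches the first 20 alphabet symbols ARNDCQEGHILKMFPSTWYV.
blosumBackground <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
}

# run code under a fixed RNG state without disturbing the caller's stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

randomResidues <- function(n, background = c("blosum62", "uniform")) {
  background <- match.arg(background)
  syms <- alphabetSymbols(aaAlphabet())[1:20]
  prob <- if (background == "blosum62") blosumBackground() else rep(1 / 20, 20)
  sample(syms, n, replace = TRUE, prob = prob)
}

fastaText <- function(ids, seqs, width = 60L) {
  out <- character(0)
  for (i in seq_along(seqs)) {
    chunks <- substring(seqs[i], seq(1, nchar(seqs[i]), width),
                        pmin(seq(1, nchar(seqs[i]), width) + width - 1L,
                             nchar(seqs[i])))
    out <- c(out, paste0(">", ids[i]), chunks)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Generate an equal-length synthetic database
#'
#' n protein sequences all of length L, residues drawn from the BLOSUM62
#' background frequencies (or uniformly), deterministic under the seed —
#' the same call always produces byte-identical FASTA text. Emulates the
#' equal-length benchmark databases (lengths 128, 256, 512, 1024, 2048) at
#' any scale.
#'
#' @param n number of sequences (>= 1).
#' @param L sequence length (>= 1).
#' @param seed RNG seed.
#' @param background `"blosum62"` or `"uniform"` residue distribution.
#' @return FASTA text as a single character scalar.
#' @export
genEqualLengthDb <- function(n, L, seed, background = "blosum62") {
  stopifnot(n >= 1, L >= 1)
  withSeed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(randomResidues(L, background), collapse = ""), "")
    fastaText(sprintf("syn|eq%06d len=%d", seq_len(n), L), seqs)
  })
}

# mean of a lognormal capped at `cap`:
# E[min(X, cap)] = e^{mu + s^2/2} Phi((ln cap - mu - s^2)/s)
#                  + cap (1 - Phi((ln cap - mu)/s))
cappedLnormMean <- function(mu, sdlog, cap) {
  exp(mu + sdlog^2 / 2) * pnorm((log(cap) - mu - sdlog^2) / sdlog) +
    cap * (1 - pnorm((log(cap) - mu) / sdlog))
}

#' Generate a length-distributed synthetic database
#'
#' Sequence lengths follow a log-normal (sdlog = 1) whose meanlog is solved
#' so the capped mean matches `meanLen`, hard-capped at `maxLen` — emulating
#' real protein databases, whose length distributions are long-tailed with a
#' mean near 361 and rare very long outliers. For `n >= 1000` the empirical
#' mean lands within 10% of `meanLen`.
#'
#' @param n number of sequences.
#' @param meanLen target mean length.
#' @param maxLen hard length cap.
#' @param seed RNG seed.
#' @param background residue distribution as in [genEqualLengthDb()].
#' @return FASTA text as a single character scalar.
#' @export
genDistributedDb <- function(n, meanLen = 361, maxLen = 35213, seed = 1L,
                             background = "blosum62") {
  stopifnot(n >= 1, meanLen >= 1, meanLen <= maxLen)
  sdlog <- 1
  mu <- uniroot(function(m) cappedLnormMean(m, sdlog, maxLen) - meanLen,
                interval = c(log(meanLen) - 6, log(meanLen) + 2))$root
  withSeed(seed, {
    lens <- pmax(1L, pmin(as.integer(maxLen),
                          as.integer(round(rlnorm(n, mu, sdlog)))))
    seqs <- vapply(lens, function(L)
      paste(randomResidues(L, background), collapse = ""), "")
    fastaText(sprintf("syn|ln%06d len=%d", seq_len(n), lens), seqs)
  })
}

#' Construct a pair guaranteed to overflow a score threshold
#'
#' Repeats the highest-scoring self-pair residue often enough that the
#' exact local alignment score reaches at least `targetScore` — the
#' adversarial input for the 16-bit overflow machinery.
#'
#' @param scheme a [ScoringScheme-class].
#' @param targetScore required minimum oracle score (>= 1).
#' @param maxLen longest sequence the generator may emit.
#' @return List with residue strings `Q` and `S` (identical repeats) and
#'   the guaranteed `minScore`.
#' @export
genOverflowPair <- function(scheme, targetScore, maxLen = 50000L) {
  stopifnot(targetScore >= 1)
  res <- sigmaMatrix(scheme)
  diag20 <- diag(res)[1:20]
  best <- which.max(diag20)
  reps <- ceiling(targetScore / diag20[best])
  if (reps > maxLen)
    stop(sprintf("target %d needs %d repeats, above the %d cap",
                 targetScore, reps, maxLen))
  s <- paste(rep(alphabetSymbols(scheme@alphabet)[best], reps),
             collapse = "")
  list(Q = s, S = s, minScore = reps * diag20[[best]])
}

#' Write FASTA text to a file
#'
#' @param text FASTA text from a generator.
#' @param path output path; a `.gz` suffix writes gzip-compressed.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(text, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeBin(charToRaw(text), con)
  close(con)
  invisible(path)
}

#' Named fixture presets
#'
#' `d128`..`d2048` give equal-length databases; `swissprot-like` gives the
#' length-distributed model with mean 361 capped at 35,213.
#'
#' @param preset preset name.
#' @param n number of sequences.
#' @param seed RNG seed.
#' @return FASTA text.
#' @export
fixturePreset <- function(preset = c("d128", "d256", "d512", "d1024",
                                     "d2048", "swissprot-like"),
                          n = 1000L, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "swissprot-like") genDistributedDb(n, 361, 35213, seed)
  else genEqualLengthDb(n, as.integer(sub("^d", "", preset)), seed)
}
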
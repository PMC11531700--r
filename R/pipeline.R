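#' Scan parameters
#'
#' @param topK hits reported per query (>= 1).
#' @param precision `"auto16"` — saturating 16-bit first pass, then exact
#'   wide-integer recompute of flagged subjects — or `"wide32"` throughout.
#' @param residueBudget residues per batch (see [iterateBatches()]).
#' @param nWorkers worker partitions (results are worker-count invariant).
#' @param scheme a [ScoringScheme-class].
#' @return A named list of validated parameters.
#' @export
scanParams <- function(topK = 10L, precision = c("auto16", "wide32"),
                       residueBudget = 64e6, nWorkers = 1L,
                       scheme = loadBuiltinScheme("blosum62", 11, 1)) {
  precision <- match.arg(precision)
  topK <- as.integer(topK)
  stopifnot(topK >= 1L, nWorkers >= 1L, residueBudget >= 1)
  list(topK = topK, precision = precision, residueBudget = residueBudget,
       nWorkers = as.integer(nWorkers), scheme = scheme)
}

# score one set of db indices with bin-dispatched engines; returns scores
# and overflow flags (mode: "wide32" or "int16sat")
scoreIndices <- function(db, qcodes, indices, scheme, mode) {
  if (length(indices) == 0L)
    return(list(score = integer(0), overflow = logical(0)))
  bins <- partitionByLength(db@lengths[indices])
  p <- integer(length(indices)); k <- integer(length(indices))
  tiled <- logical(length(indices))
  for (b in unique(bins)) {
    cfg <- selectKernelConfig(b)
    sel <- bins == b
    p[sel] <- cfg@p; k[sel] <- cfg@k; tiled[sel] <- cfg@tiled
  }
  cpp_scan_batch(qcodes, db@residues, db@offsets[indices],
                 db@lengths[indices], p, k, tiled, scheme@sigma,
                 scheme@alphabet@padCode, scheme@alpha, scheme@beta,
                 precisionMode(mode))
}

#' Scan a database with one or more queries
#'
#' The full workflow: every database sequence is scored once per query with
#' the engine configuration of its length bin (tiled for the long bin).
#' Under the `auto16` policy the first pass runs in saturating 16-bit
#' arithmetic and subjects whose scores overflow are rescored exactly in
#' wide-integer arithmetic ([recomputeOverflows()]); final scores are
#' therefore identical to a `wide32` scan. With several workers the
#' database is partitioned by [assignToWorkers()], each partition is
#' scanned in batches under the residue budget, and the per-worker hit
#' lists are merged ([mergeWorkerResults()]); results are independent of
#' the worker count.
#'
#' @param db a [LocalDB-class] (or a database directory path).
#' @param queries named character vector of residue strings, or an
#'   `AAStringSet`; queries with invalid (non-letter) characters are
#'   rejected before any scanning.
#' @param params a [scanParams()] list.
#' @param fullScores also attach the complete per-sequence score vector as
#'   attribute `"scores"` of each hit list.
#' @return Named list (one element per query) of hit-list data.frames with
#'   columns `rank`, `subject`, `score`, `dbIndex`, sorted by descending
#'   score (ties: ascending subject id, then ascending database index) and
#'   truncated to `topK` rows.
#' @export
scanDb <- function(db, queries, params = scanParams(), fullScores = FALSE) {
  if (is.character(db) && length(db) == 1L) db <- loadDb(db)
  stopifnot(is(db, "LocalDB"), dbCount(db) >= 1L)
  queries <- asQuerySet(queries)
  scheme <- params$scheme
  qcodesList <- lapply(queries, encodeSequence, alphabet = scheme@alphabet)
  parts <- assignToWorkers(db, params$nWorkers)
  out <- vector("list", length(queries))
  names(out) <- names(queries)
  for (qi in seq_along(queries)) {
    qcodes <- qcodesList[[qi]]
    perWorker <- vector("list", length(parts$workers))
    allScores <- integer(dbCount(db))
    for (w in seq_along(parts$workers)) {
      idx <- parts$workers[[w]]
      scores <- integer(length(idx))
      pos <- 1L
      for (bstart in splitBatches(as.numeric(db@lengths[idx]),
                                  params$residueBudget)) {
        bidx <- idx[bstart$from:bstart$to]
        firstMode <- if (params$precision == "auto16") "int16sat" else "wide32"
        res <- scoreIndices(db, qcodes, bidx, scheme, firstMode)
        sc <- res$score
        if (params$precision == "auto16" && any(res$overflow))
          sc[res$overflow] <- recomputeOverflows(db, qcodes,
                                                 bidx[res$overflow], scheme)
        scores[pos:(pos + length(bidx) - 1L)] <- sc
        pos <- pos + length(bidx)
      }
      allScores[idx] <- scores
      perWorker[[w]] <- rankHits(db, idx, scores, params$topK)
    }
    hits <- mergeWorkerResults(perWorker, params$topK)
    if (fullScores) attr(hits, "scores") <- allScores
    out[[qi]] <- hits
  }
  out
}

#' Rescore overflowed subjects in wide-integer arithmetic
#'
#' @param db a [LocalDB-class].
#' @param query residue string or encoded query.
#' @param flags database indices flagged by a 16-bit pass.
#' @param scheme a [ScoringScheme-class].
#' @return Integer vector of exact scores, one per flagged index (empty
#'   flags are a no-op).
#' @export
recomputeOverflows <- function(db, query, flags, scheme) {
  if (length(flags) == 0L) return(integer(0))
  qcodes <- asCodes(query, scheme)
  scoreIndices(db, qcodes, flags, scheme, "wide32")$score
}

#' Merge per-worker hit lists
#'
#' @param perWorker list of hit-list data.frames, each internally sorted.
#' @param topK hits retained after the merge.
#' @return A single hit list identical to a single-worker run's.
#' @export
mergeWorkerResults <- function(perWorker, topK) {
  all <- do.call(rbind, perWorker)
  all <- all[order(-all$score, all$subject, all$dbIndex), , drop = FALSE]
  all <- head(all, topK)
  all$rank <- seq_len(nrow(all))
  rownames(all) <- NULL
  all[, c("rank", "subject", "score", "dbIndex")]
}

rankHits <- function(db, indices, scores, topK) {
  hl <- data.frame(rank = NA_integer_, subject = db@ids[indices],
                   score = scores, dbIndex = indices)
  hl <- hl[order(-hl$score, hl$subject, hl$dbIndex), , drop = FALSE]
  hl <- head(hl, topK)
  hl$rank <- seq_len(nrow(hl))
  rownames(hl) <- NULL
  hl
}

# contiguous sub-batches of a worker's index list under the residue budget
splitBatches <- function(lens, budget) {
  out <- list(); i <- 1L; n <- length(lens)
  while (i <= n) {
    tot <- lens[i]; j <- i
    while (j < n && tot + lens[j + 1L] <= budget) {
      j <- j + 1L; tot <- tot + lens[j]
    }
    out[[length(out) + 1L]] <- list(from = i, to = j)
    i <- j + 1L
  }
  out
}

asQuerySet <- function(queries) {
  if (is(queries, "AAStringSet")) {
    q <- as.character(queries)
    names(q) <- names(queries)
    queries <- q
  }
  stopifnot(is.character(queries), length(queries) >= 1L)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    names(queries) <- paste0("query", seq_along(queries))
  queries
}

#' Interactive search session
#'
#' Loads a database once and serves repeated scans against it; the load
#' counter exposes that multi-query scans reuse the loaded database.
#'
#' @param dbDir database directory.
#' @return An environment with the loaded `db` and `loadCount`.
#' @export
searchSession <- function(dbDir) {
  ses <- new.env(parent = emptyenv())
  ses$db <- loadDb(dbDir)
  ses$loadCount <- 1L
  ses$scans <- 0L
  ses
}

#' @rdname searchSession
#' @param session a [searchSession()].
#' @inheritParams scanDb
#' @export
sessionScan <- function(session, queries, params = scanParams(), ...) {
  session$scans <- session$scans + 1L
  scanDb(session$db, queries, params, ...)
}
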
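#' Align a subject of any length with the tiled multi-stage engine
#'
#' Splits the DP matrix into `l = ceiling(n / (k * p))` column chunks
#' processed left to right by one lane group. Within a stage the rightmost
#' lane's boundary-column (H, F) values accumulate in a p-slot buffer that
#' is shifted once per iteration and flushed in blocks of p rows, emulating
#' a coalesced write; the next stage's leftmost lane reads exactly those
#' stored values (the first stage reads the initialization boundary). The
#' running maximum and overflow flags carry across stages, so overflow
#' semantics match the untiled engine, and in `wide32` mode the final score
#' equals [swScoreFull()] exactly.
#'
#' @inheritParams alignGroup
#' @param S subject of any length `n >= 1`.
#' @return As [alignGroup()]; `stages` is the number of column chunks, and
#'   under `debug = TRUE` `boundaryH`/`boundaryF` hold each stage's boundary
#'   store (rows 0..m).
#' @export
alignTiled <- function(Q, S, config, scheme, debug = FALSE) {
  q <- asCodes(Q, scheme)
  s <- asCodes(S, scheme)
  res <- cpp_lane_align(q, s, scheme@sigma, scheme@alphabet@padCode,
                        scheme@alpha, scheme@beta, config@p, config@k,
                        precisionMode(config@precision), TRUE, debug)
  laneResult(res, config@precision)
}

#' Flush a boundary buffer into a stage store
#'
#' The write-side contract of the tiling scheme: a buffer of p row entries
#' `(row, H, F)` is appended to the stage store in row order and reset. A
#' partially filled buffer may only be flushed at the final wavefront drain
#' (`final = TRUE`); rows outside 1..m (wavefront ramp-up/drain slots) are
#' discarded.
#'
#' @param buffer data.frame with columns `row`, `H`, `F`.
#' @param store data.frame with the same columns (rows appended in order).
#' @param p lanes per group (the full buffer size).
#' @param final allow a partial flush at the wavefront drain.
#' @return List with the updated `store` and an emptied `buffer`.
#' @export
flushBoundary <- function(buffer, store, p, final = FALSE) {
  if (nrow(buffer) < p && !final)
    stop("partial flush only allowed at the final wavefront drain")
  if (nrow(buffer) > p) stop("buffer overfilled beyond p rows")
  keep <- buffer[buffer$row >= 1, , drop = FALSE]
  list(store = rbind(store, keep[order(keep$row), , drop = FALSE]),
       buffer = buffer[0, , drop = FALSE])
}

#' Number of tile stages for a subject length
#'
#' @param n subject length.
#' @param config a [KernelConfig-class].
#' @return `ceiling(n / (k * p))`.
#' @export
tileStages <- function(n, config) as.integer(ceiling(n / (config@k * config@p)))
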
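#' Maximum DP columns per lane
#'
#' The register-pressure ceiling on columns computed per lane, fixed at 40;
#' with the widest group (p = 32) this caps the untiled subject length at
#' `32 * 40 = 1280`. Longer subjects are dispatched to the tiled engine.
#'
#' @return Integer, 40.
#' @export
kMaxColumns <- function() 40L

#' Construct a lane-group kernel configuration
#'
#' @param p lanes per group; one of 2, 4, 8, 16, 32.
#' @param k columns per lane, 1..[kMaxColumns()].
#' @param precision `"wide32"` (exact, never flags), `"int16sat"`
#'   (saturating signed 16-bit; flags at 32767) or `"fp16emu"` (exact below
#'   the half-float precision-loss region; flags at 2048).
#' @param packed two subjects per group (16-bit precisions only).
#' @param tiled dispatch through the multi-stage tiled engine.
#' @return A [KernelConfig-class].
#' @export
kernelConfig <- function(p, k = 32L, precision = "wide32", packed = FALSE,
                         tiled = FALSE) {
  new("KernelConfig", p = as.integer(p), k = as.integer(k),
      precision = precision, packed = isTRUE(packed), tiled = isTRUE(tiled))
}

#' Shuffle-style shift-up exchange across lanes
#'
#' Lane t receives the value lane `t - offset` held; lanes `t < offset` keep
#' their own value, mirroring the out-of-range contract of a hardware
#' shuffle-up.
#'
#' @param values one value per lane.
#' @param offset shift distance, `0 <= offset < length(values)`.
#' @return Vector of the same length.
#' @examples
#' shiftUpExchange(c(10, 20, 30, 40), 1)  # 10 10 20 30
#' @export
shiftUpExchange <- function(values, offset) {
  p <- length(values)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= p) stop("require 0 <= offset < p")
  if (offset == 0L) return(values)
  out <- values
  out[(offset + 1L):p] <- values[seq_len(p - offset)]
  out
}

#' Query-character rotation state
#'
#' The two-register scheme by which lanes receive query characters without
#' rereading memory: every p iterations lane t loads code `q[i + t]` into
#' its `cqNext` register (pad beyond the query); each iteration `cqCurrent`
#' is shuffled up by one lane, lane 0 refills its `cqCurrent` from `cqNext`,
#' and `cqNext` is shuffled down. The net effect is that at (0-based)
#' iteration i lane t holds query code `q[i - t]`.
#'
#' @param p lanes per group.
#' @param pad pad code filling registers before/after the query.
#' @return A list with `cqCurrent` and `cqNext` vectors (one slot per lane).
#' @export
rotationState <- function(p, pad = padCode(aaAlphabet())) {
  list(cqCurrent = rep(pad, p), cqNext = rep(pad, p))
}

#' Advance the query rotation by one iteration
#'
#' @param state a [rotationState()].
#' @param iteration 0-based iteration index.
#' @param qcodes encoded query.
#' @param pad pad code.
#' @return Updated state; `state$cqCurrent[t+1]` is the code lane t uses at
#'   this iteration.
#' @export
rotateQueryChars <- function(state, iteration, qcodes,
                             pad = padCode(aaAlphabet())) {
  p <- length(state$cqCurrent)
  m <- length(qcodes)
  if (iteration %% p == 0L) {
    idx <- iteration + seq_len(p) - 1L          # lane t loads q[iteration + t]
    state$cqNext <- ifelse(idx < m, qcodes[idx + 1L], pad)
  }
  state$cqCurrent <- shiftUpExchange(state$cqCurrent, 1L)
  state$cqCurrent[1L] <- state$cqNext[1L]       # lane 0 copies cqNext
  state$cqNext <- c(state$cqNext[-1L], state$cqNext[p])  # shuffle-down
  state
}

#' Full rotation schedule
#'
#' Runs [rotateQueryChars()] over all iterations and returns the matrix of
#' `cqCurrent` codes: row i (0-based iteration), column t (lane). Equals the
#' closed-form schedule `q[i - t]` wherever `0 <= i - t < m` — the rotation
#' is independent of subject content.
#'
#' @inheritParams rotateQueryChars
#' @param p lanes per group.
#' @param iters number of iterations (typically `m + p`).
#' @return `iters` x `p` integer matrix.
#' @export
laneQuerySchedule <- function(qcodes, p, iters = length(qcodes) + p,
                              pad = padCode(aaAlphabet())) {
  st <- rotationState(p, pad)
  out <- matrix(NA_integer_, iters, p)
  for (i in seq_len(iters)) {
    st <- rotateQueryChars(st, i - 1L, qcodes, pad)
    out[i, ] <- st$cqCurrent
  }
  out
}

#' Align one subject with a single lane group
#'
#' Emulates the lockstep wavefront: in each of exactly `m + p` iterations,
#' lane t computes the k cells of DP row `i - t` in its own columns,
#' looking substitution scores up row-first (the row selected by the lane's
#' current query character), then passes its rightmost H and F to the next
#' lane shuffle-style; the diagonal H is the value exchanged two iterations
#' earlier. The final score is the lane-wise running maximum reduced across
#' the group. In `wide32` mode the score equals [swScoreFull()] exactly.
#'
#' @param Q,S residue strings or encoded vectors; `length(S) <= p * k`.
#' @param config a [KernelConfig-class] (untiled).
#' @param scheme a [ScoringScheme-class].
#' @param debug if `TRUE` also return the cell-coverage bitmap, the
#'   per-iteration query-character schedule and the boundary stores.
#' @return List with `score`, `overflow` (`NULL`, or a list with
#'   `subject_index` and `reason`), `iterations`, `stages` and debug fields.
#' @export
alignGroup <- function(Q, S, config, scheme, debug = FALSE) {
  q <- asCodes(Q, scheme)
  s <- asCodes(S, scheme)
  span <- config@p * config@k
  if (length(s) > span)
    stop(sprintf(paste0("subject length %d exceeds the group span p*k = %d;",
                        " use alignTiled()"), length(s), span))
  res <- cpp_lane_align(q, s, scheme@sigma, scheme@alphabet@padCode,
                        scheme@alpha, scheme@beta, config@p, config@k,
                        precisionMode(config@precision), FALSE, debug)
  laneResult(res, config@precision)
}

#' Align two subjects packed into one lane group
#'
#' Both subjects are computed simultaneously in the two 16-bit halves of the
#' group's registers; substitution scores come from one access to the packed
#' pairwise table ([buildPackedTable()]). Scores and overflow flags are
#' independent per subject.
#'
#' @param Q query; `Sa`, `Sb` subjects, each at most `p * k` residues.
#' @param config a packed 16-bit [KernelConfig-class].
#' @param scheme a [ScoringScheme-class].
#' @return List of two results as in [alignGroup()], named `a` and `b`.
#' @export
alignGroupPacked <- function(Q, Sa, Sb, config, scheme) {
  if (!config@packed)
    stop("config is not packed; use alignGroup()")
  q <- asCodes(Q, scheme)
  sa <- asCodes(Sa, scheme)
  sb <- asCodes(Sb, scheme)
  span <- config@p * config@k
  if (length(sa) > span || length(sb) > span)
    stop("packed subjects must fit one group span; pad to the same p*k")
  pt <- buildPackedTable(scheme)
  res <- cpp_lane_align_packed(q, sa, sb, scheme@sigma, pt@table,
                               scheme@alphabet@padCode, scheme@alpha,
                               scheme@beta, config@p, config@k,
                               precisionMode(config@precision), FALSE)
  list(a = laneResult(list(score = res$score_a, overflow = res$overflow_a,
                           stages = res$stages, iterations = res$iterations),
                      config@precision, 1L),
       b = laneResult(list(score = res$score_b, overflow = res$overflow_b,
                           stages = res$stages, iterations = res$iterations),
                      config@precision, 2L))
}

#' Saturating arithmetic contract of a precision mode
#'
#' Returns the arithmetic behaviour the engine uses in the given mode:
#' `add(a, b)` (carrying an `"overflow"` attribute where applicable),
#' `max(a, b)`, the representable range and the overflow threshold at which
#' a subject is flagged.
#'
#' @param precision `"wide32"`, `"int16sat"` or `"fp16emu"`.
#' @return List with `add`, `max`, `lo`, `hi`, `threshold`.
#' @examples
#' ops <- saturatingOps("int16sat")
#' ops$add(32000, 1000)  # 32767, attr overflow TRUE
#' @export
saturatingOps <- function(precision = c("wide32", "int16sat", "fp16emu")) {
  precision <- match.arg(precision)
  thr <- overflowThreshold(precision)
  if (precision == "int16sat") {
    add <- function(a, b) {
      v <- pmin(pmax(a + b, -32768), 32767)
      attr(v, "overflow") <- any(v >= 32767)
      v
    }
    list(add = add, max = function(a, b) pmax(a, b),
         lo = -32768, hi = 32767, threshold = thr)
  } else {
    add <- function(a, b) {
      v <- a + b
      attr(v, "overflow") <- any(v >= thr)
      v
    }
    list(add = add, max = function(a, b) pmax(a, b),
         lo = -Inf, hi = Inf, threshold = thr)
  }
}

#' @rdname saturatingOps
#' @export
overflowThreshold <- function(precision) {
  switch(precision,
         wide32 = Inf,
         int16sat = 32767,   # signed 16-bit ceiling
         fp16emu = 2048,     # half-float precision-loss onset
         stop("unknown precision '", precision, "'"))
}

# map precision label to the engine's integer mode
precisionMode <- function(precision) {
  match(precision, c("wide32", "int16sat", "fp16emu")) - 1L
}

# shape a C++ engine result; attach an OverflowFlag when raised
laneResult <- function(res, precision, subjectIndex = 1L) {
  out <- list(score = res$score,
              overflow = if (isTRUE(res$overflow))
                list(subject_index = subjectIndex,
                     reason = if (precision == "int16sat") "saturated16"
                              else "fp16range")
              else NULL,
              iterations = res$iterations,
              stages = res$stages)
  for (f in c("coverage", "schedule", "boundaryH", "boundaryF"))
    if (!is.null(res[[f]])) out[[f]] <- res[[f]]
  if (!is.null(out$overflow)) out$score <- NA_integer_
  out
}
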
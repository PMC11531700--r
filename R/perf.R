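#' Arithmetic operations per DP cell
#'
#' Counts the arithmetic instructions one cell update costs in unpacked
#' scalar arithmetic: the main recurrence contributes 1 addition and 3
#' maximum operations, the optimized gap recurrences contribute 3
#' subtractions and 2 maxima, and the comparison with the running maximum
#' adds 1 more maximum — 6 max plus 4 add/sub in total. Substitution-table
#' lookups and register moves are excluded: they can proceed concurrently
#' with the arithmetic.
#'
#' @return List with `max`, `addsub`, `total` and the per-source breakdown.
#' @export
baseOpCount <- function() {
  contrib <- data.frame(
    source = c("main recurrence", "gap recurrences (optimized)",
               "running maximum"),
    max = c(3L, 2L, 1L),
    addsub = c(1L, 3L, 0L))
  list(max = sum(contrib$max), addsub = sum(contrib$addsub),
       total = sum(contrib$max) + sum(contrib$addsub), breakdown = contrib)
}

#' Instruction schedule under a capability set
#'
#' Applies the capability rewrites in order to the base per-cell schedule:
#' `packing2` processes two cells per instruction (halving per-cell cost);
#' `dual_port` issues add/sub on a second port so only the maxima serialize;
#' `dpx_fused` additionally fuses add+max pairs, dropping the serialized
#' packed-pair count to 4. With no capabilities the cost is the full 10
#' operations per cell.
#'
#' @param caps character subset of `"packing2"`, `"dual_port"`,
#'   `"dpx_fused"` (`dpx_fused` requires `packing2`).
#' @return List with `nMax`, `nAddsub`, `serializedOps`, `cellsPerIssue`
#'   and `cyclesPerCell`.
#' @export
instructionSchedule <- function(caps = character(0)) {
  bad <- setdiff(caps, c("packing2", "dual_port", "dpx_fused"))
  if (length(bad)) stop("unknown capability: ", bad[1])
  if ("dpx_fused" %in% caps && !"packing2" %in% caps)
    stop("inconsistent capabilities: dpx_fused requires packing2")
  ops <- baseOpCount()
  serialized <- ops$total                       # 10: all ops on one port
  if ("dual_port" %in% caps) serialized <- ops$max  # add/sub move off-port
  if ("dpx_fused" %in% caps) serialized <- 4L   # fused add+max endpoint
  cellsPerIssue <- if ("packing2" %in% caps) 2L else 1L
  list(nMax = ops$max, nAddsub = ops$addsub, serializedOps = serialized,
       cellsPerIssue = cellsPerIssue,
       cyclesPerCell = serialized / cellsPerIssue)
}

#' Cycles per DP cell update
#'
#' @inheritParams instructionSchedule
#' @return Numeric cycles per cell: 10 with no capabilities, 5 with
#'   `packing2`, 3 adding `dual_port`, 2 adding `dpx_fused`.
#' @examples
#' cyclesPerCell(c("packing2", "dual_port"))  # 3
#' @export
cyclesPerCell <- function(caps = character(0)) {
  instructionSchedule(caps)$cyclesPerCell
}

#' Built-in architecture specifications
#'
#' Device constants for the three modeled GPU-class architectures: streaming
#' processor counts 108 (a100), 142 (l40s), 132 (h100); max clocks
#' 1.41 / 2.56 / 1.98 GHz (sustained 1.41 / 2.11 / 1.98); per-instruction
#' throughput 64 results per cycle per processor; and the capability sets
#' packing2 (a100), packing2+dual_port (l40s),
#' packing2+dual_port+dpx_fused (h100). Measured best-kernel throughputs
#' (1.94 / 5.01 / 5.71 TCUPS) are carried for efficiency reporting.
#'
#' @param name `"a100"`, `"l40s"` or `"h100"`.
#' @return An [ArchSpec-class].
#' @export
builtinArch <- function(name = c("a100", "l40s", "h100")) {
  name <- match.arg(tolower(name[1]), c("a100", "l40s", "h100"))
  spec <- switch(name,
    a100 = list(sm = 108L, cmax = 1.41, csus = 1.41,
                caps = "packing2", achieved = 1.94, datatype = "half2"),
    l40s = list(sm = 142L, cmax = 2.56, csus = 2.11,
                caps = c("packing2", "dual_port"), achieved = 5.01,
                datatype = "half2"),
    h100 = list(sm = 132L, cmax = 1.98, csus = 1.98,
                caps = c("packing2", "dual_port", "dpx_fused"),
                achieved = 5.71, datatype = "s16x2"))
  new("ArchSpec", name = name, smCount = spec$sm, clockMaxGhz = spec$cmax,
      clockSustainedGhz = spec$csus, throughputPerInstruction = 64L,
      caps = spec$caps, achievedTcups = spec$achieved,
      datatype = spec$datatype)
}

#' Read an architecture specification from JSON
#'
#' Expected fields: `name`, `sm_count`, `clock_max_ghz`,
#' `clock_sustained_ghz`, `throughput_per_instruction`, `caps` (array),
#' optional `achieved_tcups`, `datatype`.
#'
#' @param path JSON file path.
#' @return An [ArchSpec-class].
#' @export
readArchSpec <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("ArchSpec", name = as.character(j$name),
      smCount = as.integer(j$sm_count),
      clockMaxGhz = as.numeric(j$clock_max_ghz),
      clockSustainedGhz = as.numeric(j$clock_sustained_ghz),
      throughputPerInstruction = as.integer(j$throughput_per_instruction),
      caps = as.character(j$caps %||% character(0)),
      achievedTcups = as.numeric(j$achieved_tcups %||% NA_real_),
      datatype = as.character(j$datatype %||% NA_character_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Theoretical peak performance (TCUPS)
#'
#' `TPP = sm_count * throughput_per_instruction * clock /
#' cycles_per_cell_update`, reported in tera cell updates per second.
#'
#' @param arch an [ArchSpec-class].
#' @param clock `"max"` or `"sustained"`.
#' @param caps capability set for the schedule; defaults to the device's.
#' @return TPP in TCUPS.
#' @examples
#' tpp(builtinArch("a100"))  # ~1.95
#' @export
tpp <- function(arch, clock = c("max", "sustained"), caps = arch@caps) {
  clock <- match.arg(clock)
  ghz <- if (clock == "max") arch@clockMaxGhz else arch@clockSustainedGhz
  cyc <- cyclesPerCell(caps)
  if (cyc <= 0) stop("cycles per cell must be positive")
  arch@smCount * arch@throughputPerInstruction * ghz / cyc / 1000
}

#' Kernel efficiency in percent
#'
#' @param achievedTcups measured throughput.
#' @param tppTcups theoretical peak from [tpp()].
#' @return `round(100 * achieved / tpp)` as integer percent.
#' @export
efficiencyPct <- function(achievedTcups, tppTcups) {
  stopifnot(achievedTcups > 0, tppTcups > 0)
  as.integer(round(100 * achievedTcups / tppTcups))
}

#' Peak-performance report for one or more architectures
#'
#' @param archs list of [ArchSpec-class] objects (default: all built-ins).
#' @return data.frame with device constants, cycles per cell, TPP at max
#'   and sustained clocks, and efficiencies where measured throughput is
#'   available. Efficiencies are taken against the peak values at the
#'   table's two-decimal reporting precision, matching how such tables are
#'   conventionally printed.
#' @export
perfReport <- function(archs = lapply(c("h100", "l40s", "a100"),
                                      builtinArch)) {
  rows <- lapply(archs, function(a) {
    tmax <- tpp(a, "max"); tsus <- tpp(a, "sustained")
    data.frame(name = a@name, sms = a@smCount, clock_max = a@clockMaxGhz,
               clock_sustained = a@clockSustainedGhz,
               cycles_per_cell = cyclesPerCell(a@caps),
               tpp_max = tmax, tpp_sustained = tsus,
               achieved = a@achievedTcups,
               eff_max_pct = if (is.na(a@achievedTcups)) NA_integer_
                             else efficiencyPct(a@achievedTcups,
                                                round(tmax, 2)),
               eff_sustained_pct = if (is.na(a@achievedTcups)) NA_integer_
                                   else efficiencyPct(a@achievedTcups,
                                                      round(tsus, 2)))
  })
  do.call(rbind, rows)
}
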
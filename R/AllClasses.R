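#' Amino-acid alphabet with a dedicated pad code
#'
#' Residue symbols in the canonical NCBI BLAST column order
#' `ARNDCQEGHILKMFPSTWYVBZX*`, coded 0..23, plus a pad code (24) reserved for
#' filling lane groups and tile columns. The pad code maps to no residue
#' symbol and is scored so low against everything that a padded column can
#' never start or extend a local alignment.
#'
#' @slot symbols character vector of residue symbols, in canonical order.
#' @slot padCode integer code reserved for padding (one past the last symbol).
#' @export
setClass("AAAlphabet",
  representation(symbols = "character", padCode = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@symbols)) return("symbols must be unique")
    if (object@padCode != length(object@symbols))
      return("padCode must be the code one past the last symbol")
    TRUE
  })

#' Substitution matrix plus affine gap parameters
#'
#' A scoring scheme is a symmetric substitution matrix sigma over the residue
#' alphabet together with affine gap penalties: a gap of length g costs
#' alpha + (g-1) * beta. The stored matrix is extended by one pad row/column
#' holding -(alpha + max|sigma| + 1) so padded positions can never contribute
#' to an alignment.
#'
#' @slot name scheme label, e.g. "blosum62".
#' @slot alphabet the [AAAlphabet-class] the matrix is indexed by.
#' @slot sigma integer matrix, (nsym+1) x (nsym+1) including the pad row/col.
#' @slot alpha gap-open penalty (positive integer, includes first extension).
#' @slot beta gap-extension penalty (positive integer).
#' @export
setClass("ScoringScheme",
  representation(name = "character", alphabet = "AAAlphabet",
                 sigma = "matrix", alpha = "integer", beta = "integer"),
  validity = function(object) {
    ns <- length(object@alphabet@symbols)
    if (!is.integer(object@sigma)) return("sigma must be integer")
    if (!all(dim(object@sigma) == ns + 1L))
      return("sigma must include exactly one pad row and column")
    res <- object@sigma[seq_len(ns), seq_len(ns)]
    if (!identical(res, t(res))) return("sigma must be symmetric")
    if (max(abs(res)) > 127L) return("sigma values must fit in 8 bits")
    if (object@alpha < object@beta || object@beta < 1L)
      return("require alpha >= beta >= 1")
    # the -inf sentinel must survive alpha/beta arithmetic in int32
    stopifnot(-(2^31 / 4) - object@alpha - 1e6 * object@beta > -2^31)
    TRUE
  })

#' Packed pairwise substitution table
#'
#' Stores sigma as an nsym x nsym^2 table in which entry
#' (q, pack(s1, s2)) carries both sigma(q, s1) and sigma(q, s2) in the low
#' and high 16-bit halves of one 32-bit word, so one access yields the scores
#' of a query character against a packed pair of subject characters. Used by
#' the packed (two-subjects-per-group) 16-bit engine modes.
#'
#' @slot table integer matrix of packed score pairs.
#' @slot nsym number of codes covered (residues plus pad).
#' @export
setClass("PackedSubstitutionTable",
  representation(table = "matrix", nsym = "integer"),
  validity = function(object) {
    if (nrow(object@table) != object@nsym ||
        ncol(object@table) != object@nsym^2)
      return("table must be nsym x nsym^2")
    TRUE
  })

#' Lane-group kernel configuration
#'
#' The shape of one lane group: p lockstep lanes, k DP columns per lane, the
#' arithmetic precision mode, and whether two subjects are packed per group.
#' An untiled group covers subjects up to p * k residues; longer subjects go
#' through the tiled engine.
#'
#' @slot p lanes per group; one of 2, 4, 8, 16, 32.
#' @slot k columns per lane, 1..40 (the register-pressure ceiling).
#' @slot precision "wide32", "int16sat" or "fp16emu".
#' @slot packed logical; two subjects per group (16-bit modes only).
#' @slot tiled logical; dispatch subjects through the multi-stage engine.
#' @export
setClass("KernelConfig",
  representation(p = "integer", k = "integer", precision = "character",
                 packed = "logical", tiled = "logical"),
  validity = function(object) {
    if (!object@p %in% c(2L, 4L, 8L, 16L, 32L))
      return("p must be one of 2, 4, 8, 16, 32")
    if (object@k < 1L || object@k > kMaxColumns())
      return(sprintf("k must be in 1..%d", kMaxColumns()))
    if (!object@precision %in% c("wide32", "int16sat", "fp16emu"))
      return("precision must be wide32, int16sat or fp16emu")
    if (object@packed && object@precision == "wide32")
      return("packed mode requires a 16-bit precision")
    TRUE
  })

#' Length-sorted encoded sequence database
#'
#' In-memory image of the on-disk database produced by [makeDb()]: encoded
#' residues concatenated in ascending length order, per-sequence offsets and
#' lengths, and the original FASTA headers. Sorting by length enables
#' partitioning sequences into length bins served by specialized kernel
#' configurations.
#'
#' @slot version on-disk format version.
#' @slot alphabetId identifier of the encoding alphabet.
#' @slot residues integer vector of concatenated residue codes.
#' @slot offsets numeric, 0-based start of each sequence in `residues`.
#' @slot lengths integer sequence lengths, non-decreasing.
#' @slot headers full FASTA headers in storage order.
#' @slot ids headers truncated at the first whitespace.
#' @export
setClass("LocalDB",
  representation(version = "integer", alphabetId = "character",
                 residues = "integer", offsets = "numeric",
                 lengths = "integer", headers = "character",
                 ids = "character"),
  validity = function(object) {
    n <- length(object@lengths)
    if (length(object@offsets) != n || length(object@headers) != n ||
        length(object@ids) != n) return("per-sequence fields disagree on n")
    if (n > 0) {
      if (is.unsorted(object@lengths)) return("lengths must be non-decreasing")
      if (n > 1 && any(diff(object@offsets) <= 0))
        return("offsets must be strictly increasing")
      if (sum(as.numeric(object@lengths)) != length(object@residues))
        return("sum of lengths must equal total residues")
    }
    TRUE
  })

#' Architecture specification for the peak-performance model
#'
#' Describes a device for the analytic throughput model: number of streaming
#' processors, clocks, per-instruction result throughput, and which
#' instruction-level capabilities it offers (two-way 16-bit packing, a second
#' issue port for add/sub, fused add+max DP instructions).
#'
#' @slot name device label.
#' @slot smCount number of streaming processors.
#' @slot clockMaxGhz,clockSustainedGhz clocks in GHz.
#' @slot throughputPerInstruction results per cycle per processor.
#' @slot caps character subset of packing2, dual_port, dpx_fused.
#' @slot achievedTcups measured throughput in TCUPS (NA if unknown).
#' @slot datatype arithmetic format the measurement used.
#' @export
setClass("ArchSpec",
  representation(name = "character", smCount = "integer",
                 clockMaxGhz = "numeric", clockSustainedGhz = "numeric",
                 throughputPerInstruction = "integer", caps = "character",
                 achievedTcups = "numeric", datatype = "character"),
  validity = function(object) {
    if (object@smCount <= 0 || object@clockMaxGhz <= 0 ||
        object@clockSustainedGhz <= 0 || object@throughputPerInstruction <= 0)
      return("all device constants must be positive")
    bad <- setdiff(object@caps, c("packing2", "dual_port", "dpx_fused"))
    if (length(bad)) return(paste("unknown capability:", bad[1]))
    if ("dpx_fused" %in% object@caps && !"packing2" %in% object@caps)
      return("dpx_fused implies packing2 (fused DP ops are packed 16-bit)")
    TRUE
  })

setMethod("show", "AAAlphabet", function(object) {
  cat("AAAlphabet:", paste(object@symbols, collapse = ""),
      sprintf("(%d symbols + pad code %d)\n",
              length(object@symbols), object@padCode))
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme %s: alpha=%d beta=%d, %dx%d sigma (+pad)\n",
              object@name, object@alpha, object@beta,
              length(object@alphabet@symbols),
              length(object@alphabet@symbols)))
})

setMethod("show", "KernelConfig", function(object) {
  cat(sprintf("KernelConfig: p=%d k=%d span=%d precision=%s%s%s\n",
              object@p, object@k, object@p * object@k, object@precision,
              if (object@packed) " packed" else "",
              if (object@tiled) " tiled" else ""))
})

setMethod("show", "LocalDB", function(object) {
  cat(sprintf("LocalDB: %d sequences, %.0f residues, lengths %s..%s\n",
              length(object@lengths), length(object@residues),
              if (length(object@lengths)) min(object@lengths) else "-",
              if (length(object@lengths)) max(object@lengths) else "-"))
})

setMethod("show", "ArchSpec", function(object) {
  cat(sprintf("ArchSpec %s: %d SMs @ %.2f/%.2f GHz, throughput %d, caps [%s]\n",
              object@name, object@smCount, object@clockMaxGhz,
              object@clockSustainedGhz, object@throughputPerInstruction,
              paste(object@caps, collapse = ", ")))
})
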
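DB_MAGIC <- charToRaw("SWDB")
DB_VERSION <- 1L
LONG_BIN_THRESHOLD <- 1280L   # 32 * 40, the widest untiled group span
N_FIXED_BINS <- 20L           # bins [64i+1, 64(i+1)] for i = 0..19

# little-endian u64 written as two u32 words (lo, hi); counts stay < 2^53
writeU64 <- function(con, x) {
  x <- as.numeric(x)
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32
  asI32 <- function(v) as.integer(ifelse(v >= 2^31, v - 2^32, v))
  writeBin(c(asI32(lo), asI32(hi)), con, size = 4L, endian = "little")
}

readU64 <- function(con, n = 1L) {
  w <- readBin(con, "integer", 2L * n, size = 4L, endian = "little")
  w <- ifelse(w < 0, w + 2^32, w)
  w[seq(1L, 2L * n, by = 2L)] + w[seq(2L, 2L * n, by = 2L)] * 2^32
}

#' Build a local database from FASTA input (makeDB)
#'
#' Parses one or more protein FASTA files (plain or gzip-compressed —
#' both yield byte-identical databases), encodes every record, sorts the
#' records by ascending length (ties broken by original input order) and
#' writes the binary database to `outDir`: `db.bin` holds, little-endian, a
#' magic/version header, u64 sequence and residue counts, a u32 length
#' table, a u64 offset table, one residue code per byte, and a header blob
#' with its own u32 length table; `db.meta` is a small JSON description.
#'
#' @param fastaPaths character vector of FASTA / FASTA.gz paths.
#' @param outDir output directory (created if missing).
#' @param alphabet encoding alphabet.
#' @return The [LocalDB-class], invisibly.
#' @export
makeDb <- function(fastaPaths, outDir, alphabet = aaAlphabet()) {
  stopifnot(length(fastaPaths) >= 1)
  missing <- fastaPaths[!file.exists(fastaPaths)]
  if (length(missing)) stop("input not found: ", missing[1])
  headers <- character(0)
  seqs <- character(0)
  for (path in fastaPaths) {
    aa <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e)
                     stop("malformed FASTA in '", path, "': ",
                          conditionMessage(e)))
    w <- Biostrings::width(aa)
    if (any(w == 0L))
      stop(sprintf("zero-length record %d in '%s'", which(w == 0L)[1], path))
    headers <- c(headers, names(aa))
    seqs <- c(seqs, as.character(aa))
  }
  if (length(seqs) == 0L) stop("no sequences in input")
  codes <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    codes[[i]] <- tryCatch(encodeSequence(seqs[[i]], alphabet),
                           error = function(e)
                             stop(sprintf("record %d ('%s'): %s", i,
                                          headers[i], conditionMessage(e))))
  }
  ord <- order(lengths(codes))          # stable: ties keep input order
  codes <- codes[ord]
  headers <- headers[ord]
  lens <- lengths(codes)
  offs <- cumsum(c(0, as.numeric(lens[-length(lens)])))
  db <- new("LocalDB", version = DB_VERSION, alphabetId = "aa-blast-24",
            residues = unlist(codes, use.names = FALSE),
            offsets = offs, lengths = as.integer(lens), headers = headers,
            ids = sub("\\s.*$", "", headers))
  writeDb(db, outDir)
  invisible(db)
}

writeDb <- function(db, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(outDir, "db.bin"), "wb")
  on.exit(close(con))
  writeBin(DB_MAGIC, con)
  writeBin(db@version, con, size = 4L, endian = "little")
  n <- length(db@lengths)
  writeU64(con, n)
  writeU64(con, length(db@residues))
  writeBin(db@lengths, con, size = 4L, endian = "little")
  for (o in db@offsets) writeU64(con, o)
  writeBin(as.raw(db@residues), con)
  hdrRaw <- lapply(db@headers, charToRaw)
  writeBin(as.integer(lengths(hdrRaw)), con, size = 4L, endian = "little")
  writeU64(con, sum(lengths(hdrRaw)))
  writeBin(unlist(hdrRaw, use.names = FALSE), con)
  meta <- list(format = "swWavefront-localdb", version = db@version,
               alphabet = db@alphabetId, count = n,
               total_residues = length(db@residues))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(outDir, "db.meta"))
  invisible(NULL)
}

#' Load a local database from disk
#'
#' @param dir directory written by [makeDb()].
#' @return A [LocalDB-class].
#' @export
loadDb <- function(dir) {
  path <- file.path(dir, "db.bin")
  if (!file.exists(path)) stop("no db.bin under '", dir, "'")
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4L), DB_MAGIC))
    stop("not a swWavefront database (bad magic)")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != DB_VERSION) stop("unsupported database version ", version)
  n <- readU64(con)
  total <- readU64(con)
  lens <- readBin(con, "integer", n, size = 4L, endian = "little")
  offs <- readU64(con, n)
  residues <- as.integer(readBin(con, "raw", total))
  hdrLens <- readBin(con, "integer", n, size = 4L, endian = "little")
  blobLen <- readU64(con)
  blob <- readBin(con, "raw", blobLen)
  ends <- cumsum(hdrLens)
  starts <- ends - hdrLens + 1
  headers <- vapply(seq_len(n),
                    function(i) rawToChar(blob[starts[i]:ends[i]]), "")
  new("LocalDB", version = version, alphabetId = "aa-blast-24",
      residues = residues, offsets = offs, lengths = lens,
      headers = headers, ids = sub("\\s.*$", "", headers))
}

#' LocalDB accessors
#'
#' @param db a [LocalDB-class].
#' @param i sequence index in storage (length-sorted) order.
#' @export
dbCount <- function(db) length(db@lengths)

#' @rdname dbCount
#' @export
dbLengths <- function(db) db@lengths

#' @rdname dbCount
#' @export
dbHeaders <- function(db) db@headers

#' @rdname dbCount
#' @export
dbIds <- function(db) db@ids

#' @rdname dbCount
#' @export
dbTotalResidues <- function(db) length(db@residues)

#' @rdname dbCount
#' @export
dbSequence <- function(db, i) {
  stopifnot(i >= 1, i <= dbCount(db))
  db@residues[(db@offsets[i] + 1):(db@offsets[i] + db@lengths[i])]
}

#' Plan contiguous batches under a residue budget
#'
#' Splits the database (in storage order) into contiguous batches whose
#' residue totals respect the budget; a single sequence larger than the
#' budget forms its own batch.
#'
#' @param db a [LocalDB-class].
#' @param residueBudget maximum residues per batch (default 64 Mresidues).
#' @return data.frame with `start`, `end` (inclusive indices), `residues`.
#' @export
iterateBatches <- function(db, residueBudget = 64e6) {
  lens <- as.numeric(db@lengths)
  starts <- integer(0); ends <- integer(0); totals <- numeric(0)
  i <- 1L; n <- length(lens)
  while (i <= n) {
    tot <- lens[i]; j <- i
    while (j < n && tot + lens[j + 1L] <= residueBudget) {
      j <- j + 1L; tot <- tot + lens[j]
    }
    starts <- c(starts, i); ends <- c(ends, j); totals <- c(totals, tot)
    i <- j + 1L
  }
  data.frame(start = starts, end = ends, residues = totals)
}

#' Assign sequences to fixed-width length bins
#'
#' Bin i (0-based) covers lengths `[64*i + 1, 64*(i + 1)]` for i = 0..19;
#' lengths above 1280 fall into the long bin (index 20) served by the tiled
#' engine.
#'
#' @param lengths integer vector of sequence lengths (>= 1).
#' @return Integer bin index per sequence, 0..20.
#' @export
partitionByLength <- function(lengths) {
  stopifnot(all(lengths >= 1))
  bin <- (as.integer(lengths) - 1L) %/% 64L
  bin[lengths > LONG_BIN_THRESHOLD] <- N_FIXED_BINS
  bin
}

#' Kernel configuration serving a length bin
#'
#' Lanes scale with the bin's upper length bound at k = 32: p = 4 up to
#' length 128, p = 8 up to 256, p = 16 up to 512, p = 32 up to 1024;
#' lengths 1025..1280 use the widest untiled shape p = 32, k = 40; the long
#' bin uses p = 32, k = 32 with tiling.
#'
#' @param bin bin index 0..20 (from [partitionByLength()]).
#' @param precision precision mode for the returned config.
#' @return A [KernelConfig-class].
#' @export
selectKernelConfig <- function(bin, precision = "wide32") {
  bin <- as.integer(bin)
  stopifnot(bin >= 0L, bin <= N_FIXED_BINS)
  if (bin == N_FIXED_BINS)
    return(kernelConfig(32L, 32L, precision, tiled = TRUE))
  hi <- 64L * (bin + 1L)
  if (hi <= 128L) kernelConfig(4L, 32L, precision)
  else if (hi <= 256L) kernelConfig(8L, 32L, precision)
  else if (hi <= 512L) kernelConfig(16L, 32L, precision)
  else if (hi <= 1024L) kernelConfig(32L, 32L, precision)
  else kernelConfig(32L, 40L, precision)   # 1025..1280, untiled since 32*40
}

#' The length-bin table
#'
#' @param precision precision mode recorded in each bin's config.
#' @return data.frame with `bin`, `lo`, `hi`, `p`, `k`, `tiled`.
#' @export
lengthBins <- function(precision = "wide32") {
  bins <- 0:N_FIXED_BINS
  cfg <- lapply(bins, selectKernelConfig, precision = precision)
  data.frame(bin = bins,
             lo = c(64L * (0:(N_FIXED_BINS - 1L)) + 1L,
                    LONG_BIN_THRESHOLD + 1L),
             hi = c(64L * (1:N_FIXED_BINS), NA_integer_),
             p = vapply(cfg, slot, 0L, "p"),
             k = vapply(cfg, slot, 0L, "k"),
             tiled = vapply(cfg, slot, NA, "tiled"))
}

#' Balance sequences across workers by residue count
#'
#' Within each length bin, sequences are taken in descending length order
#' and each is assigned to the currently least-loaded worker (greedy
#' balancing, ties to the lowest worker id), so per-bin worker residue
#' totals differ by at most the longest sequence in that bin and every
#' worker scans work of every length class.
#'
#' @param db a [LocalDB-class].
#' @param nWorkers number of workers (>= 1).
#' @return List with `workers` (list of index vectors, each sorted
#'   ascending) and `residues` (per-worker totals).
#' @export
assignToWorkers <- function(db, nWorkers) {
  nWorkers <- as.integer(nWorkers)
  stopifnot(nWorkers >= 1L)
  lens <- as.numeric(db@lengths)
  bins <- partitionByLength(db@lengths)
  assign <- integer(length(lens))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    idx <- idx[order(-lens[idx], idx)]
    load <- numeric(nWorkers)
    for (i in idx) {
      w <- which.min(load)   # ties -> lowest worker id
      assign[i] <- w
      load[w] <- load[w] + lens[i]
    }
  }
  workers <- lapply(seq_len(nWorkers), function(w) which(assign == w))
  list(workers = workers,
       residues = vapply(workers, function(ix) sum(lens[ix]), 0))
}
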
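test_that("makeDb sorts by length with stable ties and round-trips content", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "in.fasta")
  writeLines(c(">s1 first", paste(rep("A", 10), collapse = ""),
               ">s2 second", "ARNDC",
               ">s3 third", "WYVWYVW",
               ">s4 tie", "CDCDC"), fa)
  db <- makeDb(fa, file.path(td, "db"))
  expect_identical(dbLengths(db), c(5L, 5L, 7L, 10L))
  expect_identical(dbIds(db), c("s2", "s4", "s3", "s1"))  # tie keeps order
  expect_identical(dbHeaders(db)[1], "s2 second")
  # decode equals the input multiset
  got <- vapply(seq_len(dbCount(db)),
                function(i) decodeSequence(dbSequence(db, i)), "")
  expect_setequal(got, c("AAAAAAAAAA", "ARNDC", "WYVWYVW", "CDCDC"))
  # reload from disk is identical
  db2 <- loadDb(file.path(td, "db"))
  expect_equal(db, db2)
})

test_that("plain and gzip-compressed FASTA give byte-identical databases", {
  td <- withr::local_tempdir()
  txt <- genDistributedDb(50, meanLen = 120, maxLen = 900, seed = 8)
  writeFasta(txt, file.path(td, "a.fasta"))
  writeFasta(txt, file.path(td, "a.fasta.gz"))
  makeDb(file.path(td, "a.fasta"), file.path(td, "d1"))
  makeDb(file.path(td, "a.fasta.gz"), file.path(td, "d2"))
  readAll <- function(p) readBin(p, "raw", file.size(p))
  expect_identical(readAll(file.path(td, "d1", "db.bin")),
                   readAll(file.path(td, "d2", "db.bin")))
})

test_that("makeDb round-trip agrees with an independent FASTA parse", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "in.fasta")
  writeFasta(genDistributedDb(40, meanLen = 80, maxLen = 400, seed = 9), fa)
  db <- makeDb(fa, file.path(td, "db"))
  ref <- Biostrings::readAAStringSet(fa)
  got <- vapply(seq_len(dbCount(db)),
                function(i) decodeSequence(dbSequence(db, i)), "")
  expect_setequal(got, as.character(ref))
  expect_setequal(dbHeaders(db), names(ref))
  expect_identical(dbTotalResidues(db), sum(Biostrings::width(ref)))
})

test_that("makeDb rejects bad input with the record identified", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "bad.fasta")
  writeLines(c(">ok", "ARN", ">empty", "", ">ok2", "CDE"), fa)
  expect_error(makeDb(fa, file.path(td, "db")), "record 2")
  expect_error(makeDb(file.path(td, "missing.fasta"), file.path(td, "db")),
               "not found")
})

test_that("batch plans are contiguous, covering and budget-respecting", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "in.fasta")
  writeFasta(genEqualLengthDb(10, 100, seed = 2), fa)
  db <- makeDb(fa, file.path(td, "db"))
  one <- iterateBatches(db, residueBudget = 1e9)
  expect_identical(nrow(one), 1L)
  plan <- iterateBatches(db, residueBudget = 300)
  expect_identical(plan$end - plan$start + 1L, c(3L, 3L, 3L, 1L))
  # random databases: batches concatenate back to db order
  db2 <- makeDb({
    f <- file.path(td, "r.fasta")
    writeFasta(genDistributedDb(60, 150, 2000, seed = 3), f); f
  }, file.path(td, "db2"))
  pl <- iterateBatches(db2, residueBudget = 5000)
  idx <- unlist(mapply(seq, pl$start, pl$end, SIMPLIFY = FALSE))
  expect_identical(idx, seq_len(dbCount(db2)))
  expect_true(all(pl$residues[pl$end - pl$start > 0] <= 5000))
})

test_that("length bins partition [1, Inf) with the stated boundaries", {
  expect_identical(partitionByLength(64L), 0L)
  expect_identical(partitionByLength(65L), 1L)
  expect_identical(partitionByLength(1280L), 19L)
  expect_identical(partitionByLength(1281L), 20L)
  lens <- 1:5000
  bins <- partitionByLength(lens)
  expect_true(all(bins >= 0L & bins <= 20L))
  # every length maps to exactly one bin and bin bounds are respected
  tbl <- lengthBins()
  for (b in 0:19) {
    covered <- lens[bins == b]
    expect_identical(range(covered), c(tbl$lo[b + 1], tbl$hi[b + 1]))
  }
  expect_identical(min(lens[bins == 20L]), 1281L)
})

test_that("kernel configs scale lanes with bin length and cover each bin", {
  expect_cfg <- function(len, p, k, tiled = FALSE) {
    cfg <- selectKernelConfig(partitionByLength(len))
    expect_identical(slot(cfg, "p"), p)
    expect_identical(slot(cfg, "k"), k)
    expect_identical(slot(cfg, "tiled"), tiled)
  }
  expect_cfg(128L, 4L, 32L)
  expect_cfg(256L, 8L, 32L)
  expect_cfg(512L, 16L, 32L)
  expect_cfg(1024L, 32L, 32L)
  expect_cfg(1280L, 32L, 40L)          # untiled since 32 * 40 = 1280
  expect_cfg(1281L, 32L, 32L, tiled = TRUE)
  # every fixed bin's upper bound fits its group span
  tbl <- lengthBins()
  fixed <- tbl[!tbl$tiled, ]
  expect_true(all(fixed$hi <= fixed$p * fixed$k))
})

test_that("worker assignment partitions the db with bounded imbalance", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "in.fasta")
  writeFasta(genDistributedDb(80, 150, 2000, seed = 4), fa)
  db <- makeDb(fa, file.path(td, "db"))
  one <- assignToWorkers(db, 1)
  expect_identical(one$workers[[1]], seq_len(dbCount(db)))
  for (nw in c(2L, 4L, 8L)) {
    asg <- assignToWorkers(db, nw)
    expect_identical(sort(unlist(asg$workers)), seq_len(dbCount(db)))
    # per-bin residue totals differ by at most the bin's longest sequence
    bins <- partitionByLength(dbLengths(db))
    for (b in unique(bins)) {
      tot <- vapply(asg$workers, function(ix)
        sum(as.numeric(dbLengths(db)[intersect(ix, which(bins == b))])), 0)
      expect_lte(max(tot) - min(tot), max(dbLengths(db)[bins == b]))
    }
  }
})

test_that("4 equal-length sequences split 2 + 2 over 2 workers", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "eq.fasta")
  writeFasta(genEqualLengthDb(4, 50, seed = 6), fa)
  db <- makeDb(fa, file.path(td, "db"))
  asg <- assignToWorkers(db, 2)
  expect_identical(lengths(asg$workers), c(2L, 2L))
  expect_identical(asg$residues, c(100, 100))
})

test_that("greedy balancing is near an exhaustive optimal split", {
  # all 2^n assignments of n <= 12 sequences to 2 workers
  set.seed(305)
  lens <- sample(65:128, 10, replace = TRUE)  # one length bin
  bestDiff <- min(vapply(0:(2^10 - 1), function(mask) {
    sel <- bitwAnd(mask, 2^(0:9)) > 0
    abs(sum(lens[sel]) - sum(lens[!sel]))
  }, 0))
  td <- withr::local_tempdir()
  fa <- file.path(td, "n.fasta")
  # one bin only, so the greedy bound applies to the whole set
  writeLines(unlist(lapply(seq_along(lens), function(i)
    c(paste0(">s", i), paste(rep("A", lens[i]), collapse = "")))), fa)
  db <- makeDb(fa, file.path(td, "db"))
  asg <- assignToWorkers(db, 2)
  greedyDiff <- abs(diff(asg$residues))
  expect_lte(greedyDiff, bestDiff + max(lens))
})
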
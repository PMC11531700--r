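test_that("shift-up exchange matches the hardware contract", {
  expect_identical(shiftUpExchange(c(10, 20, 30, 40), 1), c(10, 10, 20, 30))
  expect_identical(shiftUpExchange(c(1, 2, 3, 4), 0), c(1, 2, 3, 4))
  # index-arithmetic oracle over all offsets and several widths
  for (p in c(2, 4, 8)) {
    v <- seq_len(p) * 100
    for (off in 0:(p - 1)) {
      expected <- vapply(seq_len(p) - 1L, function(t)
        if (t - off >= 0) v[t - off + 1L] else v[t + 1L], 0)
      expect_identical(shiftUpExchange(v, off), expected)
    }
  }
  expect_error(shiftUpExchange(1:4, 4), "offset")
})

test_that("query rotation delivers q[i - t] to lane t, independent of subject", {
  pad <- padCode(aaAlphabet())
  for (p in c(2, 4, 8)) {
    q <- encodeSequence(randSeq(11))
    m <- length(q)
    sched <- laneQuerySchedule(q, p)
    for (i in seq_len(m + p) - 1L) {
      for (t in seq_len(p) - 1L) {
        want <- if (i - t >= 0 && i - t < m) q[i - t + 1L] else pad
        expect_identical(sched[i + 1L, t + 1L], want)
      }
    }
  }
  # lanes beyond a short query receive pad codes
  sched <- laneQuerySchedule(encodeSequence("AR"), 8)
  expect_true(all(sched[1, -1] == pad))
  # the engine's internal rotation agrees with the R-level register scheme
  q <- encodeSequence(randSeq(9))
  res <- cpp_lane_align(q, encodeSequence(randSeq(12)), bl62@sigma, pad,
                        11L, 1L, 4L, 8L, 0L, FALSE, TRUE)
  expect_identical(res$schedule, laneQuerySchedule(q, 4))
})

test_that("wavefront engine equals the oracle across all group shapes", {
  set.seed(201)
  for (p in c(2L, 4L, 8L, 16L, 32L)) {
    for (k in c(1L, 8L, 32L, 40L)) {
      cfg <- kernelConfig(p, k)
      for (rep in 1:6) {
        Q <- randSeq(sample(1:100, 1))
        S <- randSeq(sample(1:(p * k), 1))
        g <- alignGroup(Q, S, cfg, bl62)
        expect_identical(g$score, swScoreFull(Q, S, bl62)$score)
        expect_null(g$overflow)
      }
    }
  }
})

test_that("the wavefront takes exactly m + p lockstep iterations", {
  set.seed(202)
  for (rep in 1:5) {
    m <- sample(1:80, 1); p <- sample(c(2L, 4L, 8L), 1)
    g <- alignGroup(randSeq(m), randSeq(sample(1:(p * 8L), 1)),
                    kernelConfig(p, 8L), bl62)
    expect_identical(g$iterations, as.numeric(m + p))
    expect_identical(g$stages, 1L)
  }
})

test_that("lockstep schedule covers each real DP cell exactly once", {
  set.seed(203)
  for (rep in 1:5) {
    Q <- randSeq(sample(2:40, 1))
    S <- randSeq(sample(2:60, 1))
    g <- alignGroup(Q, S, kernelConfig(4, 16), bl62, debug = TRUE)
    expect_identical(dim(g$coverage), c(nchar(Q), nchar(S)))
    expect_true(all(g$coverage == 1L))
  }
})

test_that("subjects longer than the group span are redirected to tiling", {
  expect_error(alignGroup(randSeq(5), randSeq(70), kernelConfig(4, 16), bl62),
               "alignTiled")
})

test_that("saturating arithmetic contracts per precision mode", {
  sat <- saturatingOps("int16sat")
  v <- sat$add(32000, 1000)
  expect_identical(as.numeric(v), 32767)
  expect_true(attr(v, "overflow"))
  expect_identical(as.numeric(sat$add(-32768, -100)), -32768)
  expect_identical(overflowThreshold("fp16emu"), 2048)
  expect_identical(overflowThreshold("wide32"), Inf)
  half <- saturatingOps("fp16emu")
  expect_false(attr(half$add(1000, 1000), "overflow"))
  expect_true(attr(half$add(1500, 600), "overflow"))
})

test_that("narrow modes are exact below threshold and flag above it", {
  set.seed(204)
  # small random pairs stay far below 2048: fp16emu must agree with wide32
  for (rep in 1:20) {
    Q <- randSeq(sample(5:60, 1)); S <- randSeq(sample(5:60, 1))
    ref <- swScoreFull(Q, S, bl62)$score
    for (prec in c("int16sat", "fp16emu")) {
      g <- alignGroup(Q, S, kernelConfig(4, 16, prec), bl62)
      expect_null(g$overflow)
      expect_identical(g$score, ref)
    }
  }
  # engineered high-identity pair crossing each threshold
  ovHalf <- genOverflowPair(bl62, 2100)
  gHalf <- alignTiled(ovHalf$Q, ovHalf$S,
                      kernelConfig(32, 32, "fp16emu", tiled = TRUE), bl62)
  expect_identical(gHalf$overflow$reason, "fp16range")
  gInt <- alignTiled(ovHalf$Q, ovHalf$S,
                     kernelConfig(32, 32, "int16sat", tiled = TRUE), bl62)
  expect_null(gInt$overflow)   # 2100 < 32767: no 16-bit overflow
  ovInt <- genOverflowPair(bl62, 33000)
  gInt2 <- alignTiled(ovInt$Q, ovInt$S,
                      kernelConfig(32, 32, "int16sat", tiled = TRUE), bl62)
  expect_identical(gInt2$overflow$reason, "saturated16")
  expect_true(is.na(gInt2$score))
  gWide <- alignTiled(ovInt$Q, ovInt$S,
                      kernelConfig(32, 32, "wide32", tiled = TRUE), bl62)
  expect_null(gWide$overflow)
  expect_gte(gWide$score, 33000L)
})

test_that("packed groups equal two independent unpacked runs, flags included", {
  set.seed(205)
  cfg <- kernelConfig(8, 16, "int16sat", packed = TRUE)
  un <- kernelConfig(8, 16, "int16sat")
  for (rep in 1:10) {
    Q <- randSeq(sample(5:60, 1))
    Sa <- randSeq(sample(1:128, 1))
    Sb <- randSeq(sample(1:128, 1))
    pk <- alignGroupPacked(Q, Sa, Sb, cfg, bl62)
    ra <- alignGroup(Q, Sa, un, bl62)
    rb <- alignGroup(Q, Sb, un, bl62)
    expect_identical(pk$a$score, ra$score)
    expect_identical(pk$b$score, rb$score)
    expect_identical(is.null(pk$a$overflow), is.null(ra$overflow))
    expect_identical(is.null(pk$b$overflow), is.null(rb$overflow))
    expect_identical(pk$a$score, swScoreFull(Q, Sa, bl62)$score)
  }
  # identical subjects give identical halves
  S <- randSeq(64)
  pk <- alignGroupPacked(randSeq(20), S, S, cfg, bl62)
  expect_identical(pk$a$score, pk$b$score)
  # flags are independent per half (half-float range crossed by one subject)
  ov <- genOverflowPair(bl62, 2100)
  short <- randSeq(100)
  cfgHalf <- kernelConfig(8, 32, "fp16emu", packed = TRUE)
  pk2 <- alignGroupPacked(ov$Q, ov$S, short, cfgHalf, bl62)
  expect_identical(pk2$a$overflow$reason, "fp16range")
  expect_null(pk2$b$overflow)
  expect_identical(pk2$b$score, swScoreFull(ov$Q, short, bl62)$score)
})

test_that("overflow detection has no false negatives", {
  # whenever the oracle score reaches the mode threshold the flag is raised
  set.seed(206)
  for (target in c(2048, 2500, 32767, 40000)) {
    ov <- genOverflowPair(bl62, target)
    ref <- swScoreFull(ov$Q, ov$S, bl62)$score
    expect_gte(ref, target)
    cfg16 <- kernelConfig(32, 32, "int16sat", tiled = TRUE)
    cfgH <- kernelConfig(32, 32, "fp16emu", tiled = TRUE)
    if (ref >= 32767)
      expect_false(is.null(alignTiled(ov$Q, ov$S, cfg16, bl62)$overflow))
    if (ref >= 2048)
      expect_false(is.null(alignTiled(ov$Q, ov$S, cfgH, bl62)$overflow))
  }
})

test_that("kernel configurations are validated", {
  expect_error(kernelConfig(3, 32), "p must be")
  expect_error(kernelConfig(4, 41), "k must be")
  expect_error(kernelConfig(4, 32, "float64"), "precision")
  expect_error(kernelConfig(4, 32, "wide32", packed = TRUE), "16-bit")
  expect_identical(kMaxColumns(), 40L)
})
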
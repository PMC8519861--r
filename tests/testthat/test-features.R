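test_that("reference time courses are mask means", {
  arr <- array(rep(sin(seq_len(40)), each = 8), c(2, 2, 2, 40))
  s <- BoldSeries(arr, 2.3)
  ven <- array(FALSE, c(2, 2, 2)); ven[1, 1, 1] <- TRUE
  refs <- extractReferences(s, ven)
  expect_equal(refs$global, arr[1, 1, 1, ])
  expect_equal(refs$venous, refs$global)

  refsAll <- extractReferences(s, brainMask(s))
  expect_equal(refsAll$venous, refsAll$global)

  # +s / -s checkerboard cancels in the global mean
  chk <- array(0, c(2, 1, 1, 40))
  sig <- stats::rnorm(40)
  chk[1, 1, 1, ] <- sig; chk[2, 1, 1, ] <- -sig
  s2 <- BoldSeries(chk, 2.3)
  expect_lt(max(abs(extractReferences(s2, brainMask(s2))$global)), 1e-12)

  expect_error(extractReferences(s, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("delay estimation finds constructed shifts with the right sign", {
  tr <- 2.3
  x <- testSignal(146, tr, seed = 21)
  expect_equal(computeDelay(x, x, tr)$delaySec, 0, tolerance = 1e-9)

  # delayed by exactly 2 samples: tc follows the reference by +4.6 s
  tc <- c(x[1], x[1], x[1:144])
  est <- computeDelay(tc, x, tr)
  expect_equal(est$delaySec, 4.6, tolerance = 0.1)
  expect_false(est$onBoundary)

  expect_error(computeDelay(x, rep(1, 146), tr), "flat")
  expect_error(computeDelay(x[1:20], x[1:20], tr), "30 samples")
})

test_that("delay estimation is antisymmetric on band-limited pairs", {
  tr <- 2.3
  for (seed in 1:10) {
    a <- testSignal(146, tr, seed = seed)
    b <- testSignal(146, tr, seed = seed + 100)
    ab <- computeDelay(a, b, tr)
    ba <- computeDelay(b, a, tr)
    if (!ab$onBoundary && !ba$onBoundary)
      expect_lt(abs(ab$delaySec + ba$delaySec), tr)
  }
})

test_that("band-power fractions isolate single- and two-line spectra", {
  tr <- 2.5; n <- 100
  tt <- (seq_len(n) - 1) * tr
  one <- sin(2 * pi * 0.02 * tt)
  bp <- bandPowerFractions(one, tr)
  expect_equal(unname(bp["band2"]), 100, tolerance = 1e-9)
  expect_lt(sum(bp[-2]), 1e-9)

  two <- sin(2 * pi * 0.02 * tt) + sin(2 * pi * 0.06 * tt + 1)
  bp2 <- bandPowerFractions(two, tr)
  expect_equal(unname(bp2["band2"]), 50, tolerance = 0.01)
  expect_equal(unname(bp2["band4"]), 50, tolerance = 0.01)

  set.seed(1)
  noisy <- stats::rnorm(146)
  expect_lte(sum(bandPowerFractions(noisy, 2.3)), 100 + 1e-9)
  expect_warning(bandPowerFractions(noisy, 4), "truncated")
})

test_that("band powers plus supra-band power obey Parseval", {
  tr <- 2.3; n <- 146
  set.seed(2)
  for (rep in 1:5) {
    tc <- stats::rnorm(n)
    bp <- bandPowerFractions(tc, tr)
    # independent periodogram for the power above 0.2 Hz
    p <- Mod(stats::fft(tc - mean(tc)))^2
    f <- (1:(n %/% 2)) / (n * tr)
    p <- p[2:(n %/% 2 + 1)]
    above <- 100 * sum(p[f > 0.2]) / sum(p)
    expect_equal(sum(bp) + above, 100, tolerance = 1e-6)
  }
})

test_that("territory occupancy counts voxels and breaks ties low", {
  atlas <- array(0L, c(10, 10, 1))
  atlas[1:5, , 1] <- 1L
  atlas[6:10, , 1] <- 3L
  inside <- array(FALSE, c(10, 10, 1)); inside[7:9, 2:6, 1] <- TRUE
  tm <- new("ThresholdedMap", map = inside, zThreshold = 2.33, empty = FALSE)
  occ <- territoryOccupancy(tm, atlas)
  expect_equal(occ$territory, 3L)
  expect_equal(occ$percent, 100)
  expect_true(occ$dominant)

  mixed <- array(FALSE, c(10, 10, 1))
  mixed[1:5, 1:6, 1] <- TRUE            # 30 voxels in territory 1
  mixed[6:10, 1:4, 1] <- TRUE           # 20 voxels in territory 3
  tmM <- new("ThresholdedMap", map = mixed, zThreshold = 2.33, empty = FALSE)
  occM <- territoryOccupancy(tmM, atlas)
  expect_equal(occM$territory, 1L)
  expect_equal(occM$percent, 60)

  tie <- array(FALSE, c(10, 10, 1))
  tie[5:6, 1:5, 1] <- TRUE              # 5 voxels each in territories 1 and 3
  tmT <- new("ThresholdedMap", map = tie, zThreshold = 2.33, empty = FALSE)
  occT <- territoryOccupancy(tmT, atlas)
  expect_equal(occT$territory, 1L)
  expect_false(occT$dominant)

  empty <- new("ThresholdedMap", map = array(FALSE, c(10, 10, 1)),
               zThreshold = 2.33, empty = TRUE)
  occE <- territoryOccupancy(empty, atlas)
  expect_true(is.na(occE$territory))
  expect_equal(occE$percent, 0)
})

test_that("mean Tmax overlap is a plain masked mean", {
  tmax <- array(2, c(4, 4, 2))
  m <- array(FALSE, c(4, 4, 2)); m[1:2, 1, 1] <- TRUE
  tm <- new("ThresholdedMap", map = m, zThreshold = 2.33, empty = FALSE)
  expect_equal(meanTmaxOverlap(tm, tmax), 2)

  half <- array(1, c(4, 4, 2)); half[3:4, , ] <- 3
  m2 <- array(FALSE, c(4, 4, 2)); m2[2:3, 2, 2] <- TRUE
  tm2 <- new("ThresholdedMap", map = m2, zThreshold = 2.33, empty = FALSE)
  expect_equal(meanTmaxOverlap(tm2, half), 2)

  emptyTm <- new("ThresholdedMap", map = array(FALSE, c(4, 4, 2)),
                 zThreshold = 2.33, empty = TRUE)
  expect_true(is.na(meanTmaxOverlap(emptyTm, tmax)))
  expect_error(meanTmaxOverlap(tm, array(1, c(5, 4, 2))), "geometry")
})

test_that("min-max normalization matches its defining formula", {
  expect_equal(as.numeric(minmaxNormalize(c(2, 4, 6))), c(0, 0.5, 1))

  set.seed(9)
  x <- stats::rnorm(40)
  z <- minmaxNormalize(x)
  expect_equal(as.numeric(z), (x - min(x)) / (max(x) - min(x)))
  expect_equal(as.numeric(minmaxNormalize(3 * x + 7)), as.numeric(z),
               tolerance = 1e-12)

  deg <- minmaxNormalize(rep(4, 5))
  expect_true(attr(deg, "degenerate"))
  expect_equal(as.numeric(deg), rep(0.5, 5))
})

test_that("single-pass time-shift map equals plain per-voxel lag mapping", {
  sub <- smallPhantom(seed = 7)
  pp <- preprocessBold(sub$series)
  tsm <- timeShiftMap(pp, nPasses = 1, corFloor = 0)
  refs <- extractReferences(pp, brainMask(pp))
  m <- voxelMatrix(pp)
  idx <- round(seq(1, nrow(m), length.out = 25))
  vox <- which(brainMask(pp))
  for (i in idx) {
    est <- computeDelay(m[i, ], refs$global, trSec(pp))
    if (est$peakCor >= 0)
      expect_equal(tsm[vox[i]], est$delaySec, tolerance = 1e-9)
    else
      expect_true(is.na(tsm[vox[i]]))
  }
})

test_that("time-shift map recovers the injected lesion delay", {
  sub <- simulateSubject(phantomConfig(seed = 13))
  pp <- preprocessBold(sub$series)
  tsm <- timeShiftMap(pp)
  lesionMean <- mean(tsm[sub$truth@lesionMask], na.rm = TRUE)
  expect_gte(lesionMean, 7 - trSec(pp) / 2)
  expect_lte(lesionMean, 7 + trSec(pp) / 2)
})
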
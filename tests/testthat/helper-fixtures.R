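# Shared fixtures, generated in code. Heavy phantom-recovery runs are cached
# in a session-local environment so several test files can share them.

.fixtureCache <- new.env(parent = emptyenv())

# A small, fast phantom subject (default signal model, small grid).
smallPhantom <- function(seed = 1L, ...) {
  simulateSubject(phantomConfig(gridShape = c(24L, 24L, 12L), nVolumes = 80L,
                                seed = seed, ...))
}

# Band-limited test signal drawn with a local seed (does not touch fixtures).
testSignal <- function(n, trSec, seed, fLo = 0.01, fHi = 0.1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * trSec)
  xf[!(abs(f) > fLo & abs(f) <= fHi)] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Full-scale phantom -> preprocess -> ICA recovery over `n` seeds, with the
# HIC-matched component identified by spatial correlation against the truth
# map. Used by the end-to-end acceptance criterion and the overlap QC test.
phantomRecoveryRuns <- function(n = 20L) {
  key <- paste0("recovery", n)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  runs <- lapply(seq_len(n), function(s) {
    sub <- simulateSubject(phantomConfig(seed = s))
    pp <- preprocessBold(sub$series)
    cs <- spatialICA(pp, seed = s)
    truthHic <- sub$truth@sourceMaps[[which(sub$truth@labels == "HIC")[1]]]
    tv <- truthHic[brainMask(cs)]
    absCor <- apply(cs@maps, 1, function(m) abs(stats::cor(m, tv)))
    hicIdx <- which.max(absCor)
    ft <- componentFeatureTable(cs, pp, sub$atlas, sub$venousMask)
    overlap <- identifyHicByOverlap(cs, sub$truth@lesionMask,
                                    hicIndex = hicIdx)
    hicMask <- thresholdMap(componentMap(cs, hicIdx), 2.33, brainMask(cs))
    list(subject = sub, components = cs, features = ft, hicIdx = hicIdx,
         absCor = absCor, overlap = overlap,
         diceTruth = as.numeric(diceCoefficient(hicMask@map,
                                                truthHic > 0)))
  })
  .fixtureCache[[key]] <- runs
  runs
}
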
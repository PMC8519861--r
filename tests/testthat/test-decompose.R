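# Three disjoint-support sources on a small grid, optional noise.
threeSourceSeries <- function(noiseSd = 0, t = 60L, seed = 1) {
  set.seed(seed)
  d <- c(12L, 12L, 4L)
  n <- prod(d)
  tt <- seq_len(t)
  tcs <- rbind(sin(2 * pi * tt / 11), sin(2 * pi * tt / 17),
               sin(2 * pi * tt / 29))
  # small disjoint supports: near-uncorrelated spatial sources
  maps <- matrix(0, 3, n)
  maps[1, 1:40] <- 1
  maps[2, 201:240] <- 1
  maps[3, 401:440] <- 1
  arr <- array(t(maps) %*% tcs + stats::rnorm(n * t, sd = noiseSd), c(d, t))
  list(series = BoldSeries(arr, 2.3), maps = maps, tcs = tcs)
}

test_that("dimensionality estimate recovers exact low-rank structure", {
  fx <- threeSourceSeries(noiseSd = 0)
  expect_equal(estimateDimensionality(fx$series), 3L)
})

test_that("dimensionality estimate stays small on pure noise", {
  set.seed(42)
  s <- BoldSeries(array(stats::rnorm(12 * 12 * 4 * 60), c(12, 12, 4, 60)), 2.3)
  expect_lte(estimateDimensionality(s), 5L)
})

test_that("user-supplied k bypasses estimation and rank is enforced", {
  fx <- threeSourceSeries(noiseSd = 0.05)
  cs <- spatialICA(fx$series, k = 5L, seed = 1)
  expect_equal(nComponents(cs), 5L)
  noiseless <- threeSourceSeries(noiseSd = 0)
  expect_error(spatialICA(noiseless$series, k = 10L), "rank")
})

test_that("spatial ICA recovers disjoint sources with matched time courses", {
  fx <- threeSourceSeries(noiseSd = 0.02)
  cs <- spatialICA(fx$series, k = 3L, seed = 7)
  # one-to-one greedy matching on |spatial correlation|
  r <- abs(stats::cor(t(cs@maps), t(fx$maps)))
  taken <- integer(0)
  for (src in 1:3) {
    best <- order(r[, src], decreasing = TRUE)
    best <- best[!best %in% taken][1]
    expect_gte(r[best, src], 0.8)
    taken <- c(taken, best)
  }
  expect_equal(sort(taken), 1:3)
})

test_that("rank-1 data is recovered up to sign by a single component", {
  set.seed(3)
  d <- c(10L, 10L, 3L)
  map <- as.numeric(stats::runif(prod(d)) < 0.1)
  tc <- sin(2 * pi * seq_len(50) / 13)
  arr <- array(outer(map, tc) + stats::rnorm(prod(d) * 50, sd = 1e-3), c(d, 50))
  cs <- spatialICA(BoldSeries(arr, 2.3), k = 1L, seed = 2)
  expect_gte(abs(stats::cor(cs@maps[1, ], map)), 0.99)
})

test_that("component maps obey the nonnegative-skewness sign convention", {
  fx <- threeSourceSeries(noiseSd = 0.05)
  cs <- spatialICA(fx$series, k = 3L, seed = 5)
  sk <- apply(cs@maps, 1, function(m) mean((m - mean(m))^3) / stats::sd(m)^3)
  expect_true(all(sk >= 0))
})

test_that("decomposition is reproducible under a fixed seed", {
  fx <- threeSourceSeries(noiseSd = 0.1)
  a <- spatialICA(fx$series, k = 3L, seed = 11)
  b <- spatialICA(fx$series, k = 3L, seed = 11)
  expect_identical(a@maps, b@maps)
  expect_identical(a@timecourses, b@timecourses)
})

test_that("maps times timecourses reproduces the rank-k PCA truncation", {
  fx <- threeSourceSeries(noiseSd = 0.2)
  k <- 3L
  cs <- spatialICA(fx$series, k = k, seed = 1)
  m <- voxelMatrix(fx$series)
  m <- m - rowMeans(m)
  mc <- sweep(m, 2, colMeans(m))
  sv <- svd(mc)
  pca <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  recon <- t(cs@maps) %*% t(cs@timecourses)
  # equal reconstructions up to the map centring absorbed during Z-scaling
  relErr <- sum((recon - pca)^2) / sum(pca^2)
  expect_lt(relErr, 1e-3)
})

test_that("map thresholding keeps the Gaussian tail fraction", {
  set.seed(8)
  z <- array(stats::rnorm(1e4), c(100, 10, 10))
  tm <- thresholdMap(z, 2.33)
  expect_false(tm@empty)
  frac <- sum(tm@map) / length(z)
  expect_lt(abs(frac - 2 * (1 - stats::pnorm(2.33))), 0.006)

  weak <- array(stats::rnorm(1000), c(10, 10, 10)) * 0.5
  weak[abs(weak) > 2] <- 2
  tmw <- thresholdMap(weak, 2.33)
  expect_true(tmw@empty)

  full <- thresholdMap(array(5, c(4, 4, 2)), 2.33)
  expect_true(all(full@map))
})

test_that("reordering components permutes features; orientation fixes signs", {
  sub <- smallPhantom(seed = 4)
  pp <- preprocessBold(sub$series)
  cs <- spatialICA(pp, k = 3L, seed = 1)
  perm <- c(3L, 1L, 2L)
  csPerm <- new("ComponentSet", maps = cs@maps[perm, ],
                timecourses = cs@timecourses[, perm], mask = cs@mask,
                explainedVariance = cs@explainedVariance[perm],
                metadata = cs@metadata)
  a <- componentFeatureTable(cs, pp, sub$atlas, sub$venousMask)
  b <- componentFeatureTable(csPerm, pp, sub$atlas, sub$venousMask)
  reord <- b[order(perm), ]
  for (col in c("delayGlobal", "delayVenous", "occupancy", paste0("band", 1:6)))
    expect_equal(reord[[col]], a[[col]], tolerance = 1e-12)
  # joint sign flips are unreachable: ICA re-orients a negated input
  csNeg <- spatialICA(BoldSeries(-pp@data, pp@trSec, pp@brainMask,
                                 pp@voxelSizeMm), k = 3L, seed = 1)
  skew <- apply(csNeg@maps, 1, function(m) mean((m - mean(m))^3))
  expect_true(all(skew >= 0))
})
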
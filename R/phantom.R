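# Synthetic phantom generator: 4D BOLD series with a systemic low-frequency
# oscillation (sLFO) propagating through the brain, territory-restricted
# hypoperfusion sources with delayed and low-frequency-shifted time courses,
# bilateral network sources, noise, drift, motion traces and matched
# ground-truth Tmax volumes.

#' Phantom configuration
#'
#' Bundles the acquisition geometry and signal model of one simulated
#' subject. Defaults mirror a typical 3T resting-state stroke protocol
#' (TR 2.3 s, 150 volumes, 3 mm voxels) at a desk-scale 32 x 32 x 16 grid.
#'
#' @param gridShape integer length-3 volume dimensions.
#' @param voxelSizeMm voxel edge length in mm.
#' @param trSec repetition time in seconds.
#' @param nVolumes number of time points.
#' @param nTerritories number of vascular territories (>= 2) in the wedge
#'   atlas.
#' @param hicSpec list of hypoperfusion sources; each element is a list with
#'   \code{territory} (atlas label), \code{delaySec} in [0, 20] (lag of the
#'   territory's sLFO behind the systemic one), \code{occupancy} in (0, 1]
#'   (fraction of the territory covered) and \code{lfBoost} >= 0 (amplitude
#'   of an extra oscillation below 0.025 Hz, relative to the sLFO).
#' @param nRsn number of bilateral resting-state-network sources.
#' @param noiseSd Gaussian noise sd (sLFO has unit sd).
#' @param driftAmplitude sd of per-voxel linear/quadratic drift terms.
#' @param sourceAmplitude amplitude of source time courses relative to the
#'   unit-sd background sLFO.
#' @param hicAmplitudeScale multiplicative BOLD amplitude factor inside
#'   hypoperfused tissue (exposed as a free parameter; 1 = no reduction).
#' @param motionAmplitudes length-6 amplitudes for the simulated motion
#'   trace (3 translations in mm, 3 rotations in radians).
#' @param seed integer RNG seed; the phantom is bitwise reproducible.
#' @return A validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 16L), voxelSizeMm = 3,
                          trSec = 2.3, nVolumes = 150L, nTerritories = 8L,
                          hicSpec = list(list(territory = 1L, delaySec = 7,
                                              occupancy = 0.9, lfBoost = 1)),
                          nRsn = 2L, noiseSd = 0.3, driftAmplitude = 0.5,
                          sourceAmplitude = 3, hicAmplitudeScale = 1,
                          motionAmplitudes = c(0.15, 0.15, 0.15,
                                               0.002, 0.002, 0.002),
                          seed = 1L) {
  cfg <- list(gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
              trSec = trSec, nVolumes = as.integer(nVolumes),
              nTerritories = as.integer(nTerritories), hicSpec = hicSpec,
              nRsn = as.integer(nRsn), noiseSd = noiseSd,
              driftAmplitude = driftAmplitude,
              sourceAmplitude = sourceAmplitude,
              hicAmplitudeScale = hicAmplitudeScale,
              motionAmplitudes = motionAmplitudes, seed = as.integer(seed))
  stopifnot(length(cfg$gridShape) == 3, all(cfg$gridShape > 0),
            cfg$voxelSizeMm > 0, cfg$trSec > 0, cfg$nVolumes > 0,
            cfg$nTerritories >= 2, cfg$nRsn >= 0, cfg$noiseSd >= 0,
            cfg$driftAmplitude >= 0, cfg$sourceAmplitude >= 0,
            cfg$hicAmplitudeScale >= 0, length(cfg$motionAmplitudes) == 6)
  # lag tracking spans +-20 s; the series must cover twice the maximum lag
  if (cfg$trSec * cfg$nVolumes < 80)
    stop("series too short: trSec * nVolumes must be >= 80 s for +-20 s lag tracking")
  for (h in cfg$hicSpec) {
    stopifnot(is.list(h), all(c("territory", "delaySec", "occupancy") %in% names(h)))
    if (h$delaySec < 0 || h$delaySec > 20)
      stop("hic delaySec must lie in [0, 20] s (the tracked lag range)")
    if (h$occupancy <= 0 || h$occupancy > 1)
      stop("hic occupancy must lie in (0, 1]")
    if (h$territory < 1 || h$territory > cfg$nTerritories)
      stop("hic territory ", h$territory, " not present in a ",
           cfg$nTerritories, "-territory atlas")
    if (is.null(h$lfBoost)) h$lfBoost <- 0
    if (h$lfBoost < 0) stop("lfBoost must be nonnegative")
  }
  class(cfg) <- "PhantomConfig"
  cfg
}

#' Build the phantom atlas: brain, vascular territories, venous sinus, CSF
#'
#' The brain is an ellipsoid inscribed in the grid; vascular territories are
#' contiguous angular wedges around the inferior-superior axis (a stand-in
#' for a real arterial-territory atlas); the venous-sinus mask is a small
#' posterior midline strip and the CSF mask a central ventricle-like
#' ellipsoid. Purely geometric, hence deterministic given the configuration.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{atlas} (integer 3D array, 0 outside the brain),
#'   \code{brainMask}, \code{venousMask}, \code{csfMask} (3D logical arrays).
#' @export
buildAtlas <- function(config) {
  d <- config$gridShape
  ctr <- (d + 1) / 2
  rad <- d / 2 - 0.5
  ax <- (seq_len(d[1]) - ctr[1]) / rad[1]
  ay <- (seq_len(d[2]) - ctr[2]) / rad[2]
  az <- (seq_len(d[3]) - ctr[3]) / rad[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  brain <- r2 <= 1
  if (!any(brain)) stop("grid too small to host a brain ellipsoid")

  k <- config$nTerritories
  theta <- array(rep(outer(ax, ay, function(x, y) atan2(y, x)), d[3]), d)
  lab <- as.integer(floor((theta + pi) / (2 * pi) * k)) + 1L
  lab[lab > k] <- k
  atlas <- array(0L, d)
  atlas[brain] <- lab[brain]
  counts <- tabulate(atlas[brain], nbins = k)
  if (any(counts < 50))
    stop("grid too small: territory voxel counts ", paste(counts, collapse = ", "),
         " (each territory needs >= 50 voxels)")

  # posterior midline strip, spanning the central slices
  xi <- abs(seq_len(d[1]) - ctr[1]) <= max(1, d[1] / 16)
  yi <- seq_len(d[2]) >= ctr[2] + 0.55 * rad[2]
  zi <- abs(seq_len(d[3]) - ctr[3]) <= max(1, d[3] / 4)
  venous <- outer(outer(xi, yi, `&`), zi, `&`) & brain
  if (!any(venous)) stop("venous-sinus mask came out empty; enlarge the grid")

  csf <- r2 <= 0.04 & brain  # central ventricle-like core

  list(atlas = atlas, brainMask = brain, venousMask = venous, csfMask = csf)
}

# Contiguous sub-mask covering `frac` of a territory: voxels nearest the
# territory centroid (grid distance), ties broken by linear index.
territoryBlob <- function(atlas, territory, frac) {
  idx <- which(atlas == territory, arr.ind = TRUE)
  n <- max(1L, round(frac * nrow(idx)))
  ctr <- colMeans(idx)
  d2 <- rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2)
  keep <- order(d2, seq_len(nrow(idx)))[seq_len(n)]
  m <- array(FALSE, dim(atlas))
  m[idx[keep, , drop = FALSE]] <- TRUE
  m
}

# Bilateral (x-mirrored) spherical blob fully inside the brain mask.
bilateralBlob <- function(brain, radiusVox = 3) {
  d <- dim(brain)
  idx <- which(brain, arr.ind = TRUE)
  ok <- idx[, 1] != (d[1] + 1) / 2   # off the midline so the mirror differs
  idx <- idx[ok, , drop = FALSE]
  c1 <- idx[sample.int(nrow(idx), 1), ]
  c2 <- c(d[1] + 1 - c1[1], c1[2], c1[3])
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  near <- function(ctr) (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <=
    radiusVox^2
  m <- array(near(c1) | near(c2), d) & brain
  m
}

#' Simulate one phantom subject
#'
#' Builds the 4D BOLD series as: a unit-sd systemic LFO (band-limited
#' 0.01-0.1 Hz) in every in-brain voxel, plus per-source time courses on
#' their support maps, plus Gaussian noise and per-voxel polynomial drift.
#' Hypoperfusion sources carry the systemic LFO delayed by \code{delaySec}
#' (exact fractional-sample Fourier shift) with an extra band-limited
#' oscillation below 0.025 Hz; network sources carry independent 0.01-0.1 Hz
#' signals on bilateral supports. A matched Tmax volume, lesion mask and
#' six-parameter motion trace are returned as ground truth.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{series} (\linkS4class{BoldSeries}),
#'   \code{truth} (\linkS4class{PhantomTruth}), \code{atlas},
#'   \code{venousMask} and \code{csfMask}.
#' @export
simulateSubject <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  geom <- buildAtlas(config)
  d <- config$gridShape
  n <- config$nVolumes
  tr <- config$trSec
  brain <- geom$brainMask

  withSeed(config$seed, {
    pad <- ceiling(40 / tr)
    nLong <- n + 2L * pad
    win <- (pad + 1):(pad + n)
    slfoLong <- bandlimitedNoise(nLong, tr, 0.01, 0.1)
    slfo <- slfoLong[win]

    sourceMaps <- list(); sourceTcs <- list()
    delays <- numeric(0); labels <- character(0)
    for (h in config$hicSpec) {
      boost <- h$lfBoost %||% 0
      tc <- fourierShift(slfoLong, h$delaySec, tr)[win]
      if (boost > 0)
        tc <- tc + boost * bandlimitedNoise(nLong, tr, 0, 0.025)[win]
      tc <- tc * config$hicAmplitudeScale
      sourceMaps <- c(sourceMaps, list(territoryBlob(geom$atlas, h$territory,
                                                     h$occupancy) * 1))
      sourceTcs <- c(sourceTcs, list(tc))
      delays <- c(delays, h$delaySec)
      labels <- c(labels, "HIC")
    }
    if (config$nRsn > 0) for (i in seq_len(config$nRsn)) {
      sourceMaps <- c(sourceMaps, list(bilateralBlob(brain) * 1))
      sourceTcs <- c(sourceTcs, list(bandlimitedNoise(nLong, tr, 0.01, 0.1)[win]))
      delays <- c(delays, 0)
      labels <- c(labels, "RSN")
    }

    vox <- which(brain)
    nv <- length(vox)
    sig <- matrix(slfo, nv, n, byrow = TRUE)
    for (s in seq_along(sourceMaps)) {
      inSrc <- sourceMaps[[s]][brain] > 0
      if (any(inSrc))
        sig[inSrc, ] <- sig[inSrc, ] +
          config$sourceAmplitude * matrix(sourceTcs[[s]], sum(inSrc), n,
                                          byrow = TRUE)
    }
    if (config$noiseSd > 0)
      sig <- sig + matrix(stats::rnorm(nv * n, sd = config$noiseSd), nv, n)
    if (config$driftAmplitude > 0) {
      tt <- seq(-1, 1, length.out = n)
      co <- matrix(stats::rnorm(nv * 2, sd = config$driftAmplitude), nv, 2)
      sig <- sig + co %*% rbind(tt, tt^2)
    }
    data <- array(0, c(d, n))
    flat <- matrix(data, prod(d), n)
    flat[vox, ] <- sig
    data <- array(flat, c(d, n))

    motion <- sapply(seq_len(6), function(j) {
      w <- cumsum(stats::rnorm(n))
      config$motionAmplitudes[j] * w / max(stats::sd(w), .Machine$double.eps)
    })
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    # Tmax ground truth: normal tissue ~1.3 s, lesion adds the injected lag
    tmax <- array(0, d)
    tmax[brain] <- pmax(0, 1.3 + stats::rnorm(nv, sd = 0.2))
    lesion <- array(FALSE, d)
    for (s in which(labels == "HIC")) {
      supp <- sourceMaps[[s]] > 0
      tmax[supp] <- pmax(0, 1.3 + delays[s] + stats::rnorm(sum(supp), sd = 0.2))
      lesion <- lesion | supp
    }

    series <- BoldSeries(data, trSec = tr, brainMask = brain,
                         voxelSizeMm = config$voxelSizeMm)
    truth <- new("PhantomTruth", sourceMaps = sourceMaps,
                 sourceDelaysSec = delays, labels = labels, tmaxMap = tmax,
                 lesionMask = lesion, motionTrace = motion)
    list(series = series, truth = truth, atlas = geom$atlas,
         venousMask = geom$venousMask, csfMask = geom$csfMask)
  })
}

#' Reference per-class feature moments for the synthetic feature generator
#'
#' Mean and standard deviation of each classifier feature for the HIC and
#' non-HIC classes, as observed in an acute-stroke rs-fMRI cohort (57 HICs,
#' 471 non-HICs). Published summaries give the mean and its 95% confidence
#' interval; the per-component sd is recovered as
#' \code{sd = halfwidth * sqrt(n) / 1.96}.
#'
#' @return data.frame with columns \code{feature}, \code{class},
#'   \code{mean}, \code{sd} and \code{inModel} (whether the feature enters
#'   the classifier; mean Tmax is validation-only).
#' @export
referenceFeatureMoments <- function() {
  hw <- function(lo, hi) (hi - lo) / 2
  sdci <- function(h, n) h * sqrt(n) / 1.96
  feats <- c("delayGlobal", "delayVenous", "meanTmax", "occupancy",
             paste0("band", 1:6))
  hicMean <- c(7.2, 5.9, 2.15, 51.6, 21.7, 23.9, 22.6, 15.1, 12.5, 4.2)
  hicHw <- c(hw(5.4, 9.1), hw(4.1, 7.6), hw(1.8, 2.5), hw(44.3, 58.9),
             hw(19.1, 24.3), hw(22.1, 25.7), hw(21.2, 24.0),
             hw(13.6, 16.7), hw(11.2, 13.8), hw(3.6, 4.8))
  nonMean <- c(-0.5, -2.2, 1.3, 6.2, 17.9, 21.4, 25.8, 17.4, 13.3, 4.0)
  nonHw <- c(hw(-0.8, -0.1), hw(-2.6, -1.9), hw(1.2, 1.4), hw(4.6, 7.8),
             hw(17.3, 18.5), hw(20.9, 22.0), hw(25.4, 26.3),
             hw(17.0, 17.9), hw(12.9, 13.8), hw(3.8, 4.2))
  rbind(
    data.frame(feature = feats, class = "HIC", mean = hicMean,
               sd = sdci(hicHw, 57), inModel = feats != "meanTmax"),
    data.frame(feature = feats, class = "non-HIC", mean = nonMean,
               sd = sdci(nonHw, 471), inModel = feats != "meanTmax"))
}

#' Names of the features entering the HIC classifier
#'
#' Two reference delays, single-territory occupancy and six spectral band
#' powers (0-0.01, 0.01-0.025, 0.025-0.05, 0.05-0.1, 0.1-0.15,
#' 0.15-0.2 Hz).
#' @return character vector of length 9.
#' @export
hicModelFeatures <- function() {
  c("delayGlobal", "delayVenous", "occupancy", paste0("band", 1:6))
}

#' Simulate a labelled component feature table
#'
#' Draws independent Gaussian feature vectors per class from the supplied
#' per-class moments, then applies the generator's physical constraints:
#' occupancy is clipped to [0, 100] and each row's six band powers are
#' clipped at zero and rescaled proportionally so they keep the drawn total
#' (preserving the drawn band profile shape). Mean Tmax, when present, is
#' clipped at zero.
#'
#' @param nHic rows to draw for the HIC class.
#' @param nNonHic rows to draw for the non-HIC class.
#' @param moments per-class feature moments as returned by
#'   \code{\link{referenceFeatureMoments}}; all sds must be positive.
#' @param seed integer RNG seed.
#' @return data.frame with a \code{label} factor ("HIC"/"non-HIC") and one
#'   column per feature.
#' @export
simulateFeatureTable <- function(nHic = 57L, nNonHic = 471L,
                                 moments = referenceFeatureMoments(),
                                 seed = 1L) {
  stopifnot(nHic >= 0, nNonHic >= 0, nHic + nNonHic >= 1)
  if (any(moments$sd <= 0)) stop("all feature sds must be positive")
  feats <- unique(moments$feature)
  drawClass <- function(cls, n) {
    if (n == 0) return(NULL)
    m <- moments[moments$class == cls, ]
    x <- sapply(feats, function(f) {
      row <- m[m$feature == f, ]
      if (nrow(row) != 1) stop("moments must contain one row per feature/class")
      stats::rnorm(n, row$mean, row$sd)
    })
    x <- matrix(x, nrow = n, dimnames = list(NULL, feats))
    if ("occupancy" %in% feats)
      x[, "occupancy"] <- pmin(pmax(x[, "occupancy"], 0), 100)
    if ("meanTmax" %in% feats)
      x[, "meanTmax"] <- pmax(x[, "meanTmax"], 0)
    bands <- grep("^band", feats, value = TRUE)
    if (length(bands)) {
      tot <- rowSums(x[, bands, drop = FALSE])
      cl <- pmax(x[, bands, drop = FALSE], 0)
      s <- rowSums(cl)
      ok <- s > 0
      x[ok, bands] <- cl[ok, , drop = FALSE] * tot[ok] / s[ok]
    }
    data.frame(label = cls, x, check.names = FALSE)
  }
  withSeed(seed, {
    out <- rbind(drawClass("HIC", nHic), drawClass("non-HIC", nNonHic))
    out$label <- factor(out$label, levels = c("non-HIC", "HIC"))
    rownames(out) <- NULL
    out
  })
}
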
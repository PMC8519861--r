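# Component feature extraction: temporal delay to the global and
# venous-sinus references, spectral band-power fractions, single-territory
# occupancy, mean Tmax overlap, per-subject min-max normalization, and
# voxelwise time-shift (BOLD lag) mapping.

#' Frequency bands of the spectral power features
#'
#' @return data.frame with columns \code{lo} and \code{hi} (Hz) for the six
#'   bands 0-0.01, 0.01-0.025, 0.025-0.05, 0.05-0.1, 0.1-0.15, 0.15-0.2 Hz.
#' @export
bandFrequencies <- function() {
  data.frame(band = paste0("band", 1:6),
             lo = c(0, 0.01, 0.025, 0.05, 0.1, 0.15),
             hi = c(0.01, 0.025, 0.05, 0.1, 0.15, 0.2))
}

#' Extract the global and venous reference time courses
#'
#' @param series a preprocessed \linkS4class{BoldSeries}.
#' @param venousMask 3D logical array over the major venous sinuses.
#' @return list with \code{global} (mean over the brain mask) and
#'   \code{venous} (mean over the venous mask), each of length t.
#' @export
extractReferences <- function(series, venousMask) {
  stopifnot(is(series, "BoldSeries"))
  assertSameGeometry(series@brainMask, venousMask, "series and venous mask")
  if (!any(venousMask)) stop("venous mask is empty")
  d <- dim(series@data)
  flat <- matrix(series@data, prod(d[1:3]), d[4])
  list(global = colMeans(flat[as.vector(series@brainMask), , drop = FALSE]),
       venous = colMeans(flat[as.vector(venousMask), , drop = FALSE]))
}

# Normalized cross-correlation of tc against ref at an integer lag L >= 0
# means tc follows ref by L samples (overlapping segments only).
lagCorrelation <- function(tc, ref, lag) {
  n <- length(tc)
  if (lag >= 0) {
    a <- tc[(1 + lag):n]; b <- ref[1:(n - lag)]
  } else {
    a <- tc[1:(n + lag)]; b <- ref[(1 - lag):n]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Temporal delay of a time course behind a reference
#'
#' Finds the lag maximising the normalized cross-correlation over
#' [-maxLagSec, +maxLagSec], then refines it to sub-sample precision by
#' parabolic interpolation through the three correlation values around the
#' integer-lag peak. Positive delays mean the time course follows the
#' reference; negative delays mean it precedes it.
#'
#' @param tc component time course.
#' @param referenceTc reference time course (same length, nonconstant).
#' @param trSec sampling interval in seconds.
#' @param maxLagSec lag search half-range in seconds (default 20).
#' @return list with \code{delaySec}, \code{peakCor} and \code{onBoundary}
#'   (TRUE when the peak sits on the search boundary).
#' @export
computeDelay <- function(tc, referenceTc, trSec, maxLagSec = 20) {
  stopifnot(length(tc) == length(referenceTc), trSec > 0, maxLagSec > 0)
  if (length(tc) < 30)
    stop("delay estimation needs at least 30 samples")
  if (stats::sd(referenceTc) == 0) stop("flat reference: delay undefined")
  if (stats::sd(tc) == 0) stop("flat time course: delay undefined")
  maxLag <- floor(maxLagSec / trSec)
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(L) lagCorrelation(tc, referenceTc, L), 0)
  if (all(is.na(cc))) stop("correlation undefined at every lag")
  i <- which.max(cc)
  onBoundary <- i == 1L || i == length(lags)
  delta <- 0
  if (!onBoundary && !anyNA(cc[(i - 1):(i + 1)])) {
    y1 <- cc[i - 1]; y2 <- cc[i]; y3 <- cc[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) delta <- 0.5 * (y1 - y3) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  list(delaySec = (lags[i] + delta) * trSec, peakCor = cc[i],
       onBoundary = onBoundary)
}

#' Spectral power fractions in six frequency bands
#'
#' Computes the FFT periodogram of a time course and returns the percentage
#' of total power falling in each of the six bands of
#' \code{\link{bandFrequencies}}. The denominator is all non-DC power up to
#' the Nyquist frequency, so the six fractions sum to at most 100% (strictly
#' less when power exists above 0.2 Hz).
#'
#' @param tc time course.
#' @param trSec sampling interval in seconds.
#' @return named numeric of length 6 (percentages).
#' @export
bandPowerFractions <- function(tc, trSec) {
  n <- length(tc)
  stopifnot(n >= 8, trSec > 0)
  nyquist <- 1 / (2 * trSec)
  bands <- bandFrequencies()
  if (nyquist < max(bands$hi))
    warning("Nyquist frequency ", signif(nyquist, 3),
            " Hz < 0.2 Hz: top band truncated")
  p <- Mod(stats::fft(tc - mean(tc)))^2
  nf <- floor(n / 2)
  f <- (1:nf) / (n * trSec)
  p <- p[2:(nf + 1)]                 # DC excluded from numerator and denominator
  tot <- sum(p)
  if (tot == 0) stop("zero-power time course")
  out <- vapply(seq_len(nrow(bands)), function(b)
    100 * sum(p[f > bands$lo[b] & f <= bands$hi[b]]) / tot, 0)
  names(out) <- bands$band
  out
}

#' Single-territory occupancy of a thresholded component map
#'
#' Fraction of a component's suprathreshold voxels falling inside each
#' vascular territory; returns the dominant territory and its percentage,
#' plus whether the >50% single-territory criterion holds. Exact ties break
#' to the lower territory id.
#'
#' @param tmask a \linkS4class{ThresholdedMap}.
#' @param atlas integer 3D array of territory labels (0 = outside).
#' @return list with \code{territory} (NA when the mask is empty),
#'   \code{percent}, \code{dominant} (criterion flag) and the full
#'   \code{perTerritory} percentage vector.
#' @export
territoryOccupancy <- function(tmask, atlas) {
  stopifnot(is(tmask, "ThresholdedMap"))
  assertSameGeometry(tmask@map, atlas, "component mask and atlas")
  nTer <- max(atlas)
  if (tmask@empty || nTer < 1)
    return(list(territory = NA_integer_, percent = 0, dominant = FALSE,
                perTerritory = numeric(nTer)))
  labs <- atlas[tmask@map]
  nVox <- length(labs)
  per <- 100 * tabulate(labs[labs > 0], nbins = nTer) / nVox
  best <- which.max(per)           # first maximum = lowest territory id
  list(territory = as.integer(best), percent = per[best],
       dominant = per[best] > 50, perTerritory = per)
}

#' Mean Tmax over a component's suprathreshold voxels
#'
#' @param tmask a \linkS4class{ThresholdedMap}.
#' @param tmax 3D numeric array of time-to-maximum values (s); voxels set to
#'   NA (e.g. removed CSF artifacts) are excluded.
#' @return mean Tmax in seconds, or NA for an empty component.
#' @export
meanTmaxOverlap <- function(tmask, tmax) {
  stopifnot(is(tmask, "ThresholdedMap"))
  assertSameGeometry(tmask@map, tmax, "component mask and tmax map")
  if (tmask@empty) return(NA_real_)
  mean(tmax[tmask@map], na.rm = TRUE)
}

#' Min-max normalization across one subject's components
#'
#' Maps feature values x_i to z_i = (x_i - min S) / (max S - min S) where S
#' is the set of values across all of the subject's components, so the
#' smallest value becomes 0 and the largest 1. When all values coincide the
#' result is 0.5 everywhere with a degeneracy attribute set.
#'
#' @param x numeric feature values of one subject's components.
#' @return normalized values in [0, 1]; attribute \code{degenerate} is TRUE
#'   for the all-equal case.
#' @export
minmaxNormalize <- function(x) {
  stopifnot(is.numeric(x))
  ok <- is.finite(x)
  rng <- range(x[ok])
  if (diff(rng) == 0) {
    out <- ifelse(ok, 0.5, NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Voxelwise time-shift (BOLD lag) map
#'
#' Assigns each in-mask voxel the lag (within +-maxLagSec, sub-sample
#' refined) that maximises the cross-correlation between the voxel's time
#' course and a recursively refined regressor: pass 1 uses the global mean
#' signal; each later pass rebuilds the regressor as the mean of all voxel
#' time courses back-shifted by their current lag estimates. Positive lag
#' means the voxel follows the regressor. Voxels whose peak correlation
#' falls below \code{corFloor} are returned as NA.
#'
#' @param series a preprocessed \linkS4class{BoldSeries}.
#' @param maxLagSec lag search half-range (s).
#' @param nPasses number of regressor refinement passes (1 = plain
#'   global-regressor lag mapping).
#' @param corFloor minimum acceptable peak correlation (default 0.3).
#' @return 3D numeric array of delays in seconds (NA outside the mask or
#'   below the correlation floor).
#' @export
timeShiftMap <- function(series, maxLagSec = 20, nPasses = 3, corFloor = 0.3) {
  stopifnot(is(series, "BoldSeries"), nPasses >= 1)
  tr <- series@trSec
  m <- voxelMatrix(series)
  nv <- nrow(m); n <- ncol(m)
  maxLag <- floor(maxLagSec / tr)
  lags <- -maxLag:maxLag
  flat <- apply(m, 1, stats::sd) == 0
  regressor <- colMeans(m)
  delays <- rep(NA_real_, nv)
  cors <- rep(NA_real_, nv)
  for (pass in seq_len(nPasses)) {
    cc <- voxelLagCorrelations(m, regressor, lags)
    cc[!is.finite(cc)] <- -2      # undefined correlations never win the peak
    i <- max.col(cc, ties.method = "first")
    onBnd <- i == 1L | i == length(lags)
    # parabolic sub-sample refinement around interior peaks
    delta <- rep(0, nv)
    ok <- which(!onBnd & !flat)
    y1 <- cc[cbind(ok, i[ok] - 1L)]
    y2 <- cc[cbind(ok, i[ok])]
    y3 <- cc[cbind(ok, i[ok] + 1L)]
    den <- y1 - 2 * y2 + y3
    d <- ifelse(den < 0, 0.5 * (y1 - y3) / den, 0)
    delta[ok] <- pmax(-0.5, pmin(0.5, d))
    delays <- (lags[i] + delta) * tr
    cors <- cc[cbind(seq_len(nv), i)]
    delays[flat] <- NA_real_
    if (pass < nPasses) {
      use <- which(!is.na(delays))
      shifted <- fourierShiftRows(m[use, , drop = FALSE], -delays[use], tr)
      regressor <- colMeans(shifted)
    }
  }
  delays[is.na(cors) | cors < corFloor] <- NA_real_
  vol <- array(NA_real_, dim(series@brainMask))
  vol[series@brainMask] <- delays
  vol
}

# Row-wise normalized cross-correlation of every voxel against a reference
# at each integer lag (positive lag = voxel follows the reference), using
# only the overlapping segments.
voxelLagCorrelations <- function(m, ref, lags) {
  n <- ncol(m)
  cc <- matrix(NA_real_, nrow(m), length(lags))
  for (j in seq_along(lags)) {
    L <- lags[j]
    if (L >= 0) { av <- (1 + L):n; bv <- 1:(n - L) }
    else { av <- 1:(n + L); bv <- (1 - L):n }
    a <- m[, av, drop = FALSE]
    b <- ref[bv]
    a <- a - rowMeans(a)
    b <- b - mean(b)
    nb <- sqrt(sum(b^2)); na <- sqrt(rowSums(a^2))
    denom <- na * nb
    r <- as.numeric(a %*% b) / ifelse(denom > 0, denom, NA_real_)
    cc[, j] <- r
  }
  cc
}

# Fractional circular shift of each row i by shifts[i] seconds.
fourierShiftRows <- function(m, shifts, dt) {
  n <- ncol(m)
  f <- fftFrequencies(n, dt)
  X <- stats::mvfft(t(m))                       # n x V spectra
  ph <- exp(-2i * pi * outer(f, shifts))
  if (n %% 2 == 0) ph[n / 2 + 1, ] <- Re(ph[n / 2 + 1, ])
  t(Re(stats::mvfft(X * ph, inverse = TRUE)) / n)
}

#' Full per-component feature table for one subject
#'
#' Computes the nine classifier features (two reference delays, dominant
#' single-territory occupancy, six band-power fractions) and, when a Tmax
#' map is supplied, the mean Tmax overlap, for every component of a
#' decomposition; per-subject min-max normalized twins are appended as
#' \code{norm.*} columns.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param series the \linkS4class{BoldSeries} the decomposition came from.
#' @param atlas integer 3D territory-label array.
#' @param venousMask 3D logical venous-sinus mask.
#' @param tmax optional 3D Tmax array (s).
#' @param zThreshold map threshold for the spatial features.
#' @return data.frame, one row per component: raw features, flags
#'   (\code{dominantTerritory}, \code{emptyMap}, \code{boundaryGlobal},
#'   \code{boundaryVenous}) and normalized features.
#' @export
componentFeatureTable <- function(components, series, atlas, venousMask,
                                  tmax = NULL, zThreshold = 2.33) {
  stopifnot(is(components, "ComponentSet"), is(series, "BoldSeries"))
  refs <- extractReferences(series, venousMask)
  tr <- series@trSec
  k <- nComponents(components)
  rows <- lapply(seq_len(k), function(i) {
    tc <- components@timecourses[, i]
    dg <- computeDelay(tc, refs$global, tr)
    dv <- computeDelay(tc, refs$venous, tr)
    bp <- bandPowerFractions(tc, tr)
    tm <- thresholdMap(componentMap(components, i), zThreshold,
                       brainMask(components))
    occ <- territoryOccupancy(tm, atlas)
    data.frame(component = i, delayGlobal = dg$delaySec,
               delayVenous = dv$delaySec, occupancy = occ$percent,
               t(bp),
               meanTmax = if (is.null(tmax)) NA_real_
                          else meanTmaxOverlap(tm, tmax),
               territory = occ$territory, dominantTerritory = occ$dominant,
               emptyMap = tm@empty, boundaryGlobal = dg$onBoundary,
               boundaryVenous = dv$onBoundary)
  })
  out <- do.call(rbind, rows)
  normFeats <- c(hicModelFeatures(), if (!is.null(tmax)) "meanTmax")
  for (f in normFeats)
    out[[paste0("norm.", f)]] <- as.numeric(minmaxNormalize(out[[f]]))
  out
}
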
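# Minimal rs-fMRI preprocessing: initial-volume discard, polynomial
# detrending and volumetric Gaussian smoothing. The series is deliberately
# left temporally unfiltered so that spatial ICA sees the full frequency
# range; slice-timing and realignment are standard-tool stages outside this
# package's scope (phantom volumes are generated aligned).

#' Discard initial volumes
#'
#' Drops the first \code{n} volumes of a series (signal equilibration).
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param n number of leading volumes to drop (default 4).
#' @return the shortened \linkS4class{BoldSeries}; TR is unchanged.
#' @export
discardInitial <- function(series, n = 4L) {
  stopifnot(is(series, "BoldSeries"), n >= 0)
  t <- nVolumes(series)
  if (n >= t) stop("cannot discard ", n, " volumes from a series of length ", t)
  if (n == 0) return(series)
  BoldSeries(series@data[, , , (n + 1):t, drop = FALSE], trSec = series@trSec,
             brainMask = series@brainMask, voxelSizeMm = series@voxelSizeMm)
}

#' Remove per-voxel polynomial trends
#'
#' Removes the least-squares polynomial of degree <= \code{order} from every
#' voxel time course (default: linear and quadratic trends, plus the mean).
#' Projection onto an orthonormal polynomial basis, so detrending is
#' idempotent to numerical precision.
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param order polynomial degree (0 = mean removal only).
#' @return the detrended \linkS4class{BoldSeries}.
#' @export
detrendSeries <- function(series, order = 2L) {
  stopifnot(is(series, "BoldSeries"), order >= 0)
  t <- nVolumes(series)
  if (t <= order + 1) stop("need more than order + 1 = ", order + 1, " volumes")
  basis <- cbind(rep(1 / sqrt(t), t),
                 if (order > 0) stats::poly(seq_len(t), degree = order))
  d <- dim(series@data)
  flat <- matrix(series@data, prod(d[1:3]), t)
  flat <- flat - (flat %*% basis) %*% t(basis)
  BoldSeries(array(flat, d), trSec = series@trSec,
             brainMask = series@brainMask, voxelSizeMm = series@voxelSizeMm)
}

# 1D Gaussian convolution along margin `axis` of a 4D array with replicated
# (constant-extension) boundaries; kernel truncated at 4 sigma.
convolveAxis <- function(arr, sigmaVox, axis) {
  if (sigmaVox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sigmaVox))
  w <- exp(-(-r:r)^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  idx <- function(j) {           # replicate edges
    i <- seq_len(n) + j
    pmin(pmax(i, 1L), n)
  }
  slice <- function(a, i) {
    switch(axis,
           a[i, , , , drop = FALSE],
           a[, i, , , drop = FALSE],
           a[, , i, , drop = FALSE])
  }
  for (j in -r:r) out <- out + w[j + r + 1] * slice(arr, idx(j))
  out
}

#' Volumetric Gaussian smoothing
#'
#' Smooths every volume with a separable 3D Gaussian kernel of the given
#' full-width-at-half-maximum (default 6 mm); sigma per axis is
#' \code{fwhm / (2 sqrt(2 log 2))} divided by the voxel size, so anisotropic
#' voxels are honoured. Volume boundaries use constant extension, which
#' avoids rim attenuation on small phantom grids. \code{fwhmMm = 0} is the
#' identity.
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param fwhmMm kernel FWHM in millimetres.
#' @return the smoothed \linkS4class{BoldSeries}.
#' @export
smoothSeries <- function(series, fwhmMm = 6) {
  stopifnot(is(series, "BoldSeries"))
  if (fwhmMm < 0) stop("fwhmMm must be nonnegative")
  if (fwhmMm == 0) return(series)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / series@voxelSizeMm
  arr <- series@data
  for (axis in 1:3) arr <- convolveAxis(arr, sigma[axis], axis)
  BoldSeries(arr, trSec = series@trSec, brainMask = series@brainMask,
             voxelSizeMm = series@voxelSizeMm)
}

#' Standard preprocessing pipeline
#'
#' Volume discard, polynomial detrend and spatial smoothing, in that order.
#' No temporal filtering is applied at any stage.
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param nDiscard leading volumes to drop.
#' @param detrendOrder polynomial detrend degree.
#' @param fwhmMm smoothing kernel FWHM in mm.
#' @return the preprocessed \linkS4class{BoldSeries}.
#' @export
preprocessBold <- function(series, nDiscard = 4L, detrendOrder = 2L,
                           fwhmMm = 6) {
  smoothSeries(detrendSeries(discardInitial(series, nDiscard), detrendOrder),
               fwhmMm)
}
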
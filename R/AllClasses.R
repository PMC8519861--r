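#' @import methods
NULL

#' BoldSeries: a 4D resting-state BOLD acquisition
#'
#' Container for a 4D voxel-by-time BOLD signal together with its repetition
#' time, brain mask and voxel geometry. All preprocessing and decomposition
#' steps consume and return objects of this class.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot trSec repetition time in seconds.
#' @slot brainMask 3D logical array marking in-brain voxels.
#' @slot voxelSizeMm numeric length-3, voxel edge lengths in mm.
#'
#' @exportClass BoldSeries
setClass("BoldSeries",
  representation(data = "array", trSec = "numeric",
                 brainMask = "array", voxelSizeMm = "numeric"))

setValidity("BoldSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4D array (x, y, z, t)")
  if (!identical(dim(object@brainMask), d[1:3]))
    return("brainMask geometry does not match data")
  if (!is.logical(object@brainMask)) return("brainMask must be logical")
  if (!any(object@brainMask)) return("brainMask is empty")
  if (length(object@trSec) != 1 || object@trSec <= 0)
    return("trSec must be a positive scalar")
  if (length(object@voxelSizeMm) != 3 || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive values")
  if (anyNA(object@data)) return("data contains NA")
  TRUE
})

#' Construct a BoldSeries
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param trSec repetition time in seconds.
#' @param brainMask 3D logical array; defaults to all voxels in-brain.
#' @param voxelSizeMm voxel size in mm (scalar or length 3).
#' @return A \linkS4class{BoldSeries}.
#' @export
BoldSeries <- function(data, trSec, brainMask = NULL, voxelSizeMm = 3) {
  if (is.null(brainMask))
    brainMask <- array(TRUE, dim(data)[1:3])
  if (length(voxelSizeMm) == 1) voxelSizeMm <- rep(voxelSizeMm, 3)
  new("BoldSeries", data = data, trSec = as.numeric(trSec),
      brainMask = brainMask, voxelSizeMm = as.numeric(voxelSizeMm))
}

#' ComponentSet: one spatial ICA decomposition
#'
#' Paired spatial maps and time courses from a single decomposition of a
#' \linkS4class{BoldSeries}. Each map row is Z-scaled (mean 0, sd 1 over
#' in-mask voxels) and each component is oriented so that its spatial map
#' has nonnegative skewness.
#'
#' @slot maps k x V numeric matrix of Z-scaled spatial maps (V = in-mask
#'   voxels, column order = \code{which(mask)}).
#' @slot timecourses t x k numeric matrix of component time courses
#'   (the mixing-matrix columns).
#' @slot mask 3D logical array the map columns refer to.
#' @slot explainedVariance fraction of total in-mask variance carried by
#'   each component.
#' @slot metadata list: algorithm variant, seed, convergence details.
#'
#' @exportClass ComponentSet
setClass("ComponentSet",
  representation(maps = "matrix", timecourses = "matrix", mask = "array",
                 explainedVariance = "numeric", metadata = "list"))

setValidity("ComponentSet", function(object) {
  k <- nrow(object@maps)
  if (k < 1) return("at least one component required")
  if (ncol(object@maps) != sum(object@mask))
    return("map columns must match in-mask voxel count")
  if (ncol(object@timecourses) != k)
    return("timecourses must have one column per component")
  if (!all(is.finite(object@maps)) || !all(is.finite(object@timecourses)))
    return("maps and timecourses must be finite")
  m <- rowMeans(object@maps)
  s <- apply(object@maps, 1, stats::sd)
  if (any(abs(m) > 1e-6) || any(abs(s - 1) > 1e-6))
    return("map rows must be Z-scaled (mean 0, sd 1 over the mask)")
  if (length(object@explainedVariance) != k)
    return("explainedVariance must have one entry per component")
  TRUE
})

#' ThresholdedMap: a binarised component spatial map
#'
#' @slot map 3D logical array of voxels exceeding the |Z| threshold.
#' @slot zThreshold the |Z| cut applied.
#' @slot empty TRUE when no voxel survived thresholding.
#'
#' @exportClass ThresholdedMap
setClass("ThresholdedMap",
  representation(map = "array", zThreshold = "numeric", empty = "logical"))

setValidity("ThresholdedMap", function(object) {
  if (length(dim(object@map)) != 3 || !is.logical(object@map))
    return("map must be a 3D logical array")
  if (object@empty != !any(object@map)) return("empty flag inconsistent")
  TRUE
})

#' PhantomTruth: ground truth for one simulated subject
#'
#' @slot sourceMaps list of 3D weight volumes, one per injected source.
#' @slot sourceDelaysSec delay (s) of each source behind the systemic LFO.
#' @slot labels per-source tag: "HIC", "RSN" or "NOISE".
#' @slot tmaxMap 3D volume of simulated time-to-maximum (s).
#' @slot lesionMask 3D logical array, union of HIC source supports.
#' @slot motionTrace n_volumes x 6 matrix (3 translations mm, 3 rotations rad).
#'
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(sourceMaps = "list", sourceDelaysSec = "numeric",
                 labels = "character", tmaxMap = "array",
                 lesionMask = "array", motionTrace = "matrix"))

setValidity("PhantomTruth", function(object) {
  n <- length(object@sourceMaps)
  if (length(object@sourceDelaysSec) != n || length(object@labels) != n)
    return("per-source slots must have equal length")
  if (!all(object@labels %in% c("HIC", "RSN", "NOISE")))
    return("labels must be HIC, RSN or NOISE")
  if (any(object@tmaxMap < 0)) return("tmaxMap must be nonnegative")
  hic <- which(object@labels == "HIC")
  if (length(hic)) {
    supp <- Reduce(`|`, lapply(object@sourceMaps[hic], function(m) m > 0))
    if (any(object@lesionMask & !supp))
      return("lesionMask must lie within the union of HIC source supports")
  }
  TRUE
})

#' HicModel: fitted elastic-net logistic HIC classifier
#'
#' @slot coefficients named per-feature coefficients (zeros allowed: the
#'   penalty performs implicit variable selection).
#' @slot intercept model intercept.
#' @slot mixingAlpha elastic-net mixing parameter in [0, 1].
#' @slot shrinkageLambda penalty strength chosen by leave-one-out CV.
#' @slot probabilityThreshold Youden-index probability cut frozen at
#'   training time.
#' @slot trainingMetadata list: seed, fold structure, lambda path summary.
#'
#' @exportClass HicModel
setClass("HicModel",
  representation(coefficients = "numeric", intercept = "numeric",
                 mixingAlpha = "numeric", shrinkageLambda = "numeric",
                 probabilityThreshold = "numeric", trainingMetadata = "list"))

setValidity("HicModel", function(object) {
  if (is.null(names(object@coefficients)))
    return("coefficients must be named by feature")
  if (object@mixingAlpha < 0 || object@mixingAlpha > 1)
    return("mixingAlpha must lie in [0, 1]")
  if (object@shrinkageLambda <= 0) return("shrinkageLambda must be positive")
  if (object@probabilityThreshold <= 0 || object@probabilityThreshold >= 1)
    return("probabilityThreshold must lie in (0, 1)")
  TRUE
})

#' MetricsReport: classifier performance over repeated test subsamples
#'
#' @slot iterations data.frame with one row per iteration: auc,
#'   balancedAccuracy, sensitivity, specificity, kappa.
#' @slot medians named numeric, median of each metric over iterations.
#' @slot nIterations number of test iterations.
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(iterations = "data.frame", medians = "numeric",
                 nIterations = "integer"))

setValidity("MetricsReport", function(object) {
  need <- c("auc", "balancedAccuracy", "sensitivity", "specificity", "kappa")
  if (!all(need %in% colnames(object@iterations)))
    return("iterations must contain the five performance metrics")
  if (nrow(object@iterations) != object@nIterations)
    return("nIterations inconsistent with iteration rows")
  ba <- with(object@iterations, (sensitivity + specificity) / 2)
  if (max(abs(ba - object@iterations$balancedAccuracy)) > 1e-8)
    return("balancedAccuracy must equal (sensitivity + specificity)/2")
  TRUE
})
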
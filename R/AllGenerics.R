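# Generics and simple accessors/show methods for the core classes.

#' Number of time points in a BoldSeries
#' @param x a \linkS4class{BoldSeries}.
#' @return integer volume count.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "BoldSeries", function(x) dim(x@data)[4])

#' Repetition time accessor
#' @param x a \linkS4class{BoldSeries}.
#' @return TR in seconds.
#' @export
setGeneric("trSec", function(x) standardGeneric("trSec"))

#' @rdname trSec
#' @export
setMethod("trSec", "BoldSeries", function(x) x@trSec)

#' Brain mask accessor
#' @param x a \linkS4class{BoldSeries} or \linkS4class{ComponentSet}.
#' @return 3D logical array.
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname brainMask
#' @export
setMethod("brainMask", "BoldSeries", function(x) x@brainMask)

#' @rdname brainMask
#' @export
setMethod("brainMask", "ComponentSet", function(x) x@mask)

#' In-mask voxel-by-time matrix
#'
#' Extracts the V x t matrix of in-mask voxel time courses (row order
#' \code{which(brainMask(x))}).
#' @param x a \linkS4class{BoldSeries}.
#' @return numeric matrix, one row per in-mask voxel.
#' @export
setGeneric("voxelMatrix", function(x) standardGeneric("voxelMatrix"))

#' @rdname voxelMatrix
#' @export
setMethod("voxelMatrix", "BoldSeries", function(x) {
  d <- dim(x@data)
  m <- matrix(x@data, prod(d[1:3]), d[4])
  m[as.vector(x@brainMask), , drop = FALSE]
})

#' Number of components
#' @param x a \linkS4class{ComponentSet}.
#' @return integer.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "ComponentSet", function(x) nrow(x@maps))

#' Component time courses
#' @param x a \linkS4class{ComponentSet}.
#' @return t x k numeric matrix.
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))

#' @rdname timecourses
#' @export
setMethod("timecourses", "ComponentSet", function(x) x@timecourses)

#' Spatial map of one component as a 3D volume
#'
#' @param x a \linkS4class{ComponentSet}.
#' @param i component index.
#' @return 3D numeric array with zeros outside the mask.
#' @export
setGeneric("componentMap", function(x, i) standardGeneric("componentMap"))

#' @rdname componentMap
#' @export
setMethod("componentMap", "ComponentSet", function(x, i) {
  stopifnot(i >= 1, i <= nComponents(x))
  vol <- array(0, dim(x@mask))
  vol[x@mask] <- x@maps[i, ]
  vol
})

#' Model coefficients, intercept excluded
#' @param object a \linkS4class{HicModel}.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "HicModel", function(object, ...) object@coefficients)

setMethod("show", "BoldSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldSeries: %dx%dx%d voxels x %d volumes, TR %.3g s, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], object@trSec, sum(object@brainMask)))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components over %d voxels x %d time points (%s ICA)\n",
              nComponents(object), ncol(object@maps), nrow(object@timecourses),
              object@metadata$algorithm %||% "unknown"))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = " ")))
})

setMethod("show", "HicModel", function(object) {
  cat(sprintf("HicModel: elastic-net logistic (alpha = %.2f, lambda = %.4g)\n",
              object@mixingAlpha, object@shrinkageLambda))
  cat(sprintf("  probability threshold (Youden) = %.3f\n",
              object@probabilityThreshold))
  nz <- sum(object@coefficients != 0)
  cat(sprintf("  %d/%d nonzero coefficients\n", nz, length(object@coefficients)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d iterations (medians):\n", object@nIterations))
  print(round(object@medians, 3))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d sources (%s), %d lesion voxels\n",
              length(object@sourceMaps), paste(object@labels, collapse = ", "),
              sum(object@lesionMask)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
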
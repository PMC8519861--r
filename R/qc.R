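# Motion quality control (framewise displacement, severe-motion flag),
# Dice spatial-overlap validation and HIC identification against a lesion
# mask, and CSF artifact removal for Tmax maps.

#' Framewise displacement from a six-parameter motion trace
#'
#' FD at volume t is the sum of absolute backward differences of the three
#' translations (mm) plus the head radius times the sum of absolute
#' backward differences of the three rotations (rad), with FD = 0 at the
#' first volume. Differencing follows the standard FD definition; the
#' rotation-to-arc conversion uses a 50 mm head radius.
#'
#' @param trace n x 6 numeric matrix: translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @param rotationRadiusMm head radius for the rotation arc length.
#' @return list with \code{fd} (per-volume, mm), \code{mean} and \code{max}.
#' @export
framewiseDisplacement <- function(trace, rotationRadiusMm = 50) {
  trace <- as.matrix(trace)
  stopifnot(ncol(trace) == 6, nrow(trace) >= 2)
  if (!all(is.finite(trace))) stop("motion parameters must be finite")
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
             rotationRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean = mean(fd), max = max(fd))
}

#' Severe-motion flag
#'
#' A scan counts as severely motion-affected when mean FD exceeds 0.4 mm or
#' maximum FD exceeds 3 mm (strict inequalities).
#'
#' @param fdSummary output of \code{\link{framewiseDisplacement}}.
#' @param meanLimitMm,maxLimitMm the two thresholds.
#' @return logical.
#' @export
flagSevereMotion <- function(fdSummary, meanLimitMm = 0.4, maxLimitMm = 3) {
  stopifnot(is.list(fdSummary), all(c("mean", "max") %in% names(fdSummary)))
  fdSummary$mean > meanLimitMm || fdSummary$max > maxLimitMm
}

#' Dice similarity coefficient of two masks
#'
#' 2|A intersect B| / (|A| + |B|), ranging from 0 (no overlap) to 1
#' (perfect overlap). Two empty masks give 0 by convention, with an
#' attribute flagging the degenerate case.
#'
#' @param maskA,maskB logical arrays of identical geometry (or
#'   \linkS4class{ThresholdedMap} objects).
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (is(maskA, "ThresholdedMap")) maskA <- maskA@map
  if (is(maskB, "ThresholdedMap")) maskB <- maskB@map
  assertSameGeometry(maskA, maskB, "masks")
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) {
    out <- 0
    attr(out, "bothEmpty") <- TRUE
    return(out)
  }
  2 * sum(maskA & maskB) / (a + b)
}

#' Identify the hypoperfusion component by lesion overlap
#'
#' Thresholds every component map at |Z| > \code{zThreshold} and computes
#' its Dice overlap with a lesion (perfusion-deficit) mask; the component
#' with the highest overlap is reported as the HIC candidate. Dice ties
#' break to the component with the larger sum of |Z| inside the lesion.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param lesionMask 3D logical lesion mask (nonempty).
#' @param zThreshold map threshold (default 2.33).
#' @param hicIndex optional known HIC component index; when given, the
#'   report flags whether the argmax recovered it.
#' @return list with \code{dice} (per component), \code{argmax} (NA when
#'   every component thresholds to empty), \code{matchesLabel} (NA unless
#'   \code{hicIndex} given).
#' @export
identifyHicByOverlap <- function(components, lesionMask, zThreshold = 2.33,
                                 hicIndex = NULL) {
  stopifnot(is(components, "ComponentSet"))
  assertSameGeometry(brainMask(components), lesionMask, "mask and lesion")
  if (!any(lesionMask)) stop("lesion mask is empty")
  k <- nComponents(components)
  dice <- numeric(k)
  zin <- numeric(k)
  anySurvived <- FALSE
  for (i in seq_len(k)) {
    vol <- componentMap(components, i)
    tm <- thresholdMap(vol, zThreshold, brainMask(components))
    anySurvived <- anySurvived || !tm@empty
    dice[i] <- as.numeric(diceCoefficient(tm@map, lesionMask))
    zin[i] <- sum(abs(vol[lesionMask]))
  }
  argmax <- if (!anySurvived) NA_integer_ else {
    best <- which(dice == max(dice))
    as.integer(best[which.max(zin[best])])
  }
  list(dice = dice, argmax = argmax,
       matchesLabel = if (is.null(hicIndex)) NA else
         isTRUE(argmax == hicIndex))
}

#' Remove CSF artifacts from a Tmax map
#'
#' Sets Tmax voxels inside the CSF mask to NA so they are excluded from all
#' downstream overlap and mean computations.
#'
#' @param tmax 3D numeric Tmax array (s).
#' @param csfMask 3D logical CSF mask.
#' @return the cleaned Tmax array.
#' @export
removeCsfArtifacts <- function(tmax, csfMask) {
  assertSameGeometry(tmax, csfMask, "tmax and CSF mask")
  tmax[csfMask] <- NA_real_
  tmax
}
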
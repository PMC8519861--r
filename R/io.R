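# File I/O: NIfTI volumes via RNifti, whitespace motion traces, plain-text
# model serialisation, component-set export and YAML phantom configs.

# Strip RNifti's image attributes down to a plain R array.
asPlainArray <- function(img) {
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Read a 4D BOLD NIfTI into a BoldSeries
#'
#' @param path 4D NIfTI file.
#' @param maskPath optional 3D NIfTI brain mask (nonzero = in-brain);
#'   defaults to all voxels.
#' @param trSec repetition time override; defaults to the header pixdim.
#' @return a \linkS4class{BoldSeries}.
#' @export
readBoldSeries <- function(path, maskPath = NULL, trSec = NULL) {
  img <- RNifti::readNifti(path)
  arr <- asPlainArray(img)
  if (length(dim(arr)) != 4) stop(path, " is not a 4D image")
  pix <- RNifti::pixdim(img)
  if (is.null(trSec)) {
    trSec <- if (length(pix) >= 4) pix[4] else NA_real_
    if (!isTRUE(trSec > 0))
      stop("TR not recoverable from the header; pass trSec explicitly")
  }
  mask <- if (is.null(maskPath)) NULL else
    asPlainArray(RNifti::readNifti(maskPath)) != 0
  BoldSeries(arr, trSec = trSec, brainMask = mask,
             voxelSizeMm = pix[1:3])
}

#' Write a BoldSeries (and optionally its mask) as NIfTI
#'
#' @param series a \linkS4class{BoldSeries}.
#' @param path output 4D NIfTI path.
#' @param maskPath optional output path for the brain mask.
#' @return invisibly, \code{path}.
#' @export
writeBoldSeries <- function(series, path, maskPath = NULL) {
  stopifnot(is(series, "BoldSeries"))
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(series@voxelSizeMm, series@trSec)
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath))
    writeVolume(series@brainMask * 1L, maskPath, series@voxelSizeMm)
  invisible(path)
}

#' Write a 3D volume as NIfTI
#'
#' @param volume 3D numeric/integer/logical array.
#' @param path output path.
#' @param voxelSizeMm voxel size for the header.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path, voxelSizeMm = 3) {
  if (is.logical(volume)) volume <- volume * 1L
  img <- RNifti::asNifti(volume)
  if (length(voxelSizeMm) == 1) voxelSizeMm <- rep(voxelSizeMm, 3)
  RNifti::pixdim(img) <- voxelSizeMm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file.
#' @param logical return a logical mask (nonzero voxels)?
#' @return 3D array.
#' @export
readVolume <- function(path, logical = FALSE) {
  arr <- asPlainArray(RNifti::readNifti(path))
  if (length(dim(arr)) != 3) stop(path, " is not a 3D image")
  if (logical) arr != 0 else arr
}

#' Read / write a six-column motion trace
#'
#' Whitespace-delimited text, one row per volume: three translations (mm)
#' then three rotations (radians).
#'
#' @param path text file.
#' @return n x 6 numeric matrix.
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion trace must have 6 columns")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' @rdname readMotionTrace
#' @param trace n x 6 numeric matrix.
#' @export
writeMotionTrace <- function(trace, path) {
  stopifnot(ncol(trace) == 6)
  utils::write.table(format(trace, digits = 10), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a ComponentSet
#'
#' Writes the spatial maps as a 4D NIfTI (one volume per component), the
#' time courses as a plain-text t x k matrix and a YAML sidecar with the
#' decomposition metadata.
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param mapsPath,timecoursesPath,metadataPath output paths.
#' @param voxelSizeMm voxel size for the NIfTI header.
#' @return invisibly, \code{mapsPath}.
#' @export
writeComponentSet <- function(components, mapsPath, timecoursesPath,
                              metadataPath, voxelSizeMm = 3) {
  stopifnot(is(components, "ComponentSet"))
  k <- nComponents(components)
  d <- dim(components@mask)
  arr <- array(0, c(d, k))
  for (i in seq_len(k)) arr[, , , i] <- componentMap(components, i)
  img <- RNifti::asNifti(arr)
  if (length(voxelSizeMm) == 1) voxelSizeMm <- rep(voxelSizeMm, 3)
  RNifti::pixdim(img) <- c(voxelSizeMm, 1)
  RNifti::writeNifti(img, mapsPath)
  utils::write.table(components@timecourses, timecoursesPath, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- components@metadata
  meta$voxelMean <- NULL           # bulky numeric vector, not metadata
  meta$explainedVariance <- as.numeric(components@explainedVariance)
  yaml::write_yaml(meta, metadataPath)
  invisible(mapsPath)
}

#' Serialize / restore a fitted HicModel as plain text
#'
#' Key-value lines: one per coefficient (named by feature), plus intercept,
#' mixing alpha, lambda and the frozen probability threshold.
#'
#' @param model a \linkS4class{HicModel}.
#' @param path output text file.
#' @return invisibly, \code{path}.
#' @export
writeHicModel <- function(model, path) {
  stopifnot(is(model, "HicModel"))
  lines <- c(
    sprintf("intercept\t%.17g", model@intercept),
    sprintf("mixing_alpha\t%.17g", model@mixingAlpha),
    sprintf("shrinkage_lambda\t%.17g", model@shrinkageLambda),
    sprintf("probability_threshold\t%.17g", model@probabilityThreshold),
    sprintf("coef.%s\t%.17g", names(model@coefficients), model@coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeHicModel
#' @return \code{readHicModel}: the restored \linkS4class{HicModel}.
#' @export
readHicModel <- function(path) {
  kv <- utils::read.table(path, sep = "\t", col.names = c("key", "value"),
                          colClasses = c("character", "numeric"))
  get1 <- function(k) kv$value[kv$key == k]
  isCoef <- startsWith(kv$key, "coef.")
  co <- kv$value[isCoef]
  names(co) <- sub("^coef\\.", "", kv$key[isCoef])
  new("HicModel", coefficients = co, intercept = get1("intercept"),
      mixingAlpha = get1("mixing_alpha"),
      shrinkageLambda = get1("shrinkage_lambda"),
      probabilityThreshold = get1("probability_threshold"),
      trainingMetadata = list(restoredFrom = path))
}

#' Read / write a phantom configuration as YAML
#'
#' @param path YAML file.
#' @return a \code{\link{phantomConfig}}.
#' @export
readPhantomConfig <- function(path) {
  do.call(phantomConfig, yaml::read_yaml(path))
}

#' @rdname readPhantomConfig
#' @param config a \code{\link{phantomConfig}}.
#' @export
writePhantomConfig <- function(config, path) {
  stopifnot(inherits(config, "PhantomConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Export one simulated subject to a directory
#'
#' Writes the 4D BOLD series, atlas, brain/venous/CSF masks, ground-truth
#' Tmax and lesion volumes as NIfTI plus the motion trace as text.
#'
#' @param subject output of \code{\link{simulateSubject}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writePhantomSubject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- subject$series@voxelSizeMm
  writeBoldSeries(subject$series, file.path(dir, "bold.nii.gz"),
                  file.path(dir, "brain_mask.nii.gz"))
  writeVolume(subject$atlas, file.path(dir, "atlas.nii.gz"), vs)
  writeVolume(subject$venousMask, file.path(dir, "venous_mask.nii.gz"), vs)
  writeVolume(subject$csfMask, file.path(dir, "csf_mask.nii.gz"), vs)
  writeVolume(subject$truth@tmaxMap, file.path(dir, "tmax.nii.gz"), vs)
  writeVolume(subject$truth@lesionMask, file.path(dir, "lesion_mask.nii.gz"), vs)
  writeMotionTrace(subject$truth@motionTrace, file.path(dir, "motion.par"))
  invisible(dir)
}
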
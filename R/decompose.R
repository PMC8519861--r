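# Spatial ICA of a preprocessed BOLD series: PCA whitening over in-mask
# voxels followed by fixed-point non-Gaussianity maximisation (logcosh
# contrast, symmetric decorrelation). Each component is a Z-scaled spatial
# map paired with the corresponding mixing time course.

#' Estimate the decomposition dimensionality
#'
#' Approximate automatic model-order selection: eigenvalues of the temporal
#' covariance of the in-mask voxel-by-time matrix are compared against the
#' broken-stick null spectrum; the returned order is the length of the
#' leading run of eigenvalues exceeding their broken-stick expectation,
#' clipped to the numerical matrix rank and floored at 1.
#'
#' @param series a \linkS4class{BoldSeries} (at least 20 volumes).
#' @return integer k with 1 <= k < t.
#' @export
estimateDimensionality <- function(series) {
  stopifnot(is(series, "BoldSeries"))
  t <- nVolumes(series)
  if (t < 20) stop("dimensionality estimation needs at least 20 volumes")
  m <- voxelMatrix(series)
  m <- m - rowMeans(m)
  ev <- svd(m, nu = 0, nv = 0)$d^2
  rank <- sum(ev > max(ev) * 1e-10)
  p <- ev / sum(ev)
  bs <- rev(cumsum(1 / rev(seq_len(t)))) / t
  above <- p > bs[seq_along(p)]
  run <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  max(1L, min(run, rank, t - 1L))
}

# logcosh contrast derivatives used by the fixed-point update
icaG <- function(u) tanh(u)
icaGprime <- function(u) 1 - tanh(u)^2

#' Spatial independent component analysis
#'
#' Decomposes the in-mask voxel-by-time matrix as spatial sources times
#' mixing time courses, assuming mutual statistical independence and
#' non-Gaussianity of the spatial sources. The data are reduced to
#' \code{k} principal components and whitened across voxels; a symmetric
#' fixed-point iteration with the logcosh contrast then rotates the basis to
#' maximise spatial non-Gaussianity. Sign ambiguity is resolved by orienting
#' each map to nonnegative skewness; maps are Z-scaled (mean 0, sd 1 over
#' the mask).
#'
#' @param series a preprocessed \linkS4class{BoldSeries}.
#' @param k number of components; \code{NULL} invokes
#'   \code{\link{estimateDimensionality}}.
#' @param seed RNG seed for the random orthonormal start (decomposition is
#'   reproducible given the seed).
#' @param maxit,tol fixed-point iteration controls.
#' @return a \linkS4class{ComponentSet}; metadata records the algorithm
#'   variant, seed and convergence diagnostics.
#' @export
spatialICA <- function(series, k = NULL, seed = 1L, maxit = 500L, tol = 1e-7) {
  stopifnot(is(series, "BoldSeries"))
  m <- voxelMatrix(series)
  m <- m - rowMeans(m)            # per-voxel temporal mean
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)           # centre across voxels for whitening
  if (is.null(k)) k <- estimateDimensionality(series)
  sv <- svd(mc, nu = 0, nv = min(k, ncol(mc)))
  ev <- sv$d^2
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds the matrix rank ", rank)
  V <- nrow(mc)
  E <- sv$v[, seq_len(k), drop = FALSE]
  lam <- ev[seq_len(k)] / V
  Z <- mc %*% E %*% diag(1 / sqrt(lam), k)   # V x k, identity covariance

  W <- NULL
  niter <- NA_integer_
  withSeed(seed, {
    for (try in seq_len(5L)) {
      W0 <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
      W <- W0
      converged <- FALSE
      for (it in seq_len(maxit)) {
        U <- Z %*% t(W)
        Wn <- crossprod(icaG(U), Z) / V - diag(colMeans(icaGprime(U)), k) %*% W
        sw <- svd(Wn)
        Wn <- sw$u %*% t(sw$v)     # symmetric decorrelation
        delta <- max(abs(abs(diag(Wn %*% t(W))) - 1))
        W <- Wn
        if (delta < tol) { converged <- TRUE; niter <- it; break }
      }
      if (converged) break
      if (try == 5L) stop("spatial ICA failed to converge after 5 restarts")
    }
  })

  S <- Z %*% t(W)                               # V x k spatial sources
  A <- W %*% diag(sqrt(lam), k) %*% t(E)        # k x t mixing rows
  # orient: nonnegative map skewness; Z-scale maps and push scale into A
  for (i in seq_len(k)) {
    if (sampleSkewness(S[, i]) < 0) { S[, i] <- -S[, i]; A[i, ] <- -A[i, ] }
    ctr <- mean(S[, i]); sc <- stats::sd(S[, i])
    S[, i] <- (S[, i] - ctr) / sc
    A[i, ] <- A[i, ] * sc
  }
  evar <- vapply(seq_len(k), function(i) V * sum(A[i, ]^2), 0) / sum(mc^2)
  new("ComponentSet", maps = t(S), timecourses = t(A), mask = series@brainMask,
      explainedVariance = evar,
      metadata = list(algorithm = "fixed-point logcosh, symmetric decorrelation",
                      seed = seed, k = k, iterations = niter,
                      voxelMean = mu))
}

#' Threshold a component spatial map
#'
#' Binarises a Z-scaled spatial map at |Z| > \code{zThreshold}.
#'
#' @param map 3D numeric array of Z values (e.g. \code{\link{componentMap}}).
#' @param zThreshold the |Z| cut (default 2.33).
#' @param mask optional 3D logical restricting the result.
#' @return a \linkS4class{ThresholdedMap}; \code{empty} flags maps with no
#'   suprathreshold voxel.
#' @export
thresholdMap <- function(map, zThreshold = 2.33, mask = NULL) {
  stopifnot(length(dim(map)) == 3, zThreshold >= 0)
  m <- abs(map) > zThreshold
  if (!is.null(mask)) {
    assertSameGeometry(map, mask)
    m <- m & mask
  }
  new("ThresholdedMap", map = m, zThreshold = zThreshold, empty = !any(m))
}
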
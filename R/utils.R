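# Internal numerical helpers shared across modules.

#' @importFrom stats rnorm fft sd median quantile coef predict setNames
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never clobber the
# session RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Gaussian noise band-limited to [fLo, fHi] Hz by hard FFT masking, scaled to
# unit variance. Draws from the current RNG stream.
bandlimitedNoise <- function(n, dt, fLo, fHi) {
  stopifnot(n >= 8, dt > 0, fHi > fLo, fLo >= 0)
  x <- stats::rnorm(n)
  f <- fftFrequencies(n, dt)
  keep <- abs(f) > fLo & abs(f) <= fHi
  if (!any(keep)) stop("band [", fLo, ", ", fHi, "] Hz contains no resolvable frequency")
  xf <- stats::fft(x)
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited draw")
  y / s
}

# Signed FFT bin frequencies (Hz) for length-n series sampled every dt.
fftFrequencies <- function(n, dt) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2), -(n / 2 - 1):-1)
  k / (n * dt)
}

# Circular fractional-sample delay: y(t) = x(t - shiftSec), implemented as a
# Fourier-domain phase ramp (exact for band-limited signals).
fourierShift <- function(x, shiftSec, dt) {
  n <- length(x)
  f <- fftFrequencies(n, dt)
  ph <- exp(-2i * pi * f * shiftSec)
  # keep the Nyquist bin real-valued so the output stays real
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE)) / n
}

# Sample skewness (no bias correction; only the sign is used downstream).
sampleSkewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Flatten a 3D logical mask into in-mask voxel indices, with basic checks.
maskIndices <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  which(mask)
}

assertSameGeometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop("geometry mismatch between ", what, ": ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
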
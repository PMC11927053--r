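#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif fft cor quantile sd var pnorm
#' @importFrom utils head tail
NULL

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
## seed = NULL draws from the current stream without touching it.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Band-limited Gaussian noise by Fourier masking, unit variance.
## Returns a zero-mean signal with (sample) variance exactly `variance`.
bandNoise <- function(n, fs, band, variance = 1) {
  if (variance == 0) return(numeric(n))
  w <- rnorm(n)
  F <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  F[f < band[1] | f > band[2]] <- 0i
  x <- Re(fft(F, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band: no frequency bins inside the band")
  x <- x - mean(x)
  x * sqrt(variance) / stats::sd(x)
}

## Low-pass Gaussian noise (Fourier masking), sd 1, used for slow modulators.
lowpassNoise <- function(n, fs, fc) {
  pad <- n + 4L * as.integer(fs)            # decorrelate from circular wrap
  w <- rnorm(pad)
  F <- fft(w)
  f <- (seq_len(pad) - 1) * fs / pad
  f <- pmin(f, fs - f)
  F[f > fc] <- 0i
  z <- Re(fft(F, inverse = TRUE)) / pad
  z <- z[seq_len(n) + 2L * as.integer(fs)]
  z / stats::sd(z)
}

## 1/f^alpha background noise with the beta band optionally notched
## out; frequencies below lowCut are removed, mirroring the 0.5 Hz
## acquisition high-pass of the emulated recordings.
pinkNoise <- function(n, fs, exponent = 1, notchBand = NULL, variance = 1,
                      lowCut = 0.5) {
  if (variance == 0) return(numeric(n))
  w <- rnorm(n)
  F <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f >= lowCut, f^(-exponent / 2), 0)
  if (!is.null(notchBand)) shape[f >= notchBand[1] & f <= notchBand[2]] <- 0
  x <- Re(fft(F * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sqrt(variance) / stats::sd(x)
}

hanningTaper <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

stopifnotScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

checkBand <- function(band, fs) {
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band)))
    stop("'band' must be a numeric interval c(low, high)", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, Nyquist = %g)",
                 band[1], band[2], fs / 2), call. = FALSE)
  invisible(band)
}
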
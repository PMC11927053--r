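#' @include AllClasses.R utils.R
NULL

#' Sectioned auto- and cross-spectra
#'
#' Cuts the analysis window of every kept trial into non-overlapping
#' sections of \code{sectionLength} seconds (50 ms by default, giving
#' 55 sections per 2.75 s epoch), demeans and Hanning-tapers each
#' section, and averages the per-section Fourier auto- and
#' cross-spectra over all sections pooled across trials.  Because 50 ms
#' sections natively resolve only a 20 Hz grid, sections are
#' zero-padded to \code{padTo} seconds (1 s, i.e. a 1 Hz grid) before
#' the FFT; the native-resolution spectra are retained in the
#' \code{native} slot.
#'
#' @param x an \linkS4class{EpochedSignals} object with two channels,
#'   or an n x 2 numeric matrix treated as a single trial.
#' @param window analysis interval c(start, end) in seconds relative to
#'   the stimulus (matrix input: relative to its first sample); default
#'   the whole epoch.
#' @param sectionLength section length in seconds.
#' @param padTo zero-padded section length in seconds (values below
#'   \code{sectionLength} disable padding).
#' @param periodLabel label stored with the estimate (e.g. "pmbs").
#' @param fs sampling rate, required for matrix input.
#' @param ... passed through between methods.
#' @return a \linkS4class{SpectralEstimate}.
#' @export
setGeneric("sectionSpectra",
  function(x, window = NULL, sectionLength = 0.05, padTo = 1,
           periodLabel = "all", ...) standardGeneric("sectionSpectra"))

#' @rdname sectionSpectra
setMethod("sectionSpectra", "EpochedSignals",
  function(x, window = NULL, sectionLength = 0.05, padTo = 1,
           periodLabel = "all", ...) {
  fs <- samplingRate(x)
  times <- epochTimes(x)
  if (is.null(window)) window <- range(times)
  if (window[1] < times[1] - 1e-9 || window[2] > times[length(times)] + 1e-9)
    stop("analysis window must lie inside the epoch")
  dat <- epochData(x, keptOnly = TRUE)
  if (dim(dat)[2] < 2) stop("coherence needs two channels")
  ntr <- dim(dat)[1]
  if (ntr < 1) stop("no kept trials")
  secSamp <- round(sectionLength * fs)
  if (secSamp < 2) stop("'sectionLength' must span at least 2 samples")
  i0 <- round((window[1] - times[1]) * fs) + 1L
  i1 <- round((window[2] - times[1]) * fs) + 1L
  nwin <- i1 - i0 + 1L
  nsec <- nwin %/% secSamp
  if (nsec < 1) stop("analysis window is shorter than one section")
  ## stack all sections of all trials column-wise: secSamp x (nsec*ntr)
  secIdx <- outer(seq_len(secSamp) - 1L, (seq_len(nsec) - 1L) * secSamp, "+") + i0
  grab <- function(ch) {
    m <- vapply(seq_len(ntr), function(tr)
      matrix(dat[tr, ch, ], ncol = 1)[as.vector(secIdx), 1],
      numeric(secSamp * nsec))
    matrix(m, nrow = secSamp)
  }
  s1m <- grab(1); s2m <- grab(2)
  h <- hanningTaper(secSamp)
  taper <- function(m) (m - rep(colMeans(m), each = secSamp)) * h
  s1m <- taper(s1m); s2m <- taper(s2m)
  L <- ncol(s1m)
  padSamp <- max(secSamp, round(padTo * fs))
  spec <- function(m, npad) {
    if (npad > nrow(m)) m <- rbind(m, matrix(0, npad - nrow(m), ncol(m)))
    stats::mvfft(m)
  }
  scale <- 1 / (fs * sum(h^2))
  nk <- padSamp %/% 2L + 1L
  F1 <- spec(s1m, padSamp)[seq_len(nk), , drop = FALSE]
  F2 <- spec(s2m, padSamp)[seq_len(nk), , drop = FALSE]
  s1 <- rowMeans(Mod(F1)^2) * scale
  s2 <- rowMeans(Mod(F2)^2) * scale
  x12 <- rowMeans(F1 * Conj(F2)) * scale
  nkn <- secSamp %/% 2L + 1L
  F1n <- spec(s1m, secSamp)[seq_len(nkn), , drop = FALSE]
  F2n <- spec(s2m, secSamp)[seq_len(nkn), , drop = FALSE]
  native <- list(s1 = rowMeans(Mod(F1n)^2) * scale,
                 s2 = rowMeans(Mod(F2n)^2) * scale,
                 x12 = rowMeans(F1n * Conj(F2n)) * scale,
                 freqs = (seq_len(nkn) - 1) * fs / secSamp)
  new("SpectralEstimate", s1 = s1, s2 = s2, x12 = x12,
      freqs = (seq_len(nk) - 1) * fs / padSamp, L = as.integer(L),
      sectionLength = sectionLength, fs = fs,
      channelLabels = channelLabels(x)[1:2], native = native,
      smoothed = FALSE, periodLabel = periodLabel)
})

#' @rdname sectionSpectra
setMethod("sectionSpectra", "matrix",
  function(x, window = NULL, sectionLength = 0.05, padTo = 1,
           periodLabel = "all", fs, ...) {
  if (ncol(x) != 2) stop("matrix input must have two columns (channels)")
  dat <- array(0, dim = c(1, 2, nrow(x)))
  dat[1, 1, ] <- x[, 1]; dat[1, 2, ] <- x[, 2]
  ep <- EpochedSignals(dat, fs = fs, t0 = 0)
  sectionSpectra(ep, window = window, sectionLength = sectionLength,
                 padTo = padTo, periodLabel = periodLabel)
})

#' Triangular spectral smoothing
#'
#' Replaces each interior spectral point by the weighted sum of itself
#' (weight 0.5) and its two neighbours (weight 0.25 each); at the two
#' endpoints the available weights are renormalised to sum to one.
#' Applied to the cross-spectrum and both auto-spectra of a
#' \linkS4class{SpectralEstimate} before coherence is formed.  Vectors
#' with fewer than 3 points are returned unchanged with a warning.
#'
#' @param x a numeric or complex spectrum, or a
#'   \linkS4class{SpectralEstimate}.
#' @return same class as the input.
#' @export
setGeneric("smoothSpectrum", function(x) standardGeneric("smoothSpectrum"))

smoothVec <- function(v) {
  n <- length(v)
  if (n < 3) {
    warning("spectrum has fewer than 3 points; returned unchanged")
    return(v)
  }
  out <- v
  out[2:(n - 1)] <- 0.25 * v[1:(n - 2)] + 0.5 * v[2:(n - 1)] + 0.25 * v[3:n]
  out[1] <- (0.5 * v[1] + 0.25 * v[2]) / 0.75
  out[n] <- (0.5 * v[n] + 0.25 * v[n - 1]) / 0.75
  out
}

#' @rdname smoothSpectrum
setMethod("smoothSpectrum", "numeric", function(x) smoothVec(x))
#' @rdname smoothSpectrum
setMethod("smoothSpectrum", "complex", function(x) smoothVec(x))
#' @rdname smoothSpectrum
setMethod("smoothSpectrum", "SpectralEstimate", function(x) {
  x@s1 <- smoothVec(x@s1)
  x@s2 <- smoothVec(x@s2)
  x@x12 <- smoothVec(x@x12)
  if (length(x@native$s1) >= 3) {
    x@native$s1 <- smoothVec(x@native$s1)
    x@native$s2 <- smoothVec(x@native$s2)
    x@native$x12 <- smoothVec(x@native$x12)
  }
  x@smoothed <- TRUE
  x
})

#' Magnitude-squared coherence from a spectral estimate
#'
#' C12(f) = |X12(f)|^2 / (S1(f) S2(f)), bounded in [0, 1]; frequencies
#' at which S1 S2 = 0 are undefined and reported as NA.  The band mean
#' is the unweighted mean over frequency bins inside \code{band}.
#'
#' @param est a \linkS4class{SpectralEstimate} (smooth first with
#'   [smoothSpectrum()] to follow the reference procedure).
#' @param band frequency interval for the band mean (Hz).
#' @return a \linkS4class{CoherenceResult}.
#' @export
coherence <- function(est, band = c(14, 30)) {
  stopifnot(is(est, "SpectralEstimate"))
  if (est@L < 2) stop("coherence needs at least 2 pooled sections")
  den <- est@s1 * est@s2
  C <- ifelse(den > 0, Mod(est@x12)^2 / den, NA_real_)
  C <- pmin(C, 1)
  bins <- est@freqs >= band[1] & est@freqs <= band[2]
  if (!any(bins)) stop("no frequency bins inside the requested band")
  new("CoherenceResult", coherence = C, freqs = est@freqs,
      bandMean = mean(C[bins], na.rm = TRUE), band = band, L = est@L,
      periodLabel = est@periodLabel)
}
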
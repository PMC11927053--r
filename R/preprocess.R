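#' @include AllClasses.R utils.R
NULL

#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth band-pass (default 0.5-40 Hz) and a
#' 2nd-order Butterworth band-stop notch (default centred on 50 Hz line
#' noise), both forward-backward so the net phase response is zero and
#' latency-based measures downstream are not shifted.
#'
#' @param x numeric vector (one continuous channel) or a time x channel
#'   matrix.
#' @param fs sampling rate (Hz).
#' @param band pass band c(low, high) in Hz.
#' @param notch notch centre frequency in Hz, or NULL to skip.
#' @param notchWidth half-width of the stop band (Hz).
#' @return filtered signal, same shape as \code{x}.
#' @export
bandpassNotch <- function(x, fs, band = c(0.5, 40), notch = 50,
                          notchWidth = 2) {
  checkBand(band, fs)
  if (!is.null(notch) && (notch - notchWidth <= 0 || notch + notchWidth >= fs / 2))
    stop("notch band must lie strictly inside (0, Nyquist)")
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  flt <- function(v) {
    v <- signal::filtfilt(bp, v)
    if (!is.null(notch)) {
      ns <- signal::butter(1, c(notch - notchWidth, notch + notchWidth) / (fs / 2),
                           type = "stop")
      v <- signal::filtfilt(ns, v)
    }
    v
  }
  if (is.matrix(x)) apply(x, 2, flt) else flt(x)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One trial is extracted per event, sample-aligned to the event time.
#' Events whose window does not fit inside the recording are skipped
#' with a warning.
#'
#' @param x numeric vector or time x channel matrix of the continuous
#'   recording; the first sample is taken to be at t = 0.
#' @param fs sampling rate (Hz).
#' @param eventTimes event (imperative stimulus) times in seconds.
#' @param window epoch window c(start, end) in seconds relative to each
#'   event.
#' @param channelLabels,condition metadata for the result.
#' @return an \linkS4class{EpochedSignals} object.
#' @export
epochSignal <- function(x, fs, eventTimes, window = c(-0.25, 2.5),
                        channelLabels = NULL, condition = "unlabelled") {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  nch <- ncol(x)
  nsamp <- round(diff(window) * fs) + 1L
  starts <- round((eventTimes + window[1]) * fs) + 1L
  ok <- starts >= 1L & (starts + nsamp - 1L) <= nrow(x)
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the record edge were skipped",
                    sum(!ok)))
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), nch, nsamp))
  for (i in seq_along(keep)) {
    idx <- starts[keep[i]] + seq_len(nsamp) - 1L
    dat[i, , ] <- t(x[idx, , drop = FALSE])
  }
  EpochedSignals(dat, fs = fs, t0 = window[1],
                 channelLabels = channelLabels, condition = condition)
}

#' Trial-level amplitude artifact screening
#'
#' For every channel and time point, the mean M(t) and standard
#' deviation SD(t) are computed across all trials of the epoched data;
#' a trial is rejected when any of its samples, in any channel, lies
#' strictly outside M(t) +/- k SD(t).  The boundary is inclusive:
#' samples exactly at k SD are kept, so identical trials (SD = 0) are
#' never rejected.  Rejection operates on whole trials; the result is
#' the same object with an updated \code{keptMask} (AND-ed with the
#' existing mask).
#'
#' @param epochs an \linkS4class{EpochedSignals} object with >= 2
#'   trials.
#' @param k SD multiplier (default 5).
#' @return the epochs with updated \code{keptMask}.
#' @export
rejectArtifacts <- function(epochs, k = 5) {
  stopifnot(is(epochs, "EpochedSignals"))
  stopifnotScalar(k, "k", positive = TRUE)
  d <- epochs@data
  ntr <- dim(d)[1]
  if (ntr < 2) stop("artifact screening needs at least 2 trials")
  bad <- rep(FALSE, ntr)
  for (ch in seq_len(dim(d)[2])) {
    xc <- d[, ch, ]                        # trials x time
    M <- colMeans(xc)
    SD <- sqrt(colMeans(xc^2) - M^2)
    SD <- pmax(SD, 0)
    dev <- abs(sweep(xc, 2, M)) - k * rep(SD, each = ntr)
    bad <- bad | apply(dev > 1e-12, 1, any)
  }
  newMask <- epochs@keptMask & !bad
  if (!any(newMask))
    stop("no trials survive artifact screening at k = ", k)
  epochs@keptMask <- newMask
  epochs
}
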
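#' @include AllClasses.R utils.R
NULL

#' Sliding-window time-frequency power (trial-averaged)
#'
#' Short-time Fourier power with a frequency-adaptive window of
#' \code{cycles} cycles (window length = cycles / f seconds), a Hanning
#' taper, and window centres advanced in steps of \code{timeStep}
#' seconds.  Power at (f, t) is the squared magnitude of the tapered
#' Fourier coefficient at f from the window centred at t, averaged
#' across kept trials.  Window positions that would cross the epoch
#' boundary are marked unavailable (NA).
#'
#' @param epochs an \linkS4class{EpochedSignals} object.
#' @param freqs analysed frequencies in Hz (default 5-40 Hz in 0.25 Hz
#'   steps).
#' @param cycles cycles per window (default 3).
#' @param timeStep window-centre step in seconds (default 20 ms).
#' @return a \linkS4class{PowerTfr} object.
#' @export
computeTfr <- function(epochs, freqs = seq(5, 40, by = 0.25), cycles = 3,
                       timeStep = 0.02) {
  stopifnot(is(epochs, "EpochedSignals"))
  dat <- epochData(epochs, keptOnly = TRUE)
  ntr <- dim(dat)[1]
  if (ntr < 1) stop("no kept trials to analyse")
  fs <- samplingRate(epochs)
  nsamp <- dim(dat)[3]
  nch <- dim(dat)[2]
  t0 <- epochs@t0
  times <- seq(t0, t0 + (nsamp - 1) / fs, by = timeStep)
  nt <- length(times)
  centres <- round((times - t0) * fs) + 1L
  pow <- array(NA_real_, dim = c(nch, length(freqs), nt))
  ## channel data as time x trial matrices (gathered by linear index)
  xc <- lapply(seq_len(nch), function(ch) t(dat[, ch, ]))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    wl <- max(3L, round(cycles / f * fs))
    half <- wl %/% 2L
    starts <- centres - half
    avail <- starts >= 1L & (starts + wl - 1L) <= nsamp
    if (!any(avail))
      stop(sprintf("no window position fits the epoch at %g Hz", f))
    st <- starts[avail]
    na <- length(st)
    h <- hanningTaper(wl)
    ang <- -2 * pi * f * (0:(wl - 1)) / fs
    kc <- h * cos(ang)
    ks <- h * sin(ang)
    scale <- 2 / (fs * sum(h^2))
    idx <- outer(st, 0:(wl - 1L), "+")            # na x wl
    idxBig <- idx[rep(seq_len(na), ntr), , drop = FALSE] +
      rep((seq_len(ntr) - 1L) * nsamp, each = na)
    for (ch in seq_len(nch)) {
      G <- matrix(xc[[ch]][idxBig], nrow = na * ntr)
      pv <- ((G %*% kc)^2 + (G %*% ks)^2) * scale
      pow[ch, fi, avail] <- rowMeans(matrix(pv, nrow = na))
    }
  }
  new("PowerTfr", power = pow, freqs = freqs, times = times,
      channelLabels = channelLabels(epochs), fs = fs,
      nTrials = as.integer(ntr))
}

#' Baseline-normalise a time-frequency decomposition
#'
#' Converts power to relative power RP = (P - Prest) / Prest * 100,
#' where Prest is, per channel and frequency, the mean power over the
#' available window centres inside the baseline interval.  Frequencies
#' whose adaptive window is too long for any centre to fit inside the
#' baseline are returned as NA with a warning.
#'
#' @param tfr a \linkS4class{PowerTfr} object.
#' @param baselineWindow baseline interval c(start, end) in seconds
#'   (default the 250 ms before the stimulus).
#' @return a \linkS4class{RelativePowerMap}.
#' @export
baselineNormalize <- function(tfr, baselineWindow = c(-0.25, 0)) {
  stopifnot(is(tfr, "PowerTfr"))
  inBl <- tfr@times >= baselineWindow[1] & tfr@times <= baselineWindow[2]
  if (!any(inBl)) stop("baseline window contains no window centres")
  nch <- dim(tfr@power)[1]
  nf <- length(tfr@freqs)
  rp <- array(NA_real_, dim = dim(tfr@power))
  prest <- matrix(NA_real_, nch, nf,
                  dimnames = list(tfr@channelLabels, NULL))
  noBaseline <- logical(nf)
  for (ch in seq_len(nch)) {
    for (fi in seq_len(nf)) {
      p <- tfr@power[ch, fi, ]
      bl <- p[inBl]
      bl <- bl[!is.na(bl)]
      if (length(bl) == 0) { noBaseline[fi] <- TRUE; next }
      pr <- mean(bl)
      if (pr == 0)
        stop(sprintf("degenerate baseline: zero power at %g Hz", tfr@freqs[fi]))
      prest[ch, fi] <- pr
      rp[ch, fi, ] <- (p - pr) / pr * 100
    }
  }
  if (any(noBaseline))
    warning(sprintf(
      "no baseline window centre available at %d frequenc%s (e.g. %g Hz); RP set to NA there",
      sum(noBaseline), if (sum(noBaseline) > 1) "ies" else "y",
      tfr@freqs[which(noBaseline)[1]]))
  new("RelativePowerMap", rp = rp, power = tfr@power, prest = prest,
      freqs = tfr@freqs, times = tfr@times,
      channelLabels = tfr@channelLabels, baselineWindow = baselineWindow)
}

#' Beta-band mean relative-power time course
#'
#' Collapses the time-frequency map to the time domain by taking, per
#' channel and time, the unweighted mean of relative power over all
#' frequency bins inside the band (boundaries inclusive); unavailable
#' (NA) bins are excluded from the mean.  Time points at which fewer
#' than \code{minCoverage} of the band's bins are available (the first
#' and last window positions of the epoch, where only the shortest
#' high-frequency windows fit) are reported as NA rather than as a
#' mean over a handful of edge bins.
#'
#' @param rp a \linkS4class{RelativePowerMap}.
#' @param band frequency interval c(low, high) in Hz (default 14-30).
#' @param minCoverage minimum fraction of in-band bins that must be
#'   available for a time point to be reported (default 1: the band
#'   mean is only defined where every in-band bin has a window,
#'   because a partial mean would systematically overweight the high
#'   frequencies whose shorter windows still fit).
#' @return object of class "betaTimecourse": a list with \code{times},
#'   \code{values} (channel x time matrix), \code{band} and
#'   \code{channelLabels}.
#' @export
betaTimecourse <- function(rp, band = c(14, 30), minCoverage = 1) {
  stopifnot(is(rp, "RelativePowerMap"))
  bins <- which(rp@freqs >= band[1] & rp@freqs <= band[2])
  if (length(bins) == 0)
    stop("no frequency bins inside the requested band")
  nch <- dim(rp@rp)[1]
  vals <- matrix(NA_real_, nch, length(rp@times),
                 dimnames = list(rp@channelLabels, NULL))
  for (ch in seq_len(nch)) {
    if (length(bins) == 1) {
      vals[ch, ] <- rp@rp[ch, bins, ]
    } else {
      sub <- matrix(rp@rp[ch, bins, ], nrow = length(bins))
      v <- colMeans(sub, na.rm = TRUE)
      v[colMeans(!is.na(sub)) < minCoverage] <- NA_real_
      vals[ch, ] <- v
    }
  }
  vals[is.nan(vals)] <- NA_real_
  structure(list(times = rp@times, values = vals, band = band,
                 channelLabels = rp@channelLabels),
            class = "betaTimecourse")
}

## First index at which `flag` holds for `sustain` consecutive entries.
firstSustained <- function(flag, sustain) {
  flag[is.na(flag)] <- FALSE
  if (sustain <= 1) return(if (any(flag)) which(flag)[1] else NA_integer_)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= sustain)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

## Index of the curve extreme with a tie tolerance: all points within
## `tol` of the extreme are treated as an extremal plateau and the
## median index of that set is returned.  This makes the "peak" of a
## flat-topped burst well defined instead of being decided by noise.
extremeIndex <- function(v, which = c("min", "max"), tol = 0) {
  which <- match.arg(which)
  ex <- if (which == "min") min(v, na.rm = TRUE) else max(v, na.rm = TRUE)
  idx <- if (which == "min") which(!is.na(v) & v <= ex + tol)
         else                which(!is.na(v) & v >= ex - tol)
  idx[ceiling(length(idx) / 2)]
}

#' Extract MRBD / PMBS features from a beta time course
#'
#' Detects, per channel, the movement-related beta desynchronization
#' (MRBD) and the post-movement beta synchronization (PMBS) on the
#' band-mean relative-power time course using the 10 percent-threshold
#' rules: the MRBD onset is the first time after \code{movementOnset}
#' at which relative power falls to or below \code{-threshold} and
#' stays there for \code{sustain} consecutive time steps; its end is
#' the first later return above \code{-threshold}.  The MRBD value is
#' the mean relative power over a window of \code{valueWindow} seconds
#' centred on the trough between onset and end.  PMBS landmarks are
#' defined analogously with the \code{+threshold} crossing and the
#' burst maximum, searched after the MRBD end.  Value windows that
#' would cross the epoch edge are clipped with a warning.  Features of
#' a deflection that never crosses threshold are NA.
#'
#' @param tc a "betaTimecourse" from [betaTimecourse()].
#' @param movementOnset time anchoring the search (s); the imperative
#'   stimulus at 0 by default.
#' @param threshold onset/offset threshold in percent (default 10).
#' @param sustain consecutive time steps required beyond threshold for
#'   an onset (default 3, i.e. 60 ms at the default 20 ms step).
#' @param valueWindow averaging window for the MRBD/PMBS values (s).
#' @param peakTol tie tolerance for locating the burst extremum, in
#'   percentage points: all points within \code{peakTol} of the
#'   extreme value are treated as an extremal plateau and the peak is
#'   placed at the median of that set.  The default of 2 points is
#'   small relative to the 10-point threshold that defines a burst; it
#'   keeps the peak location well defined on flat-topped bursts where
#'   the raw argmax would be decided by estimation noise.
#' @return an \linkS4class{ErspFeatures} object.
#' @export
extractErspFeatures <- function(tc, movementOnset = 0, threshold = 10,
                                sustain = 3, valueWindow = 0.2,
                                peakTol = 2) {
  stopifnot(inherits(tc, "betaTimecourse"))
  times <- tc$times
  nch <- nrow(tc$values)
  half <- valueWindow / 2
  rows <- vector("list", nch)
  for (ch in seq_len(nch)) {
    v <- tc$values[ch, ]
    burst <- function(fromTime, sign) {
      eligible <- times >= fromTime
      flag <- eligible & (sign * v >= threshold)
      on <- firstSustained(flag, sustain)
      if (is.na(on))
        return(list(onset = NA_real_, end = NA_real_, value = NA_real_,
                    peakTime = NA_real_))
      after <- seq_along(v) > on & !is.na(v)
      ret <- which(after & (sign * v < threshold))
      endIdx <- if (length(ret)) ret[1] else length(v)
      seg <- on:endIdx
      exIdx <- seg[extremeIndex(sign * v[seg], "max", tol = peakTol)]
      wlo <- times[exIdx] - half
      whi <- times[exIdx] + half
      if (wlo < times[1] || whi > times[length(times)])
        warning("value window clipped at the epoch edge")
      w <- times >= wlo & times <= whi
      list(onset = times[on], end = times[endIdx],
           value = mean(v[w], na.rm = TRUE), peakTime = times[exIdx])
    }
    mrbd <- burst(movementOnset, -1)
    pmbsFrom <- if (!is.na(mrbd$end)) mrbd$end else movementOnset
    pmbs <- burst(pmbsFrom, +1)
    rows[[ch]] <- data.frame(
      channel = tc$channelLabels[ch],
      mrbdValue = mrbd$value, mrbdOnset = mrbd$onset, mrbdEnd = mrbd$end,
      mrbdDuration = mrbd$end - mrbd$onset,
      pmbsValue = pmbs$value, pmbsLatency = pmbs$onset, pmbsEnd = pmbs$end,
      pmbsPeakTime = pmbs$peakTime, pmbsDuration = pmbs$end - pmbs$onset,
      stringsAsFactors = FALSE)
  }
  new("ErspFeatures", features = do.call(rbind, rows),
      band = tc$band, threshold = threshold, sustain = as.integer(sustain))
}
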
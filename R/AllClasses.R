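#' EpochedSignals: epoched multichannel recordings
#'
#' Container for stimulus-locked epochs of a multichannel recording, the
#' central data object of the package.  The data array is organised as
#' trials x channels x time; the time axis starts at \code{t0} seconds
#' relative to the imperative stimulus and advances at the sampling rate.
#' A per-trial logical \code{keptMask} tracks artifact screening; analysis
#' functions only consume trials with \code{keptMask == TRUE}.
#'
#' @slot data numeric array, trials x channels x time, amplitudes (uV).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds relative to the stimulus.
#' @slot channelLabels character vector, one label per channel (for
#'   right-hand movement, "C3" records CM1 and "C4" records IM1).
#' @slot condition free-form condition label (e.g. "ballistic").
#' @slot keptMask logical vector, one flag per trial.
#'
#' @seealso [genBilateralEpochs()], [epochSignal()], [rejectArtifacts()]
#' @export
setClass("EpochedSignals",
  representation(data = "array", fs = "numeric", t0 = "numeric",
                 channelLabels = "character", condition = "character",
                 keptMask = "logical"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
      return("'data' must be a trials x channels x time array")
    if (d[2] != length(object@channelLabels))
      return("number of channels does not match 'channelLabels'")
    if (d[1] != length(object@keptMask))
      return("'keptMask' must have one entry per trial")
    if (length(object@fs) != 1L || object@fs <= 0)
      return("'fs' must be a single positive number")
    if (length(object@t0) != 1L || !is.finite(object@t0))
      return("'t0' must be a single finite number")
    TRUE
  })

#' Construct an EpochedSignals object
#'
#' @param data trials x channels x time numeric array.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to the stimulus (s).
#' @param channelLabels channel names; defaults to "C3", "C4" for two
#'   channels.
#' @param condition condition label.
#' @param keptMask per-trial logical mask; defaults to all \code{TRUE}.
#' @return an \linkS4class{EpochedSignals} object.
#' @export
EpochedSignals <- function(data, fs, t0 = -0.25,
                           channelLabels = NULL,
                           condition = "unlabelled",
                           keptMask = NULL) {
  if (is.null(channelLabels)) {
    nch <- dim(data)[2]
    channelLabels <- if (nch == 2) c("C3", "C4") else paste0("ch", seq_len(nch))
  }
  if (is.null(keptMask)) keptMask <- rep(TRUE, dim(data)[1])
  new("EpochedSignals", data = data, fs = fs, t0 = t0,
      channelLabels = channelLabels, condition = condition,
      keptMask = keptMask)
}

#' PowerTfr: trial-averaged time-frequency power
#'
#' Power at each (channel, frequency, time) node from the sliding-window
#' Hanning-taper decomposition, averaged over kept trials.  Nodes whose
#' adaptive window does not fit inside the epoch are \code{NA}.
#'
#' @slot power channel x frequency x time array (uV^2/Hz scale).
#' @slot freqs analysed frequencies (Hz).
#' @slot times window-centre times (s).
#' @slot channelLabels channel names.
#' @slot fs sampling rate of the underlying epochs (Hz).
#' @slot nTrials number of trials averaged.
#' @export
setClass("PowerTfr",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 channelLabels = "character", fs = "numeric",
                 nTrials = "integer"),
  validity = function(object) {
    d <- dim(object@power)
    if (length(d) != 3L) return("'power' must be channel x freq x time")
    if (d[1] != length(object@channelLabels)) return("channel mismatch")
    if (d[2] != length(object@freqs)) return("frequency mismatch")
    if (d[3] != length(object@times)) return("time mismatch")
    TRUE
  })

#' RelativePowerMap: baseline-normalised time-frequency power
#'
#' Relative power RP = (P - Prest) / Prest * 100 (percent change from the
#' pre-stimulus baseline), per channel, frequency and time.  Also retains
#' the raw power and the per-frequency baseline power.
#'
#' @slot rp channel x frequency x time array of percent change.
#' @slot power the un-normalised power (same layout).
#' @slot prest channel x frequency matrix of mean baseline power.
#' @slot freqs,times,channelLabels axes, as in \linkS4class{PowerTfr}.
#' @slot baselineWindow the baseline interval (s).
#' @export
setClass("RelativePowerMap",
  representation(rp = "array", power = "array", prest = "matrix",
                 freqs = "numeric", times = "numeric",
                 channelLabels = "character", baselineWindow = "numeric"),
  validity = function(object) {
    if (!all(dim(object@rp) == dim(object@power)))
      return("'rp' and 'power' must have identical dimensions")
    if (any(object@rp < -100 - 1e-8, na.rm = TRUE))
      return("relative power cannot fall below -100 percent")
    TRUE
  })

#' ErspFeatures: MRBD / PMBS amplitudes and landmarks
#'
#' One row per channel with the movement-related beta desynchronization
#' (MRBD) and post-movement beta synchronization (PMBS) amplitudes (mean
#' percent change over a 200 ms window centred on the trough/peak) and
#' their 10 percent-threshold timing landmarks.  Landmarks are \code{NA}
#' when the corresponding deflection never crosses threshold.
#'
#' @slot features data.frame with columns channel, mrbdValue, mrbdOnset,
#'   mrbdEnd, mrbdDuration, pmbsValue, pmbsLatency, pmbsEnd, pmbsPeakTime,
#'   pmbsDuration.
#' @slot band beta band analysed (Hz).
#' @slot threshold onset/offset threshold (percent).
#' @slot sustain number of consecutive time steps required beyond
#'   threshold for an onset.
#' @export
setClass("ErspFeatures",
  representation(features = "data.frame", band = "numeric",
                 threshold = "numeric", sustain = "integer"))

#' SpectralEstimate: pooled sectioned auto- and cross-spectra
#'
#' Auto-spectra and cross-spectrum averaged over all non-overlapping
#' sections pooled across kept trials, on a zero-padded frequency grid
#' (the native section-resolution spectra are retained alongside).
#'
#' @slot s1,s2 auto-spectra of channels 1 and 2.
#' @slot x12 complex cross-spectrum.
#' @slot freqs frequency grid of the padded spectra (Hz).
#' @slot L total number of pooled sections.
#' @slot sectionLength section length (s).
#' @slot fs sampling rate (Hz).
#' @slot channelLabels the two channel names.
#' @slot native list with the unpadded (native-resolution) s1, s2, x12
#'   and freqs.
#' @slot smoothed whether [smoothSpectrum()] has been applied.
#' @slot periodLabel analysis-window label (e.g. "pmbs").
#' @export
setClass("SpectralEstimate",
  representation(s1 = "numeric", s2 = "numeric", x12 = "complex",
                 freqs = "numeric", L = "integer", sectionLength = "numeric",
                 fs = "numeric", channelLabels = "character",
                 native = "list", smoothed = "logical",
                 periodLabel = "character"),
  validity = function(object) {
    n <- length(object@freqs)
    if (length(object@s1) != n || length(object@s2) != n ||
        length(object@x12) != n)
      return("spectra and frequency grid lengths differ")
    if (any(object@s1 < -1e-12) || any(object@s2 < -1e-12))
      return("auto-spectra must be non-negative")
    TRUE
  })

#' CoherenceResult: magnitude-squared coherence spectrum
#'
#' @slot coherence coherence in [0, 1] per frequency (NA where undefined).
#' @slot freqs frequency grid (Hz).
#' @slot bandMean mean coherence over the beta band.
#' @slot band band used for the mean (Hz).
#' @slot L number of pooled sections behind the estimate.
#' @slot periodLabel analysis-window label.
#' @export
setClass("CoherenceResult",
  representation(coherence = "numeric", freqs = "numeric",
                 bandMean = "numeric", band = "numeric", L = "integer",
                 periodLabel = "character"),
  validity = function(object) {
    ok <- object@coherence[!is.na(object@coherence)]
    if (any(ok < -1e-8 | ok > 1 + 1e-8))
      return("coherence must lie in [0, 1]")
    TRUE
  })

#' MvarModel: fitted multivariate autoregressive model
#'
#' Coefficients of X(t) = sum_i A(i) X(t-i) + E(t) estimated from
#' trial-averaged lag covariances via the Levinson-Wiggins-Robinson
#' recursion, with the innovation covariance of E(t).
#'
#' @slot A k x k x p coefficient array.
#' @slot noiseCov k x k innovation covariance.
#' @slot order model order p.
#' @slot fs sampling rate (Hz).
#' @slot channelLabels channel names.
#' @slot nObs effective number of observations behind the covariance
#'   estimates.
#' @export
setClass("MvarModel",
  representation(A = "array", noiseCov = "matrix", order = "integer",
                 fs = "numeric", channelLabels = "character",
                 nObs = "numeric"),
  validity = function(object) {
    d <- dim(object@A)
    if (length(d) != 3L || d[1] != d[2])
      return("'A' must be a k x k x p array")
    if (object@order != d[3]) return("'order' does not match dim(A)[3]")
    if (!isTRUE(all.equal(object@noiseCov, t(object@noiseCov),
                          tolerance = 1e-6)))
      return("innovation covariance must be symmetric")
    TRUE
  })

#' DirCohResult: directed coherence spectra
#'
#' Directed coherence DirCoh[i <- j](f) derived from the MVAR transfer
#' function, with band means per direction and the analytic significance
#' threshold Z = 1 - alpha^(1/(L-1)) when the pooled section count L is
#' supplied.
#'
#' @slot dircoh k x k x nfreq array; element [i, j, ] is the influence of
#'   channel j on channel i.
#' @slot freqs frequency grid (Hz).
#' @slot bandMeans k x k matrix of band-mean directed coherence.
#' @slot band band used for the means (Hz).
#' @slot Z significance threshold (NA when L unknown).
#' @slot alpha significance level.
#' @slot L pooled section count behind Z (NA when unknown).
#' @slot mode "normalized" or "literal" (see [directedCoherence()]).
#' @slot channelLabels channel names.
#' @export
setClass("DirCohResult",
  representation(dircoh = "array", freqs = "numeric", bandMeans = "matrix",
                 band = "numeric", Z = "numeric", alpha = "numeric",
                 L = "integer", mode = "character",
                 channelLabels = "character"))

#' MepTrialSet: single-trial motor-evoked-potential waveforms
#'
#' EMG waveforms around a TMS test stimulus, one row per trial, digitised
#' at 5 kHz.  \code{mode} distinguishes single test-stimulus trials
#' ("ts") from conditioned paired-pulse trials ("cs").  Peak-to-peak
#' amplitudes are filled in by [mepPeakToPeak()].
#'
#' @slot waveforms trials x time matrix (mV).
#' @slot fs sampling rate (Hz).
#' @slot stimulusTime time of the test stimulus within the trace (s).
#' @slot mode per-trial mode, "ts" or "cs".
#' @slot condition condition label (speed, TMS timing).
#' @slot amplitudes per-trial peak-to-peak amplitude (mV), NA until
#'   extracted.
#' @export
setClass("MepTrialSet",
  representation(waveforms = "matrix", fs = "numeric",
                 stimulusTime = "numeric", mode = "character",
                 condition = "character", amplitudes = "numeric"),
  validity = function(object) {
    n <- nrow(object@waveforms)
    if (length(object@mode) != n) return("'mode' must have one entry per trial")
    if (!all(object@mode %in% c("ts", "cs")))
      return("'mode' entries must be \"ts\" or \"cs\"")
    if (length(object@amplitudes) != n)
      return("'amplitudes' must have one entry per trial")
    if (any(object@amplitudes < 0, na.rm = TRUE))
      return("amplitudes must be non-negative")
    TRUE
  })

#' IhiResult: interhemispheric inhibition ratio
#'
#' Condition-level inhibition ratio: mean conditioned (CS) MEP amplitude
#' over mean unconditioned test-stimulus (TS) MEP amplitude.  Values
#' below 1 signal inhibition.
#'
#' @slot condition condition label.
#' @slot meanTs,meanCs mean peak-to-peak amplitudes (mV).
#' @slot ihi the ratio as a fraction (primary scale).
#' @slot ihiPercent the same ratio times 100.
#' @slot nTs,nCs trial counts.
#' @slot tsAmplitudes,csAmplitudes the per-trial amplitudes.
#' @export
setClass("IhiResult",
  representation(condition = "character", meanTs = "numeric",
                 meanCs = "numeric", ihi = "numeric", ihiPercent = "numeric",
                 nTs = "integer", nCs = "integer",
                 tsAmplitudes = "numeric", csAmplitudes = "numeric"),
  validity = function(object) {
    if (!is.na(object@ihi) && object@ihi < 0) return("'ihi' must be >= 0")
    TRUE
  })

#' ConditionReport: end-to-end results for one condition
#'
#' @slot condition condition label.
#' @slot ersp \linkS4class{ErspFeatures}.
#' @slot coherence named list of \linkS4class{CoherenceResult} (per
#'   analysis period).
#' @slot dircoh named list of \linkS4class{DirCohResult}.
#' @slot ihi an \linkS4class{IhiResult}, or NULL when no MEP data.
#' @slot provenance list with seed, package version and parameters.
#' @export
setClass("ConditionReport",
  representation(condition = "character", ersp = "ErspFeatures",
                 coherence = "list", dircoh = "list", ihi = "ANY",
                 provenance = "list"))
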
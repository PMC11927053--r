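#' @include AllClasses.R utils.R
NULL

#' Peak-to-peak MEP amplitude extraction
#'
#' Fills the \code{amplitudes} slot of a \linkS4class{MepTrialSet}:
#' for every trial, amplitude = max - min of the waveform within the
#' search window after the test stimulus.  The default window of
#' 15-50 ms spans typical hand-muscle MEP latencies.
#'
#' @param trials a \linkS4class{MepTrialSet}.
#' @param searchWindow c(start, end) in seconds after the test
#'   stimulus.
#' @return the trial set with amplitudes filled in.
#' @export
mepPeakToPeak <- function(trials, searchWindow = c(0.015, 0.050)) {
  stopifnot(is(trials, "MepTrialSet"))
  n <- ncol(trials@waveforms)
  tt <- (seq_len(n) - 1) / trials@fs
  lo <- trials@stimulusTime + searchWindow[1]
  hi <- trials@stimulusTime + searchWindow[2]
  if (lo < 0 || hi > tt[n])
    stop("search window lies outside the recorded waveform")
  sel <- tt >= lo & tt <= hi
  w <- trials@waveforms[, sel, drop = FALSE]
  trials@amplitudes <- apply(w, 1, max) - apply(w, 1, min)
  validObject(trials)
  trials
}

#' Interhemispheric inhibition ratio
#'
#' IHI = mean conditioned (CS) MEP amplitude / mean unconditioned test
#' (TS) MEP amplitude, reported as a fraction (values below 1 signal
#' inhibition of the test response by the conditioning pulse); the
#' equivalent percentage is also stored.  The ratio of means (rather
#' than the mean of per-trial ratios) is used because single-pulse and
#' paired-pulse trials are interleaved but unpaired.  Amplitudes are
#' extracted with [mepPeakToPeak()] if not already present.
#'
#' @param tsTrials \linkS4class{MepTrialSet} of single test-stimulus
#'   trials (or a mixed set; only mode "ts" rows are used).
#' @param csTrials \linkS4class{MepTrialSet} of conditioned trials
#'   (omit when \code{tsTrials} is a mixed set containing both modes).
#' @param searchWindow passed to [mepPeakToPeak()] when amplitudes are
#'   missing.
#' @return an \linkS4class{IhiResult}.
#' @export
computeIhi <- function(tsTrials, csTrials = NULL,
                       searchWindow = c(0.015, 0.050)) {
  stopifnot(is(tsTrials, "MepTrialSet"))
  fill <- function(s) {
    if (anyNA(s@amplitudes)) mepPeakToPeak(s, searchWindow) else s
  }
  if (is.null(csTrials)) {
    s <- fill(tsTrials)
    tsAmp <- s@amplitudes[s@mode == "ts"]
    csAmp <- s@amplitudes[s@mode == "cs"]
    cond <- s@condition
  } else {
    stopifnot(is(csTrials, "MepTrialSet"))
    ts <- fill(tsTrials); cs <- fill(csTrials)
    tsAmp <- ts@amplitudes[ts@mode == "ts"]
    csAmp <- cs@amplitudes[cs@mode == "cs"]
    cond <- ts@condition
  }
  if (length(tsAmp) < 1 || length(csAmp) < 1)
    stop("need at least one trial of each mode")
  mTs <- mean(tsAmp); mCs <- mean(csAmp)
  if (mTs == 0) stop("undefined IHI ratio: mean TS amplitude is zero")
  new("IhiResult", condition = cond, meanTs = mTs, meanCs = mCs,
      ihi = mCs / mTs, ihiPercent = 100 * mCs / mTs,
      nTs = length(tsAmp), nCs = length(csAmp),
      tsAmplitudes = tsAmp, csAmplitudes = csAmp)
}
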
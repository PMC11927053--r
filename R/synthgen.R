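#' @include AllClasses.R utils.R
NULL

#' Generate a band-limited beta oscillation
#'
#' Produces a zero-mean stochastic oscillation whose power is
#' concentrated in the requested band.  Two carrier models are
#' available:
#' \describe{
#'   \item{\code{"sweep"} (default)}{a constant-envelope oscillation
#'     whose instantaneous frequency sweeps the band with a triangular
#'     profile of randomised phase and slowly jittered period.  Because
#'     the envelope is constant, the short-time band power of the signal
#'     equals its variance at every instant, which makes amplitude-
#'     envelope ground truth exact for time-frequency analyses.}
#'   \item{\code{"gaussian"}}{band-limited Gaussian noise obtained by
#'     Fourier masking of white noise; spectrally flat inside the band.
#'     This is the natural model when Gaussian section statistics are
#'     wanted (e.g. coherence studies).}
#' }
#'
#' @param band frequency interval c(low, high) in Hz, strictly inside
#'   (0, fs/2); defaults to the beta band 14-30 Hz.
#' @param duration signal duration in seconds.
#' @param fs sampling rate in Hz.
#' @param variance target signal variance; 0 yields an all-zero signal.
#' @param seed optional integer seed (the caller's RNG state is
#'   preserved).
#' @param model carrier model, \code{"sweep"} or \code{"gaussian"}.
#' @param sweepRate mean band-sweep rate in Hz (sweep model); the
#'   default 6.5 Hz makes one full band traversal fit inside a 3-cycle
#'   analysis window at mid-beta frequencies.
#' @param sweepJitter relative slow modulation of the sweep rate.
#' @param edgeMargin fraction of the bandwidth kept clear at each band
#'   edge so that modulation sidebands stay inside the band.
#' @return numeric vector of length \code{round(duration * fs)}.
#' @examples
#' x <- genBetaOscillation(c(14, 30), 1, 1000, 1, seed = 1)
#' var(x)
#' @export
genBetaOscillation <- function(band = c(14, 30), duration, fs, variance = 1,
                               seed = NULL, model = c("sweep", "gaussian"),
                               sweepRate = 6.5, sweepJitter = 0.15,
                               edgeMargin = 0.08) {
  model <- match.arg(model)
  stopifnotScalar(duration, "duration", positive = TRUE)
  stopifnotScalar(fs, "fs", positive = TRUE)
  stopifnotScalar(variance, "variance")
  if (variance < 0) stop("'variance' must be >= 0")
  checkBand(band, fs)
  n <- round(duration * fs)
  if (variance == 0) return(numeric(n))
  withSeed(seed, {
    if (model == "gaussian") {
      bandNoise(n, fs, band, variance)
    } else {
      sweepCarrier(n, fs, band, variance, sweepRate, sweepJitter, edgeMargin)
    }
  })
}

## Constant-envelope triangular-FM carrier (see genBetaOscillation).
sweepCarrier <- function(n, fs, band, variance, sweepRate, sweepJitter,
                         edgeMargin) {
  m <- diff(band) * edgeMargin
  lo <- band[1] + m
  hi <- band[2] - m
  jit <- lowpassNoise(n, fs, 1)
  rate <- sweepRate * (1 + sweepJitter * tanh(jit))
  theta <- cumsum(rate) / fs + runif(1)
  tri <- 2 * abs(theta %% 1 - 0.5)          # triangle in [0, 1]
  finst <- lo + (hi - lo) * tri
  phi <- 2 * pi * cumsum(finst) / fs + runif(1, 0, 2 * pi)
  sqrt(2 * variance) * cos(phi)
}

#' Default per-channel amplitude envelopes for the two movement speeds
#'
#' Plateau amplitude factors reproducing the group-mean MRBD and PMBS
#' relative-power levels of ballistic and self-paced right index-finger
#' abduction on the contralateral (C3/CM1) and ipsilateral (C4/IM1)
#' motor cortex.  A relative-power change of \code{p} percent
#' corresponds to an amplitude factor \code{sqrt(1 + p/100)}, applied
#' here as an MRBD plateau during movement (0.15-0.65 s) and a PMBS
#' plateau after movement end (1.2-1.8 s).
#'
#' @param speed "ballistic" or "self_paced".
#' @return named list (C3, C4) of data.frames with columns start, end,
#'   factor (s, s, unitless).
#' @export
defaultEnvelopes <- function(speed = c("ballistic", "self_paced")) {
  speed <- match.arg(speed)
  lv <- switch(speed,
    ballistic  = list(mrbd = c(-45.76, -37.83), pmbs = c(83.30, 58.64)),
    self_paced = list(mrbd = c(-42.34, -37.02), pmbs = c(55.27, 38.24)))
  mk <- function(i) data.frame(
    start  = c(0.15, 1.2),
    end    = c(0.65, 1.8),
    factor = sqrt(1 + c(lv$mrbd[i], lv$pmbs[i]) / 100))
  list(C3 = mk(1), C4 = mk(2))
}

#' Synthetic bilateral EEG configuration
#'
#' Assembles and validates the parameters of [genBilateralEpochs()].
#' Defaults mirror the acquisition of the emulated study: 1 kHz
#' sampling, epochs from -0.25 to 2.5 s around the imperative stimulus,
#' 60 trials per condition, beta band 14-30 Hz.
#'
#' @param samplingRate Hz.
#' @param epochWindow c(start, end) in seconds relative to the stimulus.
#' @param nTrials number of trials.
#' @param betaBand beta band (Hz).
#' @param betaVariance variance of the (unit-envelope) beta component.
#' @param backgroundExponent 1/f exponent of the background.
#' @param betaToBackgroundRatio ratio of beta variance to in-band
#'   background variance (realistic mode only).
#' @param envelopes named list per channel of data.frames with columns
#'   start, end, factor; defaults to [defaultEnvelopes()] for the given
#'   speed.
#' @param speed movement speed used for the default envelopes, and
#'   stored as the condition label.
#' @param rampMs raised-cosine ramp duration flanking each plateau (ms).
#' @param couplingMode "none", "shared_source" or "lagged_ar".
#' @param couplingParams for "shared_source": list(varShared, varNoise)
#'   with varShared + varNoise = 1; for "lagged_ar": list(coupling, lag)
#'   with lag in samples and |coupling| <= 1.
#' @param pureBand if TRUE (default) the epochs contain only the
#'   enveloped beta component, so amplitude-envelope ground truth is
#'   exact; if FALSE a 1/f background is added.
#' @param carrier carrier model passed to [genBetaOscillation()].
#' @param seed integer seed.
#' @return a validated list of class "SynthEegConfig".
#' @export
synthEegConfig <- function(samplingRate = 1000, epochWindow = c(-0.25, 2.5),
                           nTrials = 60, betaBand = c(14, 30),
                           betaVariance = 1, backgroundExponent = 1,
                           betaToBackgroundRatio = 1, envelopes = NULL,
                           speed = c("ballistic", "self_paced"),
                           rampMs = 50,
                           couplingMode = c("none", "shared_source", "lagged_ar"),
                           couplingParams = list(), pureBand = TRUE,
                           carrier = c("sweep", "gaussian"), seed = NULL) {
  speed <- match.arg(speed)
  couplingMode <- match.arg(couplingMode)
  carrier <- match.arg(carrier)
  checkBand(betaBand, samplingRate)
  if (nTrials < 0 || nTrials != round(nTrials))
    stop("'nTrials' must be a non-negative integer")
  if (is.null(envelopes)) envelopes <- defaultEnvelopes(speed)
  for (ch in names(envelopes)) {
    e <- envelopes[[ch]]
    if (!all(c("start", "end", "factor") %in% names(e)))
      stop("each envelope needs columns start, end, factor")
    if (any(e$factor <= 0))
      stop("envelope amplitude factors must be > 0")
    if (any(e$start < epochWindow[1]) || any(e$end > epochWindow[2]) ||
        any(e$start >= e$end))
      stop("envelope plateaus must lie within the epoch window")
    if (nrow(e) > 1) {
      o <- order(e$start)
      if (any(e$end[o][-nrow(e)] > e$start[o][-1]))
        stop("overlapping plateaus on channel ", ch)
    }
  }
  if (couplingMode == "shared_source") {
    p <- couplingParams
    if (is.null(p$varShared) || is.null(p$varNoise))
      stop("shared_source coupling needs couplingParams$varShared and $varNoise")
    if (p$varShared < 0 || p$varNoise < 0)
      stop("mixing variances must be non-negative")
    if (abs(p$varShared + p$varNoise - 1) > 1e-8)
      stop("shared_source mixing variances must sum to 1")
  }
  if (couplingMode == "lagged_ar") {
    p <- couplingParams
    if (is.null(p$coupling) || is.null(p$lag))
      stop("lagged_ar coupling needs couplingParams$coupling and $lag")
    if (abs(p$coupling) > 1)
      stop("|coupling| must be <= 1 for a stable mixture")
  }
  structure(list(samplingRate = samplingRate, epochWindow = epochWindow,
                 nTrials = as.integer(nTrials), betaBand = betaBand,
                 betaVariance = betaVariance,
                 backgroundExponent = backgroundExponent,
                 betaToBackgroundRatio = betaToBackgroundRatio,
                 envelopes = envelopes, speed = speed, rampMs = rampMs,
                 couplingMode = couplingMode, couplingParams = couplingParams,
                 pureBand = pureBand, carrier = carrier, seed = seed),
            class = "SynthEegConfig")
}

## Amplitude envelope over the epoch time axis: unity baseline, plateaus
## at `factor`, raised-cosine ramps of rampS seconds on both flanks.
buildEnvelope <- function(times, plateaus, rampS) {
  e <- rep(1, length(times))
  for (r in seq_len(nrow(plateaus))) {
    s <- plateaus$start[r]; en <- plateaus$end[r]; g <- plateaus$factor[r]
    on <- times >= s & times <= en
    up <- times > s - rampS & times < s
    dn <- times > en & times < en + rampS
    e[on] <- g
    e[up] <- 1 + (g - 1) * 0.5 * (1 - cos(pi * (times[up] - (s - rampS)) / rampS))
    e[dn] <- g + (1 - g) * 0.5 * (1 - cos(pi * (times[dn] - en) / rampS))
  }
  e
}

#' Generate synthetic bilateral beta epochs
#'
#' Simulates stimulus-locked two-channel (C3/C4) epochs containing a
#' beta-band oscillation whose amplitude follows per-channel plateau
#' envelopes (movement-related desynchronization followed by a
#' post-movement rebound), optionally over a 1/f background, and with
#' configurable interhemispheric coupling: none, a shared band-limited
#' source, or a lagged unidirectional mixture (C4 driven by C3).
#'
#' @param cfg a [synthEegConfig()] object.
#' @return an \linkS4class{EpochedSignals} object with
#'   \code{cfg$nTrials} trials and channels C3, C4.
#' @export
genBilateralEpochs <- function(cfg) {
  stopifnot(inherits(cfg, "SynthEegConfig"))
  fs <- cfg$samplingRate
  n <- round(diff(cfg$epochWindow) * fs) + 1L
  times <- cfg$epochWindow[1] + (seq_len(n) - 1) / fs
  chans <- names(cfg$envelopes)
  nch <- length(chans)
  env <- vapply(chans, function(ch)
    buildEnvelope(times, cfg$envelopes[[ch]], cfg$rampMs / 1000), numeric(n))
  dur <- n / fs
  gen <- function() genBetaOscillation(cfg$betaBand, dur, fs,
                                       cfg$betaVariance, seed = NULL,
                                       model = cfg$carrier)[seq_len(n)]
  bgInband <- NULL
  if (!cfg$pureBand && is.finite(cfg$betaToBackgroundRatio)) {
    bgInband <- cfg$betaVariance / cfg$betaToBackgroundRatio
  }
  dat <- array(0, dim = c(cfg$nTrials, nch, n))
  withSeed(cfg$seed, {
    for (tr in seq_len(cfg$nTrials)) {
      beta <- switch(cfg$couplingMode,
        none = vapply(seq_len(nch), function(i) gen(), numeric(n)),
        shared_source = {
          p <- cfg$couplingParams
          s <- gen()
          vapply(seq_len(nch), function(i)
            sqrt(p$varShared) * s + sqrt(p$varNoise) * gen(), numeric(n))
        },
        lagged_ar = {
          p <- cfg$couplingParams
          x <- gen()
          lagged <- c(rep(0, p$lag), x[seq_len(n - p$lag)])
          cbind(x, p$coupling * lagged +
                    sqrt(1 - p$coupling^2) * gen())
        })
      for (i in seq_len(nch)) {
        xi <- beta[, i] * env[, i]
        if (!is.null(bgInband)) {
          xi <- xi + pinkBackground(n, fs, cfg$backgroundExponent,
                                    cfg$betaBand, bgInband)
        }
        dat[tr, i, ] <- xi
      }
    }
  })
  EpochedSignals(dat, fs = fs, t0 = cfg$epochWindow[1],
                 channelLabels = chans, condition = cfg$speed)
}

## 1/f background scaled so that its variance inside `band` equals
## `inbandVar`.
pinkBackground <- function(n, fs, exponent, band, inbandVar) {
  x <- pinkNoise(n, fs, exponent, notchBand = NULL, variance = 1)
  F <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  frac <- sum(F[f >= band[1] & f <= band[2]]) / sum(F)
  x * sqrt(inbandVar / frac)
}

#' Generate a shared-source signal pair with known coherence
#'
#' Builds x = s + n1 and y = s + n2 from three independent band-limited
#' Gaussian processes with variances \code{varShared}, \code{varNoise},
#' \code{varNoise}.  Because all three components share the same (flat)
#' in-band spectral shape, the theoretical magnitude-squared coherence
#' inside the band is \code{varShared^2 / (varShared + varNoise)^2} at
#' every frequency.
#'
#' @param varShared variance of the common source.
#' @param varNoise variance of each private noise process.
#' @param band frequency band (Hz).
#' @param duration seconds.
#' @param fs Hz.
#' @param seed optional integer seed.
#' @return list with elements \code{x}, \code{y}, \code{fs}, \code{band}
#'   and \code{cohTheory} (the closed-form in-band coherence).
#' @export
genSharedSourcePair <- function(varShared, varNoise, band = c(14, 30),
                                duration = 0.5, fs = 1000, seed = NULL) {
  stopifnotScalar(varShared, "varShared")
  stopifnotScalar(varNoise, "varNoise")
  if (varShared < 0 || varNoise < 0) stop("variances must be non-negative")
  if (varShared + varNoise <= 0) stop("total variance must be > 0")
  checkBand(band, fs)
  n <- round(duration * fs)
  withSeed(seed, {
    s  <- bandNoise(n, fs, band, varShared)
    n1 <- bandNoise(n, fs, band, varNoise)
    n2 <- bandNoise(n, fs, band, varNoise)
    list(x = s + n1, y = s + n2, fs = fs, band = band,
         cohTheory = varShared^2 / (varShared + varNoise)^2)
  })
}

#' Generate a unidirectionally AR-coupled signal pair
#'
#' Simulates the stable bivariate autoregressive system
#' \deqn{x_t = a_1 x_{t-1} + e_{1,t}, \qquad
#'       y_t = a_2 y_{t-1} + c\, x_{t-lag} + e_{2,t},}
#' in which x is driven by its own innovations only while y receives a
#' lagged copy of x: causality is x -> y by construction, making the
#' pair a ground-truth benchmark for directed-coherence estimators.
#'
#' @param coupling coupling coefficient c.
#' @param lag coupling lag in samples (>= 1).
#' @param nSamples length of the simulated series (after burn-in).
#' @param seed optional integer seed.
#' @param ar1,ar2 own-history AR(1) coefficients of x and y.
#' @param innovSd innovation standard deviations, length 2.
#' @param burnin samples discarded at the start.
#' @return list with \code{x}, \code{y}, the true coefficient array
#'   \code{A} (2 x 2 x p), \code{noiseCov}, \code{coupling} and
#'   \code{lag}.
#' @export
genArCoupledPair <- function(coupling, lag = 1L, nSamples, seed = NULL,
                             ar1 = 0.5, ar2 = 0.5, innovSd = c(1, 1),
                             burnin = 500L) {
  stopifnotScalar(coupling, "coupling")
  if (lag < 1 || lag != round(lag)) stop("'lag' must be a positive integer")
  p <- max(1L, as.integer(lag))
  A <- array(0, dim = c(2, 2, p))
  A[1, 1, 1] <- ar1
  A[2, 2, 1] <- ar2
  A[2, 1, lag] <- A[2, 1, lag] + coupling
  if (!mvarStable(A))
    stop("unstable coefficient set: companion spectral radius >= 1")
  ntot <- nSamples + burnin
  withSeed(seed, {
    e1 <- rnorm(ntot, sd = innovSd[1])
    e2 <- rnorm(ntot, sd = innovSd[2])
    x <- numeric(ntot); y <- numeric(ntot)
    for (t in seq_len(ntot)) {
      xl <- if (t > 1) x[t - 1] else 0
      yl <- if (t > 1) y[t - 1] else 0
      xc <- if (t > lag) x[t - lag] else 0
      x[t] <- ar1 * xl + e1[t]
      y[t] <- ar2 * yl + coupling * xc + e2[t]
    }
    idx <- burnin + seq_len(nSamples)
    list(x = x[idx], y = y[idx], A = A,
         noiseCov = diag(innovSd^2), coupling = coupling, lag = lag)
  })
}

#' Synthetic MEP trial configuration
#'
#' Parameters of [genMepTrials()].  Defaults emulate the paired-pulse
#' protocol of the emulated study: 30 single test-stimulus (TS) trials
#' and 30 conditioned (CS-TS) trials, EMG digitised at 5 kHz, target
#' mean peak-to-peak amplitudes of 1.50 mV (TS) and 0.78 mV (CS).
#'
#' @param nTrials trials per mode.
#' @param tsMean,tsSd mean and SD of the single-TS peak-to-peak
#'   amplitude distribution (mV); draws are truncated at 0.
#' @param csMean,csSd same for conditioned trials (mV).
#' @param fs sampling rate (Hz).
#' @param latencyMs MEP onset latency after the test stimulus (ms).
#' @param durationMs MEP waveform duration (ms).
#' @param noiseSd baseline EMG noise SD (mV).
#' @param traceMs total trace duration (ms); the test stimulus sits at
#'   \code{stimulusMs}.
#' @param stimulusMs test-stimulus time within the trace (ms).
#' @param condition condition label.
#' @param seed integer seed.
#' @return a validated list of class "SynthMepConfig".
#' @export
synthMepConfig <- function(nTrials = 30, tsMean = 1.50, tsSd = 0.10,
                           csMean = 0.78, csSd = 0.10, fs = 5000,
                           latencyMs = 22, durationMs = 12, noiseSd = 0.005,
                           traceMs = 120, stimulusMs = 20,
                           condition = "ballistic_peak", seed = NULL) {
  if (tsMean <= 0 || csMean <= 0) stop("MEP means must be > 0")
  if (tsSd < 0 || csSd < 0 || noiseSd < 0) stop("SDs must be >= 0")
  if (nTrials < 1) stop("'nTrials' must be >= 1")
  if (stimulusMs + latencyMs + durationMs > traceMs)
    stop("MEP waveform does not fit inside the trace")
  structure(list(nTrials = as.integer(nTrials), tsMean = tsMean, tsSd = tsSd,
                 csMean = csMean, csSd = csSd, fs = fs,
                 latencyMs = latencyMs, durationMs = durationMs,
                 noiseSd = noiseSd, traceMs = traceMs,
                 stimulusMs = stimulusMs, condition = condition,
                 seed = seed),
            class = "SynthMepConfig")
}

## Normal draws truncated at zero (rejection sampling; exact for sd = 0).
truncNormal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate synthetic MEP trials
#'
#' Each trial is a biphasic MEP template placed at the configured
#' latency after the test stimulus, scaled so that its peak-to-peak
#' amplitude equals a draw from the mode's truncated normal amplitude
#' distribution, superposed on Gaussian baseline noise.
#'
#' @param cfg a [synthMepConfig()] object.
#' @return an \linkS4class{MepTrialSet} with \code{2 * cfg$nTrials}
#'   trials ("ts" then "cs").
#' @export
genMepTrials <- function(cfg) {
  stopifnot(inherits(cfg, "SynthMepConfig"))
  fs <- cfg$fs
  n <- round(cfg$traceMs / 1000 * fs)
  tt <- (seq_len(n) - 1) / fs
  onset <- (cfg$stimulusMs + cfg$latencyMs) / 1000
  durS <- cfg$durationMs / 1000
  inMep <- tt >= onset & tt <= onset + durS
  u <- (tt[inMep] - onset) / durS
  template <- numeric(n)
  template[inMep] <- sin(2 * pi * u) * (0.5 - 0.5 * cos(2 * pi * u))
  template <- template / (max(template) - min(template))  # unit peak-to-peak
  ntr <- 2L * cfg$nTrials
  withSeed(cfg$seed, {
    amps <- c(truncNormal(cfg$nTrials, cfg$tsMean, cfg$tsSd),
              truncNormal(cfg$nTrials, cfg$csMean, cfg$csSd))
    wf <- matrix(rnorm(ntr * n, sd = cfg$noiseSd), nrow = ntr)
    wf <- wf + outer(amps, template)
    new("MepTrialSet", waveforms = wf, fs = fs,
        stimulusTime = cfg$stimulusMs / 1000,
        mode = rep(c("ts", "cs"), each = cfg$nTrials),
        condition = cfg$condition, amplitudes = rep(NA_real_, ntr))
  })
}
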
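# Shared fixtures built in code at test time.

# Epochs holding a shared-source pair per trial (channels C3/C4).
sharedPairEpochs <- function(varShared, varNoise, nTrials = 60,
                             duration = 0.5, fs = 1000, seed = 1) {
  n <- round(duration * fs)
  dat <- array(0, dim = c(nTrials, 2, n))
  if (!is.null(seed)) set.seed(seed)
  for (tr in seq_len(nTrials)) {
    p <- genSharedSourcePair(varShared, varNoise, duration = duration, fs = fs)
    dat[tr, 1, ] <- p$x
    dat[tr, 2, ] <- p$y
  }
  EpochedSignals(dat, fs = fs, t0 = 0)
}

# Epochs of independent white noise.
whiteNoiseEpochs <- function(nTrials, nSamples, fs = 1000, seed = 1) {
  set.seed(seed)
  dat <- array(rnorm(nTrials * 2 * nSamples), dim = c(nTrials, 2, nSamples))
  EpochedSignals(dat, fs = fs, t0 = 0)
}

# Single-plateau synthetic config on channel C3 (IM1-side channel gets a
# flat envelope), as used by the parameter-recovery suites.
plateauConfig <- function(factor, start, end, nTrials = 60, seed = 1) {
  synthEegConfig(
    nTrials = nTrials,
    envelopes = list(
      C3 = data.frame(start = start, end = end, factor = factor),
      C4 = data.frame(start = numeric(0), end = numeric(0),
                      factor = numeric(0))),
    seed = seed)
}

# Group-level beta timecourse: average of `nSubjects` independently
# simulated runs of `cfg` (seeds derived from cfg$seed), evaluated on
# the beta-band portion of the frequency grid.
groupBetaTimecourse <- function(cfg, nSubjects = 8) {
  acc <- NULL
  tc <- NULL
  for (s in seq_len(nSubjects)) {
    cfg$seed <- cfg$seed + s
    ep <- rejectArtifacts(genBilateralEpochs(cfg))
    tfr <- computeTfr(ep, freqs = seq(14, 30, by = 0.25))
    tc <- betaTimecourse(baselineNormalize(tfr))
    acc <- if (is.null(acc)) tc$values else acc + tc$values
  }
  tc$values <- acc / nSubjects
  tc
}

# Manual MvarModel from known coefficients.
mvarFromTruth <- function(A, noiseCov, fs = 1000,
                          labels = c("C3", "C4")[seq_len(nrow(noiseCov))]) {
  new("MvarModel", A = A, noiseCov = noiseCov,
      order = as.integer(dim(A)[3]), fs = fs, channelLabels = labels,
      nObs = Inf)
}
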
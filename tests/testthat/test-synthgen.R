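test_that("beta oscillation concentrates power in band at the requested variance", {
  for (model in c("sweep", "gaussian")) {
    x <- genBetaOscillation(c(14, 30), 30, 1000, variance = 1, seed = 3,
                            model = model)
    expect_length(x, 30000)
    expect_lt(abs(mean(x)), 0.05)
    expect_lt(abs(var(x) - 1), 0.05)
    # Welch-style spectral oracle: periodogram in-band power fraction
    P <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * 1000 / length(x)
    f <- pmin(f, 1000 - f)
    inband <- sum(P[f >= 14 & f <= 30]) / sum(P)
    expect_gt(inband, 0.95)
  }
})

test_that("beta oscillation handles degenerate and invalid parameters", {
  expect_identical(genBetaOscillation(c(14, 30), 1, 1000, variance = 0),
                   numeric(1000))
  expect_error(genBetaOscillation(c(14, 600), 1, 1000), "Nyquist")
  expect_error(genBetaOscillation(c(30, 14), 1, 1000))
  expect_error(genBetaOscillation(c(14, 30), -1, 1000), "duration")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(genBetaOscillation(c(14, 30), 2, 1000, seed = 7),
                   genBetaOscillation(c(14, 30), 2, 1000, seed = 7))
  expect_false(isTRUE(all.equal(
    genBetaOscillation(c(14, 30), 2, 1000, seed = 7),
    genBetaOscillation(c(14, 30), 2, 1000, seed = 8))))
  cfg <- plateauConfig(1.3, 1.2, 1.8, nTrials = 3, seed = 5)
  expect_identical(epochData(genBilateralEpochs(cfg)),
                   epochData(genBilateralEpochs(cfg)))
  mc <- synthMepConfig(nTrials = 5, seed = 9)
  expect_identical(genMepTrials(mc)@waveforms, genMepTrials(mc)@waveforms)
})

test_that("envelope conservation: plateau mean square equals factor^2 x baseline", {
  for (fac in c(0.7365, 1.35388)) {
    cfg <- plateauConfig(fac, 1.2, 1.8, nTrials = 10, seed = 21)
    ep <- genBilateralEpochs(cfg)
    tt <- epochTimes(ep)
    d <- epochData(ep)
    plateau <- d[, 1, tt >= 1.25 & tt <= 1.75]
    baseline <- d[, 1, tt >= -0.25 & tt <= 1.0]
    ratio <- mean(plateau^2) / mean(baseline^2)
    expect_lt(abs(ratio / fac^2 - 1), 0.02)
  }
})

test_that("bilateral epoch container and config validation behave", {
  cfg <- plateauConfig(1.3, 1.2, 1.8, nTrials = 0)
  ep <- genBilateralEpochs(cfg)
  expect_s4_class(ep, "EpochedSignals")
  expect_identical(nTrials(ep), 0L)
  expect_identical(dim(epochData(ep))[3], 2751L)
  expect_error(synthEegConfig(envelopes = list(
    C3 = data.frame(start = c(0.1, 0.3), end = c(0.5, 0.8),
                    factor = c(1, 1.2)),
    C4 = data.frame(start = 0.1, end = 0.2, factor = 1))),
    "overlapping")
  expect_error(synthEegConfig(envelopes = list(
    C3 = data.frame(start = 0.1, end = 0.5, factor = -1))), "factor")
  expect_error(synthEegConfig(envelopes = list(
    C3 = data.frame(start = -1, end = 0.5, factor = 1))), "epoch window")
  expect_error(synthEegConfig(couplingMode = "shared_source",
                              couplingParams = list(varShared = 0.6,
                                                    varNoise = 0.6)),
               "sum to 1")
  expect_error(synthEegConfig(couplingMode = "lagged_ar",
                              couplingParams = list(coupling = 1.5, lag = 2)))
})

test_that("shared-source pair: closed-form coherence and degenerate limits", {
  p <- genSharedSourcePair(0.65574, 0.34426, duration = 1, seed = 2)
  expect_equal(p$cohTheory, 0.65574^2 / (0.65574 + 0.34426)^2)
  expect_equal(round(p$cohTheory, 4), 0.43)
  expect_equal(genSharedSourcePair(0.4899, 0.5101, seed = 1)$cohTheory,
               0.24, tolerance = 1e-4)
  # varNoise = 0: the two signals are the same source -> coherence 1
  ep <- sharedPairEpochs(1, 0, nTrials = 5, seed = 4)
  co <- coherence(smoothSpectrum(sectionSpectra(ep)))
  expect_equal(bandMean(co), 1, tolerance = 1e-10)
  # varShared = 0: independent -> near chance level
  ep0 <- sharedPairEpochs(0, 1, nTrials = 30, seed = 5)
  co0 <- coherence(smoothSpectrum(sectionSpectra(ep0)))
  expect_lt(bandMean(co0), 0.05)
  expect_error(genSharedSourcePair(-0.1, 0.5), "non-negative")
  expect_error(genSharedSourcePair(0, 0), "> 0")
})

test_that("AR-coupled pair matches the analytic Yule-Walker covariances", {
  pair <- genArCoupledPair(0.8, lag = 1, nSamples = 40000, seed = 6)
  X <- cbind(pair$x, pair$y)
  # independent oracle: stationary covariance from the discrete
  # Lyapunov fixed point P = A P A' + Q of the VAR(1) system
  A <- pair$A[, , 1]
  Q <- pair$noiseCov
  P <- Q
  for (i in 1:200) P <- A %*% P %*% t(A) + Q
  G0 <- crossprod(X) / nrow(X)
  G1 <- crossprod(X[-1, ], X[-nrow(X), ]) / nrow(X)
  expect_lt(max(abs(G0 - P)), 0.06 * max(abs(P)))
  expect_lt(max(abs(G1 - A %*% P)), 0.06 * max(abs(P)))
  expect_error(genArCoupledPair(0.5, lag = 1, nSamples = 10, ar1 = 1.05),
               "unstable")
})

test_that("MEP trials follow the configured amplitude distributions", {
  mc0 <- synthMepConfig(nTrials = 10, tsSd = 0, csSd = 0, noiseSd = 0,
                        seed = 1)
  meps <- mepPeakToPeak(genMepTrials(mc0))
  amp <- mepAmplitudes(meps)
  expect_equal(unname(amp[meps@mode == "ts"]), rep(1.50, 10), tolerance = 1e-12)
  expect_equal(unname(amp[meps@mode == "cs"]), rep(0.78, 10), tolerance = 1e-12)
  expect_equal(computeIhi(meps)@ihi, 0.52, tolerance = 1e-12)
  # truncation keeps amplitudes non-negative even for wide distributions
  mcw <- synthMepConfig(nTrials = 200, tsMean = 0.1, tsSd = 0.5,
                        csMean = 0.1, csSd = 0.5, noiseSd = 0, seed = 2)
  expect_true(all(mepAmplitudes(mepPeakToPeak(genMepTrials(mcw))) >= 0))
  expect_error(synthMepConfig(tsMean = -1), "> 0")
  expect_error(synthMepConfig(tsSd = -0.1), ">= 0")
})
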
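test_that("band-pass preserves the beta range and removes line noise and DC", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  mid <- t > 2 & t < 8                      # avoid filter edge transients
  s20 <- sin(2 * pi * 20 * t)
  y20 <- bandpassNotch(s20, fs)
  gain20 <- sd(y20[mid]) / sd(s20[mid])
  expect_lt(abs(gain20 - 1), 0.055)
  expect_gt(gain20, 10^(-1 / 20))           # within 1 dB of unity
  expect_lt(gain20, 10^(1 / 20))
  s50 <- sin(2 * pi * 50 * t)
  y50 <- bandpassNotch(s50, fs)
  expect_lt(sd(y50[mid]) / sd(s50[mid]), 10^(-20 / 20))  # > 20 dB down
  dc <- rep(2, length(t))
  expect_lt(max(abs(bandpassNotch(dc, fs)[mid])), 0.05)
  expect_error(bandpassNotch(s20, fs, band = c(0.5, 600)), "Nyquist")
})

test_that("filtering is linear", {
  fs <- 1000
  set.seed(11)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_equal(bandpassNotch(a + b, fs),
               bandpassNotch(a, fs) + bandpassNotch(b, fs),
               tolerance = 1e-8)
})

test_that("epoching aligns trials to events and skips edge events", {
  fs <- 1000
  x <- rnorm(10000)
  x[5000] <- 100                            # marker at t = 4.999 s
  ep <- epochSignal(x, fs, eventTimes = c(1, 4.999, 6), window = c(-0.25, 2.5))
  expect_identical(nTrials(ep), 3L)
  tt <- epochTimes(ep)
  expect_equal(epochData(ep)[2, 1, which.min(abs(tt))], 100)
  expect_warning(
    ep2 <- epochSignal(x, fs, eventTimes = c(0.1, 1, 6), window = c(-0.25, 2.5)),
    "skipped")
  expect_identical(nTrials(ep2), 2L)
  expect_identical(nTrials(epochSignal(x, fs, numeric(0))), 0L)
})

test_that("artifact screening rejects only strictly exceeding trials", {
  # identical trials: SD = 0 everywhere, inclusive boundary keeps all
  dat <- array(rep(sin(seq_len(100) / 5), each = 4), dim = c(4, 1, 100))
  ep <- EpochedSignals(dat, fs = 100, channelLabels = "C3")
  expect_true(all(keptMask(rejectArtifacts(ep, k = 5))))
  # one trial with a single large spike is the only rejection (the
  # spike must clear k SD even after inflating the per-timepoint SD
  # it contributes to, which needs > k^2 + 1 trials)
  set.seed(3)
  dat <- array(rnorm(60 * 2 * 300), dim = c(60, 2, 300))
  ep <- EpochedSignals(dat, fs = 1000)
  base <- rejectArtifacts(ep, k = 5)
  expect_true(all(keptMask(base)))
  dat[7, 2, 150] <- dat[7, 2, 150] + 15 * sd(dat[, 2, 150])
  epSpike <- EpochedSignals(dat, fs = 1000)
  expect_identical(which(!keptMask(rejectArtifacts(epSpike, k = 5))), 7L)
  expect_error(rejectArtifacts(EpochedSignals(dat[1, , , drop = FALSE],
                                              fs = 1000)), "2 trials")
})

test_that("screening at k = 5 keeps stationary Gaussian data (tail 2*pnorm(-5))", {
  # expected per-sample exceedance 2*pnorm(-5) ~ 5.7e-7: none of the
  # 3e4 samples here should exceed
  ep <- whiteNoiseEpochs(30, 500, seed = 12)
  expect_true(all(keptMask(rejectArtifacts(ep, k = 5))))
  # at k = 3 the exceedance rate (~2.7e-3 per sample) rejects every
  # long trial, which is the explicit no-survivor error path
  epLong <- whiteNoiseEpochs(30, 2000, seed = 13)
  expect_error(rejectArtifacts(epLong, k = 3), "survive")
})

test_that("artifact screening is idempotent on its own output", {
  set.seed(4)
  dat <- array(rnorm(30 * 2 * 200), dim = c(30, 2, 200))
  dat[5, 1, 10] <- 50
  ep <- EpochedSignals(dat, fs = 1000)
  once <- rejectArtifacts(ep, k = 5)
  twice <- rejectArtifacts(once, k = 5)
  expect_identical(keptMask(once), keptMask(twice))
})

test_that("epochs survive a disk round trip unchanged", {
  cfg <- plateauConfig(1.2, 1.0, 1.6, nTrials = 3, seed = 8)
  ep <- genBilateralEpochs(cfg)
  keptMask(ep) <- c(TRUE, FALSE, TRUE)
  dir <- withr::local_tempdir()
  writeEpochs(ep, dir)
  back <- readEpochs(dir, conditionLabel(ep))
  expect_equal(epochData(back), epochData(ep), tolerance = 1e-10)
  expect_identical(keptMask(back), keptMask(ep))
  expect_identical(samplingRate(back), samplingRate(ep))
  expect_identical(channelLabels(back), channelLabels(ep))
  expect_error(readEpochs(dir, "nope"), "no epoch files")
})
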
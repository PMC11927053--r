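test_that("TFR of a stationary sinusoid concentrates power at its frequency", {
  fs <- 1000
  n <- 2751
  dat <- array(0, dim = c(2, 1, n))
  tt <- -0.25 + (seq_len(n) - 1) / fs
  set.seed(1)
  for (tr in 1:2) dat[tr, 1, ] <- sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi))
  ep <- EpochedSignals(dat, fs = fs, t0 = -0.25, channelLabels = "C3")
  tfr <- computeTfr(ep, freqs = c(10, 20))
  p <- tfrPower(tfr)
  mid <- which.min(abs(tfrTimes(tfr) - 1))
  expect_gt(p[1, 2, mid], 20 * p[1, 1, mid])
  # adaptive window: at 10 Hz (0.3 s window) the first centres are
  # unavailable, and fewer of them than at 20 Hz (0.15 s window)
  expect_gt(sum(is.na(p[1, 1, ])), sum(is.na(p[1, 2, ])))
})

test_that("baseline normalisation follows RP = (P - Prest)/Prest * 100", {
  freqs <- c(10, 20)
  times <- seq(-0.25, 0.75, by = 0.02)
  pow <- array(NA_real_, dim = c(1, 2, length(times)))
  base <- times <= 0
  pow[1, 1, ] <- 4
  pow[1, 2, ] <- ifelse(base, 2, NA)
  pow[1, 2, times > 0.2] <- c(2, 4, 1.0848)[1 + (seq_len(sum(times > 0.2)) %% 3)]
  tfr <- new("PowerTfr", power = pow, freqs = freqs, times = times,
             channelLabels = "C3", fs = 1000, nTrials = 1L)
  rp <- baselineNormalize(tfr)
  v <- relativePower(rp)
  expect_true(all(abs(v[1, 1, ]) < 1e-12))              # P = Prest -> 0
  post <- v[1, 2, times > 0.2]
  expect_true(all(abs(post[post > 50] - 100) < 1e-9))   # 2x -> +100
  # 0.5424 x Prest -> -45.76, the arithmetic image of the printed MRBD
  expect_equal(unique(round(post[post < 0], 2)), -45.76)
  # degenerate baseline errors; missing baseline yields NA + warning
  pow0 <- pow; pow0[1, 1, base] <- 0
  tfr0 <- new("PowerTfr", power = pow0, freqs = freqs, times = times,
              channelLabels = "C3", fs = 1000, nTrials = 1L)
  expect_error(baselineNormalize(tfr0), "degenerate baseline")
  powNA <- pow; powNA[1, 1, base] <- NA
  tfrNA <- new("PowerTfr", power = powNA, freqs = freqs, times = times,
               channelLabels = "C3", fs = 1000, nTrials = 1L)
  expect_warning(rpNA <- baselineNormalize(tfrNA), "no baseline")
  expect_true(all(is.na(relativePower(rpNA)[1, 1, ])))
})

test_that("beta timecourse is the unweighted mean over in-band bins", {
  freqs <- seq(14, 30, by = 0.25)
  times <- seq(0, 1, by = 0.02)
  a <- 0.8
  rp <- array(rep(a * freqs, times = length(times)),
              dim = c(1, length(freqs), length(times)))
  m <- new("RelativePowerMap", rp = rp, power = rp + 200,
           prest = matrix(1, 1, length(freqs)), freqs = freqs,
           times = times, channelLabels = "C3",
           baselineWindow = c(-0.25, 0))
  tc <- betaTimecourse(m, band = c(14, 30))
  expect_equal(unname(tc$values[1, ]), rep(a * 22, length(times)))
  tc1 <- betaTimecourse(m, band = c(20, 20))      # single-bin band
  expect_equal(unname(tc1$values[1, ]), rep(a * 20, length(times)))
  expect_error(betaTimecourse(m, band = c(50, 60)), "no frequency bins")
})

test_that("MRBD/PMBS landmarks follow the 10%-threshold rules", {
  times <- seq(-0.25, 2.5, by = 0.02)
  v <- numeric(length(times))
  v[times >= 0.15 & times <= 0.65] <- -50
  v[times >= 1.0 & times <= 1.6] <- 80
  tc <- structure(list(times = times, values = matrix(v, 1),
                       band = c(14, 30), channelLabels = "C3"),
                  class = "betaTimecourse")
  f <- featureTable(extractErspFeatures(tc))
  expect_equal(f$mrbdValue, -50)
  expect_equal(f$mrbdOnset, 0.15)
  expect_lt(abs(f$mrbdEnd - 0.67), 0.021)
  expect_equal(f$pmbsValue, 80)
  expect_true(f$pmbsPeakTime >= 1.0 && f$pmbsPeakTime <= 1.6)
  # flat-topped bursts: tie rule centres the peak
  expect_equal(f$pmbsPeakTime, 1.3, tolerance = 0.021)
  expect_equal(f$mrbdDuration, f$mrbdEnd - f$mrbdOnset)
})

test_that("threshold crossings need the sustain count; absent bursts are NA", {
  times <- seq(-0.25, 2.5, by = 0.02)
  # never below -10: MRBD absent
  v <- numeric(length(times)); v[times >= 1 & times <= 1.5] <- 30
  tc <- structure(list(times = times, values = matrix(v, 1),
                       band = c(14, 30), channelLabels = "C3"),
                  class = "betaTimecourse")
  f <- featureTable(extractErspFeatures(tc))
  expect_true(is.na(f$mrbdValue) && is.na(f$mrbdOnset))
  expect_false(is.na(f$pmbsValue))
  # a single-sample threshold crossing does not make an onset at sustain = 3
  v2 <- numeric(length(times)); v2[50] <- -15
  tc2 <- structure(list(times = times, values = matrix(v2, 1),
                        band = c(14, 30), channelLabels = "C3"),
                   class = "betaTimecourse")
  f2 <- featureTable(extractErspFeatures(tc2, sustain = 3))
  expect_true(is.na(f2$mrbdOnset))
  f2b <- featureTable(extractErspFeatures(tc2, sustain = 1))
  expect_false(is.na(f2b$mrbdOnset))
})

test_that("baseline neutrality: envelope-free data stay within 3 points", {
  cfg <- synthEegConfig(
    nTrials = 60,
    envelopes = list(C3 = data.frame(start = numeric(0), end = numeric(0),
                                     factor = numeric(0)),
                     C4 = data.frame(start = numeric(0), end = numeric(0),
                                     factor = numeric(0))),
    seed = 31)
  ep <- genBilateralEpochs(cfg)
  tfr <- computeTfr(ep, freqs = seq(14, 30, by = 0.25))
  tc <- betaTimecourse(baselineNormalize(tfr))
  expect_lt(max(abs(tc$values), na.rm = TRUE), 3)
})

test_that("envelope factors are recovered as (g^2 - 1) * 100 and ordered", {
  recover <- function(g, seed) {
    cfg <- plateauConfig(g, 1.2, 1.8, nTrials = 60, seed = seed)
    ep <- rejectArtifacts(genBilateralEpochs(cfg))
    tfr <- computeTfr(ep, freqs = seq(14, 30, by = 0.25))
    tc <- betaTimecourse(baselineNormalize(tfr))
    featureTable(extractErspFeatures(tc))$pmbsValue[1]
  }
  v12 <- recover(1.2, seed = 41)
  expect_equal(v12, (1.2^2 - 1) * 100, tolerance = 3 / 44)
  v14 <- recover(1.4, seed = 41)
  expect_equal(v14, (1.4^2 - 1) * 100, tolerance = 3 / 96)
  expect_gt(v14, v12)                      # monotone in the factor
})
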
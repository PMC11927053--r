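test_that("LWR recursion solves the Yule-Walker system exactly", {
  # oracle: direct block-Toeplitz solve of the same equations
  pair <- genArCoupledPair(0.8, lag = 1, nSamples = 5000, seed = 1)
  X <- cbind(pair$x, pair$y)
  for (p in c(1, 3)) {
    m <- fitMvar(X, p = p)
    G <- betaConnect:::lagCovariances(X, p)
    d <- betaConnect:::ywDirect(G, p)
    expect_lt(max(abs(m@A - d$A)), 1e-10)
    expect_lt(max(abs(m@noiseCov - d$Sigma)), 1e-10)
  }
})

test_that("LWR estimates agree with the least-squares oracle", {
  pair <- genArCoupledPair(0.6, lag = 2, nSamples = 2000, seed = 2)
  X <- cbind(pair$x, pair$y)
  p <- 3
  m <- fitMvar(X, p = p)
  # brute-force oracle: multivariate regression on lagged values
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Y <- Xc[(p + 1):n, ]
  Z <- do.call(cbind, lapply(1:p, function(i) Xc[(p + 1 - i):(n - i), ]))
  B <- t(solve(crossprod(Z), crossprod(Z, Y)))
  Als <- array(0, dim = c(2, 2, p))
  for (i in 1:p) Als[, , i] <- B[, (2 * i - 1):(2 * i)]
  expect_lt(max(abs(m@A - Als)), 5e-2)
})

test_that("MVAR coefficients recover embedded univariate dynamics", {
  set.seed(3)
  n <- 10000
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  X <- cbind(x, rnorm(n))
  m <- fitMvar(X, p = 2)
  expect_equal(m@A[1, 1, 1], 0.5, tolerance = 0.04)
  expect_lt(max(abs(m@A[1, 2, ])), 0.05)
  expect_lt(max(abs(m@A[2, , ])), 0.05)
  W <- matrix(rnorm(2 * n), ncol = 2)
  mw <- fitMvar(W, p = 3)
  expect_lt(max(abs(mw@A)), 0.05)
})

test_that("ensemble (trial-averaged) fits match long-series fits", {
  pair <- genArCoupledPair(0.8, lag = 1, nSamples = 30000, seed = 4)
  X <- cbind(pair$x, pair$y)
  dat <- array(0, dim = c(60, 2, 500))
  for (tr in 1:60) dat[tr, , ] <- t(X[(tr - 1) * 500 + 1:500, ])
  ep <- EpochedSignals(dat, fs = 1000, t0 = 0)
  me <- fitMvar(ep, p = 3)
  ml <- fitMvar(X, p = 3)
  expect_lt(max(abs(me@A - ml@A)), 0.05)
  expect_true(betaConnect:::mvarStable(me@A))
})

test_that("information criteria identify the true order", {
  set.seed(5)
  n <- 10000
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n))
  y <- as.numeric(arima.sim(list(ar = c(0.4, 0.2)), n))
  sel <- selectOrder(cbind(x, y), pMax = 8)
  expect_identical(sel$bicOrder, 2L)
  expect_identical(sel$order, 10L)              # configured override
  selW <- selectOrder(matrix(rnorm(2 * n), ncol = 2), pMax = 8)
  expect_lte(selW$bicOrder, 1L)
  expect_error(selectOrder(matrix(rnorm(40), ncol = 2), pMax = 10),
               "sample budget")
})

test_that("transfer function matches closed forms", {
  # p = 0: no AR terms -> H(f) is the identity
  m0 <- mvarFromTruth(array(0, dim = c(2, 2, 0)), diag(2))
  H0 <- transferFunction(m0, c(0, 10, 20))
  for (i in 1:3) expect_equal(H0[, , i], diag(2) + 0i)
  # univariate a = 0.5: |H(f)|^2 = 1 / |1 - 0.5 exp(-i 2 pi f / fs)|^2
  m1 <- mvarFromTruth(array(0.5, dim = c(1, 1, 1)), matrix(1), fs = 1000,
                      labels = "x")
  fgrid <- c(0, 5, 20, 100)
  H1 <- transferFunction(m1, fgrid)
  expected <- 1 / Mod(1 - 0.5 * exp(-2i * pi * fgrid / 1000))^2
  expect_equal(as.numeric(Mod(H1[1, 1, ])^2), expected, tolerance = 1e-12)
  expect_equal(Mod(H1[1, 1, 1])^2, 4)           # gain 1/(1-a)^2 at f = 0
})

test_that("directed coherence identifies the coupling direction", {
  truth <- genArCoupledPair(0.8, lag = 1, nSamples = 100, seed = 6)
  m <- mvarFromTruth(truth$A, truth$noiseCov)
  dc <- directedCoherence(m, freqs = seq(1, 499, by = 2))
  # driven direction dominates at every frequency (closed-form H)
  expect_true(all(dc@dircoh[2, 1, ] > dc@dircoh[1, 2, ]))
  expect_gt(bandMean(dc)[2, 1], bandMean(dc)[1, 2])
  # normalization identity for diagonal innovation covariance
  sums <- apply(dc@dircoh, c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-10)
  # uncoupled channels -> off-diagonal directed coherence vanishes
  A <- array(0, dim = c(2, 2, 1)); A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3
  dc0 <- directedCoherence(mvarFromTruth(A, diag(2)))
  expect_lt(max(dc0@dircoh[1, 2, ], dc0@dircoh[2, 1, ]), 1e-12)
  # literal autospectrum-ratio reading is available behind a flag
  dcl <- directedCoherence(m, mode = "literal")
  expect_true(all(dcl@dircoh >= 0))
  expect_gt(bandMean(dcl)[2, 1], bandMean(dcl)[1, 2])
})

test_that("significance threshold follows Z = 1 - alpha^(1/(L-1))", {
  expect_identical(significanceThreshold(2, 0.05), 0.95)
  expect_equal(significanceThreshold(55, 0.05), 1 - 0.05^(1 / 54))
  expect_equal(round(significanceThreshold(55, 0.05), 5), 0.05397)
  Ls <- c(2, 5, 20, 100, 1000)
  Zs <- vapply(Ls, significanceThreshold, numeric(1))
  expect_true(all(diff(Zs) < 0))               # strictly decreasing
  expect_lt(significanceThreshold(1e6), 1e-4)  # -> 0 for large L
  expect_error(significanceThreshold(1), "at least 2")
})
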
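#' @include AllClasses.R utils.R
NULL

## Biased (1/n) lag-covariance matrices Gamma(0..p) of a demeaned
## n x k data matrix; Gamma(m) = (1/n) sum_t x_t x_{t-m}^T.
lagCovariances <- function(X, p) {
  n <- nrow(X)
  k <- ncol(X)
  if (n <= p) stop("series too short for ", p, " lags")
  X <- sweep(X, 2, colMeans(X))
  lapply(0:p, function(m) {
    crossprod(X[(m + 1):n, , drop = FALSE], X[1:(n - m), , drop = FALSE]) / n
  })
}

## Average lag covariances over trials (ensemble estimate).
ensembleLagCov <- function(trialList, p) {
  Gs <- lapply(trialList, lagCovariances, p = p)
  lapply(seq_len(p + 1), function(i)
    Reduce(`+`, lapply(Gs, `[[`, i)) / length(Gs))
}

## Levinson-Wiggins-Robinson (Whittle) recursion: solves the
## multivariate Yule-Walker equations Gamma(m) = sum_i A_i Gamma(m-i)
## for all orders 1..p in one pass.  G is the list Gamma(0..p).
## Returns coefficients and forward innovation covariance per order.
lwrRecursion <- function(G, p) {
  k <- nrow(G[[1]])
  Sf <- G[[1]]; Sb <- G[[1]]
  A <- list(); B <- list()
  perOrder <- vector("list", p)
  for (m in seq_len(p)) {
    acc <- G[[m + 1]]
    if (m > 1) for (i in 1:(m - 1)) acc <- acc - A[[i]] %*% G[[m - i + 1]]
    SbInv <- tryCatch(solve(Sb), error = function(e)
      stop("singular backward covariance at order ", m,
           "; try a lower model order", call. = FALSE))
    SfInv <- tryCatch(solve(Sf), error = function(e)
      stop("singular forward covariance at order ", m,
           "; try a lower model order", call. = FALSE))
    Am <- acc %*% SbInv
    Bm <- t(acc) %*% SfInv
    Anew <- vector("list", m); Bnew <- vector("list", m)
    if (m > 1) for (i in 1:(m - 1)) {
      Anew[[i]] <- A[[i]] - Am %*% B[[m - i]]
      Bnew[[i]] <- B[[i]] - Bm %*% A[[m - i]]
    }
    Anew[[m]] <- Am; Bnew[[m]] <- Bm
    A <- Anew; B <- Bnew
    Sf <- Sf - Am %*% t(acc)
    Sb <- Sb - Bm %*% acc
    Sf <- (Sf + t(Sf)) / 2
    Sb <- (Sb + t(Sb)) / 2
    perOrder[[m]] <- list(A = A, Sigma = Sf)
  }
  perOrder
}

## Direct block-Toeplitz Yule-Walker solve (used as an internal
## cross-check; O(p^3 k^3) but exact).
ywDirect <- function(G, p) {
  k <- nrow(G[[1]])
  gam <- function(m) if (m >= 0) G[[m + 1]] else t(G[[-m + 1]])
  M <- matrix(0, k * p, k * p)
  R <- matrix(0, k, k * p)
  for (i in seq_len(p)) {
    R[, ((i - 1) * k + 1):(i * k)] <- gam(i)
    for (j in seq_len(p))
      M[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)] <- gam(j - i)
  }
  Astack <- R %*% solve(M)
  A <- array(0, dim = c(k, k, p))
  for (i in seq_len(p)) A[, , i] <- Astack[, ((i - 1) * k + 1):(i * k)]
  Sigma <- G[[1]]
  for (i in seq_len(p)) Sigma <- Sigma - A[, , i] %*% t(G[[i + 1]])
  list(A = A, Sigma = (Sigma + t(Sigma)) / 2)
}

## Companion-matrix stability check for a k x k x p coefficient array.
mvarStable <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (i in seq_len(p)) C[1:k, ((i - 1) * k + 1):(i * k)] <- A[, , i]
  if (p > 1) C[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values)) < 1
}

#' Fit a multivariate autoregressive (MVAR) model
#'
#' Estimates the coefficients of X(t) = sum_i A(i) X(t-i) + E(t) from
#' lag-covariance matrices via the Levinson-Wiggins-Robinson recursion
#' for the multivariate Yule-Walker equations.  For epoched input the
#' lag covariances are computed per kept trial (each trial demeaned)
#' and averaged across trials before the recursion (ensemble
#' estimate).  An unstable fit (companion-matrix spectral radius >= 1)
#' raises a warning.
#'
#' @param x an n x k numeric matrix (single realisation) or an
#'   \linkS4class{EpochedSignals} object.
#' @param p model order (default 10).
#' @param window for epoched input, analysis interval in seconds.
#' @param ... passed through between methods.
#' @return an \linkS4class{MvarModel}.
#' @export
setGeneric("fitMvar", function(x, p = 10, ...) standardGeneric("fitMvar"))

#' @rdname fitMvar
#' @param fs sampling rate for matrix input (default 1, i.e. frequency
#'   in cycles/sample).
#' @param channelNames channel labels for matrix input.
setMethod("fitMvar", "matrix", function(x, p = 10, fs = 1,
                                        channelNames = NULL, ...) {
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(ncol(x)))
  G <- lagCovariances(x, p)
  fit <- lwrRecursion(G, p)[[p]]
  buildMvarModel(fit, p, fs, channelNames, nObs = nrow(x))
})

#' @rdname fitMvar
setMethod("fitMvar", "EpochedSignals", function(x, p = 10, window = NULL, ...) {
  dat <- epochData(x, keptOnly = TRUE)
  if (dim(dat)[1] < 1) stop("no kept trials")
  times <- epochTimes(x)
  if (is.null(window)) window <- range(times)
  sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(sel) <= p)
    stop("analysis window holds too few samples for order ", p)
  if (length(sel) < 10 * p)
    warning("fewer than 10 samples per coefficient in the analysis window")
  trials <- lapply(seq_len(dim(dat)[1]), function(tr)
    t(dat[tr, , sel, drop = TRUE]))
  G <- ensembleLagCov(trials, p)
  fit <- lwrRecursion(G, p)[[p]]
  buildMvarModel(fit, p, samplingRate(x), channelLabels(x),
                 nObs = dim(dat)[1] * length(sel))
})

buildMvarModel <- function(fit, p, fs, channelNames, nObs) {
  k <- nrow(fit$Sigma)
  A <- array(0, dim = c(k, k, p))
  for (i in seq_len(p)) A[, , i] <- fit$A[[i]]
  if (!mvarStable(A))
    warning("fitted MVAR model is unstable (companion spectral radius >= 1)")
  new("MvarModel", A = A, noiseCov = fit$Sigma, order = as.integer(p),
      fs = fs, channelLabels = channelNames, nObs = nObs)
}

#' Select an MVAR model order by AIC / BIC
#'
#' Fits all orders 0..\code{pMax} in a single Levinson-Wiggins-Robinson
#' pass and scores each by the Akaike and Bayesian information criteria
#' computed from the log-determinant of the innovation covariance.  The
#' returned \code{order} is the configured final order (the reference
#' analysis fixes p = 10 regardless of the criteria).
#'
#' @param x matrix (n x k) or \linkS4class{EpochedSignals}.
#' @param pMax largest order scored.
#' @param configured the final order to report (default 10).
#' @param window analysis interval for epoched input.
#' @return list with \code{aic}, \code{bic} (vectors indexed by order
#'   0..pMax), \code{aicOrder}, \code{bicOrder} and \code{order}.
#' @export
selectOrder <- function(x, pMax = 20, configured = 10L, window = NULL) {
  if (is(x, "EpochedSignals")) {
    dat <- epochData(x, keptOnly = TRUE)
    times <- epochTimes(x)
    if (is.null(window)) window <- range(times)
    sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
    trials <- lapply(seq_len(dim(dat)[1]), function(tr)
      t(dat[tr, , sel, drop = TRUE]))
    nObs <- dim(dat)[1] * length(sel)
    G <- ensembleLagCov(trials, pMax)
    k <- dim(dat)[2]
  } else {
    x <- as.matrix(x)
    if (nrow(x) <= pMax * 10)
      stop("'pMax' exceeds the sample budget (need > 10 pMax samples)")
    G <- lagCovariances(x, pMax)
    nObs <- nrow(x)
    k <- ncol(x)
  }
  fits <- lwrRecursion(G, pMax)
  ld <- function(S) determinant(S, logarithm = TRUE)$modulus
  logdets <- c(ld(G[[1]]), vapply(fits, function(f) ld(f$Sigma), numeric(1)))
  orders <- 0:pMax
  aic <- logdets + 2 * orders * k^2 / nObs
  bic <- logdets + log(nObs) * orders * k^2 / nObs
  list(aic = aic, bic = bic,
       aicOrder = orders[which.min(aic)], bicOrder = orders[which.min(bic)],
       order = as.integer(configured))
}

#' MVAR transfer function
#'
#' H(f) = A(f)^{-1} with A(f) = I - sum_i A(i) exp(-i 2 pi f i / fs),
#' the spectral transfer function mapping innovations to signals.
#'
#' @param model an \linkS4class{MvarModel}.
#' @param freqs frequencies (Hz) at which to evaluate H.
#' @return complex k x k x length(freqs) array.
#' @export
transferFunction <- function(model, freqs) {
  stopifnot(is(model, "MvarModel"))
  k <- dim(model@A)[1]
  p <- model@order
  H <- array(0i, dim = c(k, k, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(k) + 0i
    for (i in seq_len(p))
      Af <- Af - model@A[, , i] * exp(-2i * pi * freqs[fi] * i / model@fs)
    H[, , fi] <- tryCatch(solve(Af), error = function(e)
      stop(sprintf("A(f) numerically singular at f = %g Hz", freqs[fi]),
           call. = FALSE))
  }
  H
}

#' Directed coherence from an MVAR model
#'
#' Frequency-resolved causal influence of channel j on channel i
#' derived from the transfer function H(f).  Under the default
#' \code{"normalized"} interpretation,
#' \deqn{DirCoh_{i \leftarrow j}(f) =
#'   |H_{ij}(f)|^2 \sigma_j^2 / \sum_k |H_{ik}(f)|^2 \sigma_k^2,}
#' with \eqn{\sigma_j^2} the innovation variance of channel j and the
#' denominator the model autospectrum of channel i, so that values lie
#' in [0, 1] and rows sum to one when the innovation covariance is
#' diagonal.  The \code{"literal"} mode instead forms
#' |H_ij|^2 S_jj / S_ii from the model autospectra of both channels
#' (not bounded by 1).  When the pooled section count \code{L} is
#' given, the significance threshold Z = 1 - alpha^(1/(L-1)) is
#' attached.
#'
#' @param model an \linkS4class{MvarModel}.
#' @param freqs frequencies (Hz); default 5-40 Hz in 0.25 Hz steps.
#' @param band band for the per-direction means (Hz).
#' @param mode "normalized" (default) or "literal".
#' @param L pooled section count for the significance threshold, or
#'   NULL.
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{DirCohResult}.
#' @export
directedCoherence <- function(model, freqs = seq(5, 40, by = 0.25),
                              band = c(14, 30),
                              mode = c("normalized", "literal"),
                              L = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  H <- transferFunction(model, freqs)
  k <- dim(H)[1]
  sig2 <- diag(model@noiseCov)
  dc <- array(NA_real_, dim = dim(H))
  for (fi in seq_along(freqs)) {
    Hf <- H[, , fi]
    M2 <- Mod(Hf)^2
    if (mode == "normalized") {
      num <- sweep(M2, 2, sig2, `*`)
      den <- rowSums(num)
      if (any(den == 0)) next
      dc[, , fi] <- num / den
    } else {
      S <- Hf %*% model@noiseCov %*% Conj(t(Hf))
      Sd <- Re(diag(S))
      if (any(Sd == 0)) next
      dc[, , fi] <- M2 * rep(Sd, each = k) / Sd
    }
  }
  bins <- freqs >= band[1] & freqs <= band[2]
  bm <- apply(dc[, , bins, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  dimnames(bm) <- list(model@channelLabels, model@channelLabels)
  Z <- NA_real_
  Lout <- NA_integer_
  if (!is.null(L)) {
    Z <- significanceThreshold(L, alpha)
    Lout <- as.integer(L)
  }
  new("DirCohResult", dircoh = dc, freqs = freqs, bandMeans = bm,
      band = band, Z = Z, alpha = alpha, L = Lout, mode = mode,
      channelLabels = model@channelLabels)
}

#' Analytic significance threshold for directed coherence
#'
#' Z = 1 - alpha^(1/(L-1)), where L is the total number of
#' non-overlapping sections behind the spectral estimate; a directed
#' coherence value above Z is significant at level alpha.  Z decreases
#' strictly with L and equals 1 - alpha at L = 2.
#'
#' @param L pooled section count (>= 2).
#' @param alpha significance level (default 0.05).
#' @return the threshold Z in (0, 1).
#' @export
significanceThreshold <- function(L, alpha = 0.05) {
  stopifnotScalar(L, "L")
  if (L < 2) stop("'L' must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  1 - alpha^(1 / (L - 1))
}
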
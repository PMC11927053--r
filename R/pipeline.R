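#' @include AllClasses.R utils.R synthgen.R preprocess.R ersp.R connectivity.R mvar.R ihi.R
NULL

#' Assemble an end-to-end run configuration
#'
#' Bundles the per-module parameters consumed by [runCondition()].
#' Input is either a synthetic-EEG configuration (per condition) or a
#' directory holding epochs written by [writeEpochs()].
#'
#' @param conditions character vector of condition names.
#' @param synthConfigs named list of [synthEegConfig()] objects, one
#'   per condition (NULL when reading from disk).
#' @param inputDir directory with stored epochs (NULL for synthetic
#'   input).
#' @param mepConfigs optional named list of [synthMepConfig()] objects
#'   per condition; conditions without an entry yield no IHI result.
#' @param artifactK SD multiplier for artifact screening.
#' @param freqs,cycles,timeStep TFR parameters (see [computeTfr()]).
#' @param baselineWindow baseline interval (s).
#' @param band beta band (Hz).
#' @param sectionLength,padTo coherence sectioning parameters (s).
#' @param mvarOrder MVAR model order.
#' @param outputDir directory for [exportReport()] output, or NULL.
#' @param seed integer seed recorded in every report.
#' @return a list of class "RunConfig".
#' @export
runConfig <- function(conditions, synthConfigs = NULL, inputDir = NULL,
                      mepConfigs = NULL, artifactK = 5,
                      freqs = seq(5, 40, by = 0.25), cycles = 3,
                      timeStep = 0.02, baselineWindow = c(-0.25, 0),
                      band = c(14, 30), sectionLength = 0.05, padTo = 1,
                      mvarOrder = 10, outputDir = NULL, seed = NULL) {
  if (is.null(synthConfigs) && is.null(inputDir))
    stop("provide either 'synthConfigs' or 'inputDir'")
  if (!is.null(inputDir) && !dir.exists(inputDir))
    stop("input directory does not exist: ", inputDir)
  structure(list(conditions = conditions, synthConfigs = synthConfigs,
                 inputDir = inputDir, mepConfigs = mepConfigs,
                 artifactK = artifactK, freqs = freqs, cycles = cycles,
                 timeStep = timeStep, baselineWindow = baselineWindow,
                 band = band, sectionLength = sectionLength, padTo = padTo,
                 mvarOrder = mvarOrder, outputDir = outputDir, seed = seed),
            class = "RunConfig")
}

#' Run the full analysis for one condition
#'
#' Sequences the pipeline: obtain epochs (synthetic or from disk),
#' artifact screening, time-frequency power, baseline normalisation,
#' beta time course and MRBD/PMBS features; then sectioned coherence
#' and MVAR directed coherence within the detected MRBD and PMBS
#' windows (and the pre-stimulus baseline); and, when MEP data are
#' configured, the IHI ratio.
#'
#' @param cfg a [runConfig()] object.
#' @param condition the condition name to run.
#' @return a \linkS4class{ConditionReport}.
#' @export
runCondition <- function(cfg, condition) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!condition %in% cfg$conditions)
    stop("unknown condition: ", condition)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for condition '%s': %s",
                   name, condition, conditionMessage(e)), call. = FALSE))
  }
  epochs <- stage("input", {
    if (!is.null(cfg$synthConfigs)) {
      sc <- cfg$synthConfigs[[condition]]
      if (is.null(sc)) stop("no synthetic config for this condition")
      genBilateralEpochs(sc)
    } else {
      readEpochs(cfg$inputDir, condition)
    }
  })
  epochs <- stage("preprocess", rejectArtifacts(epochs, k = cfg$artifactK))
  tfr <- stage("ersp", computeTfr(epochs, freqs = cfg$freqs,
                                  cycles = cfg$cycles,
                                  timeStep = cfg$timeStep))
  rp <- stage("ersp", baselineNormalize(tfr, cfg$baselineWindow))
  tc <- stage("ersp", betaTimecourse(rp, cfg$band))
  feats <- stage("ersp", extractErspFeatures(tc))
  ft <- featureTable(feats)
  windows <- list(baseline = cfg$baselineWindow)
  if (!is.na(ft$mrbdOnset[1]) && !is.na(ft$mrbdEnd[1]))
    windows$mrbd <- c(ft$mrbdOnset[1], ft$mrbdEnd[1])
  if (!is.na(ft$pmbsLatency[1]) && !is.na(ft$pmbsEnd[1]))
    windows$pmbs <- c(ft$pmbsLatency[1], ft$pmbsEnd[1])
  cohRes <- list(); dcRes <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (diff(w) < cfg$sectionLength) next
    est <- stage("connectivity",
                 smoothSpectrum(sectionSpectra(epochs, window = w,
                                               sectionLength = cfg$sectionLength,
                                               padTo = cfg$padTo,
                                               periodLabel = nm)))
    cohRes[[nm]] <- stage("connectivity", coherence(est, band = cfg$band))
    nwin <- diff(w) * samplingRate(epochs)
    if (nwin > cfg$mvarOrder * 10) {
      model <- stage("connectivity",
                     fitMvar(epochs, p = cfg$mvarOrder, window = w))
      dcRes[[nm]] <- stage("connectivity",
                           directedCoherence(model, band = cfg$band,
                                             L = est@L))
    }
  }
  ihiRes <- NULL
  if (!is.null(cfg$mepConfigs) && !is.null(cfg$mepConfigs[[condition]])) {
    ihiRes <- stage("ihi", {
      meps <- genMepTrials(cfg$mepConfigs[[condition]])
      computeIhi(mepPeakToPeak(meps))
    })
  }
  report <- new("ConditionReport", condition = condition, ersp = feats,
                coherence = cohRes, dircoh = dcRes, ihi = ihiRes,
                provenance = list(
                  seed = if (is.null(cfg$seed)) NA else cfg$seed,
                  package = "betaConnect",
                  version = as.character(utils::packageVersion("betaConnect")),
                  nTrialsKept = sum(keptMask(epochs))))
  if (!is.null(cfg$outputDir)) exportReport(report, cfg$outputDir)
  report
}

#' Pearson correlation with a bootstrap confidence interval
#'
#' Pearson's r between paired samples with a percentile bootstrap
#' confidence interval from paired resampling with replacement.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @return list with \code{r}, \code{ci} (length 2), \code{nBoot},
#'   \code{conf} and \code{n}.
#' @export
pearsonBootstrap <- function(x, y, nBoot = 1000, conf = 0.95, seed = NULL) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  r <- stats::cor(x, y)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(r = r, ci = ci, nBoot = nBoot, conf = conf, n = n)
}

## Flatten a ConditionReport into a named list of scalar metrics.
reportMetrics <- function(report) {
  out <- list()
  ft <- featureTable(report@ersp)
  for (r in seq_len(nrow(ft))) {
    ch <- ft$channel[r]
    for (col in setdiff(names(ft), "channel"))
      out[[paste(ch, col, sep = ".")]] <- ft[[col]][r]
  }
  for (nm in names(report@coherence)) {
    out[[paste0("coherence.", nm, ".bandMean")]] <- bandMean(report@coherence[[nm]])
    out[[paste0("coherence.", nm, ".L")]] <- report@coherence[[nm]]@L
  }
  for (nm in names(report@dircoh)) {
    d <- report@dircoh[[nm]]
    labs <- d@channelLabels
    for (i in seq_along(labs)) for (j in seq_along(labs)) if (i != j)
      out[[sprintf("dircoh.%s.%s_from_%s", nm, labs[i], labs[j])]] <-
        d@bandMeans[i, j]
    out[[paste0("dircoh.", nm, ".Z")]] <- d@Z
  }
  if (!is.null(report@ihi)) {
    out$ihi <- report@ihi@ihi
    out$ihiPercent <- report@ihi@ihiPercent
    out$meanTsAmplitude <- report@ihi@meanTs
    out$meanCsAmplitude <- report@ihi@meanCs
  }
  out
}

#' Export a condition report
#'
#' Writes the report as JSON (full nested structure) and/or CSV (flat
#' metric table with one row per scalar metric).
#'
#' @param report a \linkS4class{ConditionReport}.
#' @param dir output directory (created if missing).
#' @param formats subset of c("json", "csv").
#' @return invisibly, the paths written.
#' @export
exportReport <- function(report, dir, formats = c("json", "csv")) {
  stopifnot(is(report, "ConditionReport"))
  bad <- setdiff(formats, c("json", "csv"))
  if (length(bad))
    stop("unknown format(s) ", paste(bad, collapse = ", "),
         "; supported formats: json, csv")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  metrics <- reportMetrics(report)
  if ("json" %in% formats) {
    p <- file.path(dir, paste0(report@condition, "_report.json"))
    jsonlite::write_json(list(schema = "betaConnect-report-1",
                              condition = report@condition,
                              provenance = report@provenance,
                              metrics = metrics),
                         p, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, json = p)
  }
  if ("csv" %in% formats) {
    p <- file.path(dir, paste0(report@condition, "_metrics.csv"))
    utils::write.csv(data.frame(metric = names(metrics),
                                value = unlist(metrics),
                                row.names = NULL), p, row.names = FALSE)
    paths <- c(paths, csv = p)
  }
  invisible(paths)
}
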
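#' @include AllClasses.R
NULL

#' Accessors for EpochedSignals
#'
#' \code{epochData} returns the trials x channels x time array (all
#' trials, or kept trials only), \code{samplingRate} the sampling rate,
#' \code{epochTimes} the time axis in seconds relative to the stimulus,
#' \code{channelLabels} the channel names, \code{conditionLabel} the
#' condition tag, \code{nTrials} the trial count, and \code{keptMask}
#' the per-trial screening mask.
#'
#' @param x an \linkS4class{EpochedSignals} object.
#' @param keptOnly return only trials that survived artifact screening.
#' @return see the individual descriptions.
#' @name epochs-accessors
NULL

#' @rdname epochs-accessors
#' @export
setGeneric("epochData", function(x, keptOnly = FALSE) standardGeneric("epochData"))
#' @rdname epochs-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname epochs-accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname epochs-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname epochs-accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname epochs-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname epochs-accessors
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))
#' @rdname epochs-accessors
#' @param value replacement logical mask.
#' @export
setGeneric("keptMask<-", function(x, value) standardGeneric("keptMask<-"))

#' @rdname epochs-accessors
setMethod("epochData", "EpochedSignals", function(x, keptOnly = FALSE) {
  if (!keptOnly) return(x@data)
  x@data[x@keptMask, , , drop = FALSE]
})
#' @rdname epochs-accessors
setMethod("samplingRate", "EpochedSignals", function(x) x@fs)
#' @rdname epochs-accessors
setMethod("epochTimes", "EpochedSignals", function(x) {
  x@t0 + (seq_len(dim(x@data)[3]) - 1) / x@fs
})
#' @rdname epochs-accessors
setMethod("channelLabels", "EpochedSignals", function(x) x@channelLabels)
#' @rdname epochs-accessors
setMethod("conditionLabel", "EpochedSignals", function(x) x@condition)
#' @rdname epochs-accessors
setMethod("nTrials", "EpochedSignals", function(x) dim(x@data)[1])
#' @rdname epochs-accessors
setMethod("keptMask", "EpochedSignals", function(x) x@keptMask)
#' @rdname epochs-accessors
setMethod("keptMask<-", "EpochedSignals", function(x, value) {
  x@keptMask <- value
  validObject(x)
  x
})

setMethod("show", "EpochedSignals", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochedSignals: %d trial(s) x %d channel(s) x %d sample(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  fs %g Hz, t = [%.3f, %.3f] s, condition \"%s\"\n",
              object@fs, object@t0,
              object@t0 + (d[3] - 1) / object@fs, object@condition))
  cat(sprintf("  channels: %s; kept %d/%d trial(s)\n",
              paste(object@channelLabels, collapse = ", "),
              sum(object@keptMask), d[1]))
})

#' Accessors for time-frequency and result objects
#'
#' \code{tfrPower} and \code{relativePower} return the underlying
#' channel x frequency x time arrays; \code{tfrFreqs} / \code{tfrTimes}
#' their axes.  \code{featureTable} returns the per-channel MRBD/PMBS
#' feature data.frame.  \code{bandMean} returns the band-mean coherence
#' or the matrix of band-mean directed coherences.
#' \code{dircohThreshold} returns the significance threshold Z.
#'
#' @param x an object of the documented classes.
#' @return see description.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("tfrPower", function(x) standardGeneric("tfrPower"))
#' @rdname result-accessors
#' @export
setGeneric("tfrFreqs", function(x) standardGeneric("tfrFreqs"))
#' @rdname result-accessors
#' @export
setGeneric("tfrTimes", function(x) standardGeneric("tfrTimes"))
#' @rdname result-accessors
#' @export
setGeneric("relativePower", function(x) standardGeneric("relativePower"))
#' @rdname result-accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname result-accessors
#' @export
setGeneric("bandMean", function(x) standardGeneric("bandMean"))
#' @rdname result-accessors
#' @export
setGeneric("dircohThreshold", function(x) standardGeneric("dircohThreshold"))
#' @rdname result-accessors
#' @export
setGeneric("mepAmplitudes", function(x) standardGeneric("mepAmplitudes"))

#' @rdname result-accessors
setMethod("tfrPower", "PowerTfr", function(x) x@power)
#' @rdname result-accessors
setMethod("tfrFreqs", "PowerTfr", function(x) x@freqs)
#' @rdname result-accessors
setMethod("tfrTimes", "PowerTfr", function(x) x@times)
#' @rdname result-accessors
setMethod("tfrFreqs", "RelativePowerMap", function(x) x@freqs)
#' @rdname result-accessors
setMethod("tfrTimes", "RelativePowerMap", function(x) x@times)
#' @rdname result-accessors
setMethod("relativePower", "RelativePowerMap", function(x) x@rp)
#' @rdname result-accessors
setMethod("featureTable", "ErspFeatures", function(x) x@features)
#' @rdname result-accessors
setMethod("bandMean", "CoherenceResult", function(x) x@bandMean)
#' @rdname result-accessors
setMethod("bandMean", "DirCohResult", function(x) x@bandMeans)
#' @rdname result-accessors
setMethod("dircohThreshold", "DirCohResult", function(x) x@Z)
#' @rdname result-accessors
setMethod("mepAmplitudes", "MepTrialSet", function(x) x@amplitudes)

setMethod("show", "PowerTfr", function(object) {
  cat(sprintf("PowerTfr: %d channel(s), %d frequencies [%g-%g Hz], %d times, %d trial(s)\n",
              dim(object@power)[1], length(object@freqs),
              min(object@freqs), max(object@freqs),
              length(object@times), object@nTrials))
})

setMethod("show", "RelativePowerMap", function(object) {
  cat(sprintf("RelativePowerMap: %d channel(s), %d frequencies, %d times; baseline [%g, %g] s\n",
              dim(object@rp)[1], length(object@freqs), length(object@times),
              object@baselineWindow[1], object@baselineWindow[2]))
})

setMethod("show", "ErspFeatures", function(object) {
  cat(sprintf("ErspFeatures (band %g-%g Hz, threshold %g%%, sustain %d steps):\n",
              object@band[1], object@band[2], object@threshold,
              object@sustain))
  print(object@features, digits = 4)
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf("SpectralEstimate: L = %d pooled sections of %g ms (%s), %d frequency bins%s\n",
              object@L, 1000 * object@sectionLength,
              paste(object@channelLabels, collapse = " x "),
              length(object@freqs),
              if (object@smoothed) ", smoothed" else ""))
})

setMethod("show", "CoherenceResult", function(object) {
  cat(sprintf("CoherenceResult [%s]: band %g-%g Hz mean = %.4f (L = %d)\n",
              object@periodLabel, object@band[1], object@band[2],
              object@bandMean, object@L))
})

setMethod("show", "MvarModel", function(object) {
  cat(sprintf("MvarModel: k = %d channels, order p = %d, fs = %g Hz, nObs = %g\n",
              dim(object@A)[1], object@order, object@fs, object@nObs))
})

setMethod("show", "DirCohResult", function(object) {
  k <- length(object@channelLabels)
  cat(sprintf("DirCohResult (%s): band %g-%g Hz means\n", object@mode,
              object@band[1], object@band[2]))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    cat(sprintf("  %s <- %s : %.4f\n", object@channelLabels[i],
                object@channelLabels[j], object@bandMeans[i, j]))
  if (!is.na(object@Z))
    cat(sprintf("  significance threshold Z = %.5f (alpha = %g, L = %d)\n",
                object@Z, object@alpha, object@L))
})

setMethod("show", "MepTrialSet", function(object) {
  cat(sprintf("MepTrialSet: %d trial(s) (%d TS, %d CS) at %g kHz, condition \"%s\"\n",
              nrow(object@waveforms), sum(object@mode == "ts"),
              sum(object@mode == "cs"), object@fs / 1000, object@condition))
})

setMethod("show", "IhiResult", function(object) {
  cat(sprintf("IhiResult [%s]: IHI = %.3f (CS %.3f mV / TS %.3f mV; n = %d + %d)\n",
              object@condition, object@ihi, object@meanCs, object@meanTs,
              object@nCs, object@nTs))
})

setMethod("show", "ConditionReport", function(object) {
  cat(sprintf("ConditionReport \"%s\"\n", object@condition))
  cat("-- ERSP features --\n"); show(object@ersp)
  for (nm in names(object@coherence)) {
    cat(sprintf("-- coherence [%s] --\n", nm)); show(object@coherence[[nm]])
  }
  for (nm in names(object@dircoh)) {
    cat(sprintf("-- directed coherence [%s] --\n", nm)); show(object@dircoh[[nm]])
  }
  if (!is.null(object@ihi)) { cat("-- IHI --\n"); show(object@ihi) }
})
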
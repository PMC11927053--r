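#' @include AllClasses.R
NULL

#' Write epochs to the on-disk text layout
#'
#' One tab-separated data file per condition (rows = trial x channel,
#' columns = samples, with leading \code{trial} and \code{channel}
#' columns) plus a JSON sidecar holding the sampling rate, epoch start,
#' channel labels, condition and kept mask.
#'
#' @param epochs an \linkS4class{EpochedSignals} object.
#' @param dir output directory (created if missing).
#' @param name file stem; defaults to the condition label.
#' @return invisibly, the paths written.
#' @export
writeEpochs <- function(epochs, dir, name = NULL) {
  stopifnot(is(epochs, "EpochedSignals"))
  if (is.null(name)) name <- conditionLabel(epochs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- epochs@data
  ntr <- dim(d)[1]; nch <- dim(d)[2]; ns <- dim(d)[3]
  flat <- matrix(aperm(d, c(3, 2, 1)), nrow = ntr * nch, byrow = TRUE)
  dt <- data.table::data.table(
    trial = rep(seq_len(ntr), each = nch),
    channel = rep(channelLabels(epochs), ntr))
  dt <- cbind(dt, data.table::as.data.table(flat))
  dataPath <- file.path(dir, paste0(name, "_data.tsv"))
  metaPath <- file.path(dir, paste0(name, "_meta.json"))
  data.table::fwrite(dt, dataPath, sep = "\t")
  meta <- list(schema = "betaConnect-epochs-1", fs = epochs@fs,
               t0 = epochs@t0, nTrials = ntr, nSamples = ns,
               channelLabels = channelLabels(epochs),
               condition = conditionLabel(epochs),
               keptMask = epochs@keptMask)
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(data = dataPath, meta = metaPath))
}

#' Read epochs from the on-disk text layout
#'
#' @param dir directory holding the files written by [writeEpochs()].
#' @param name file stem (the condition label used when writing).
#' @return an \linkS4class{EpochedSignals} object.
#' @export
readEpochs <- function(dir, name) {
  dataPath <- file.path(dir, paste0(name, "_data.tsv"))
  metaPath <- file.path(dir, paste0(name, "_meta.json"))
  if (!file.exists(dataPath) || !file.exists(metaPath))
    stop("no epoch files with stem \"", name, "\" in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  dt <- data.table::fread(dataPath, sep = "\t")
  ntr <- meta$nTrials; ns <- meta$nSamples
  chans <- meta$channelLabels
  nch <- length(chans)
  d <- array(0, dim = c(ntr, nch, ns))
  vals <- as.matrix(dt[, -(1:2)])
  for (r in seq_len(nrow(dt))) {
    tr <- dt$trial[r]
    ch <- match(dt$channel[r], chans)
    d[tr, ch, ] <- vals[r, ]
  }
  EpochedSignals(d, fs = as.numeric(meta$fs), t0 = as.numeric(meta$t0),
                 channelLabels = chans,
                 condition = meta$condition,
                 keptMask = as.logical(meta$keptMask))
}
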
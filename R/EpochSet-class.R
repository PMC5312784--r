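#' EpochSet: epoched EEG voltages with trial metadata
#'
#' S4 container for segmented EEG: a channels x samples x trials voltage
#' array in microvolts, the sampling rate, the time axis in milliseconds
#' relative to the locking event (`timeZero`, e.g. feedback or response
#' onset), channel names resolving against the montage, per-trial condition
#' labels, and a processing log (e.g. artifact-rejection counts).
#'
#' @slot voltages 3-D numeric array, channels x samples x trials, microvolts.
#' @slot samplingRate Sampling rate in Hz.
#' @slot times Time axis in ms, one value per sample.
#' @slot timeZero Event the epochs are locked to.
#' @slot channelNames Channel labels (dimension 1).
#' @slot trialInfo Data frame of per-trial labels (dimension 3 rows).
#' @slot processing List of processing annotations.
#'
#' @name EpochSet-class
#' @aliases EpochSet-class
#' @exportClass EpochSet
setClass("EpochSet",
  representation(voltages = "array", samplingRate = "numeric",
                 times = "numeric", timeZero = "character",
                 channelNames = "character", trialInfo = "data.frame",
                 processing = "list"))

setValidity("EpochSet", function(object) {
  d <- dim(object@voltages)
  msg <- character(0)
  if (length(d) != 3)
    msg <- c(msg, "voltages must be a channels x samples x trials array")
  else {
    if (length(object@channelNames) != d[1])
      msg <- c(msg, "channelNames length must match dim 1 of voltages")
    if (length(object@times) != d[2])
      msg <- c(msg, "times length must match dim 2 of voltages")
    if (nrow(object@trialInfo) != d[3])
      msg <- c(msg, "trialInfo rows must match dim 3 of voltages")
  }
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(msg) == 0) TRUE else msg
})

#' Construct an EpochSet
#'
#' @param voltages Channels x samples x trials array (microvolts).
#' @param samplingRate Sampling rate in Hz.
#' @param times Time axis in ms; defaults to a regular grid starting at
#'   `tmin`.
#' @param channelNames Channel labels; defaults to the array's dimnames or
#'   `ch01`...
#' @param trialInfo Per-trial data frame (may be empty).
#' @param timeZero Locking event label, e.g. `"feedback"` or `"response"`.
#' @param tmin Epoch start in ms when `times` is not given.
#' @return An `EpochSet` object.
#' @export
EpochSet <- function(voltages, samplingRate, times = NULL,
                     channelNames = NULL, trialInfo = NULL,
                     timeZero = "feedback", tmin = 0) {
  d <- dim(voltages)
  if (is.null(channelNames))
    channelNames <- dimnames(voltages)[[1]] %||% sprintf("ch%02d", seq_len(d[1]))
  if (is.null(times))
    times <- tmin + (seq_len(d[2]) - 1) * 1000 / samplingRate
  if (is.null(trialInfo))
    trialInfo <- data.frame(row.names = seq_len(d[3]))
  if (length(channelNames) == d[1])
    dimnames(voltages) <- list(channelNames, NULL, NULL)
  methods::new("EpochSet", voltages = voltages, samplingRate = samplingRate,
               times = times, timeZero = timeZero,
               channelNames = channelNames, trialInfo = trialInfo,
               processing = list())
}

#' @describeIn EpochSet-class Voltage array (channels x samples x trials).
#' @param object,x An `EpochSet`.
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))
#' @rdname EpochSet-class
#' @export
setMethod("voltages", "EpochSet", function(object) object@voltages)

#' @describeIn EpochSet-class Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)

#' @describeIn EpochSet-class Time axis in ms relative to `timeZero`.
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname EpochSet-class
#' @export
setMethod("epochTimes", "EpochSet", function(object) object@times)

#' @describeIn EpochSet-class Channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @describeIn EpochSet-class Per-trial label data frame.
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname EpochSet-class
#' @export
setMethod("trialInfo", "EpochSet", function(object) object@trialInfo)

#' @describeIn EpochSet-class Number of trials.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname EpochSet-class
#' @export
setMethod("nTrials", "EpochSet", function(object) dim(object@voltages)[3])

#' @describeIn EpochSet-class Subset trials, keeping labels aligned.
#' @param i Trial indices (integer or logical).
#' @export
setGeneric("subsetTrials", function(object, i) standardGeneric("subsetTrials"))
#' @rdname EpochSet-class
#' @export
setMethod("subsetTrials", "EpochSet", function(object, i) {
  if (is.logical(i)) i <- which(i)
  out <- object
  out@voltages <- object@voltages[, , i, drop = FALSE]
  out@trialInfo <- object@trialInfo[i, , drop = FALSE]
  rownames(out@trialInfo) <- NULL
  methods::validObject(out)
  out
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@voltages)
  cat(sprintf("EpochSet: %d channels x %d samples x %d trials\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %.0f Hz, %.0f..%.0f ms relative to %s onset\n",
              object@samplingRate, min(object@times), max(object@times),
              object@timeZero))
  if (ncol(object@trialInfo) > 0)
    cat("  trial labels:", paste(names(object@trialInfo), collapse = ", "),
        "\n")
  if (length(object@processing) > 0)
    cat("  processing:", paste(names(object@processing), collapse = ", "),
        "\n")
})

#' Write / read the canonical epochs container
#'
#' The canonical on-disk form is a flat binary array of doubles
#' (`<path>.dat`, channel index fastest, trial index slowest) plus a
#' structured-text sidecar (`<path>.yml`) holding dimensions, channel names,
#' sampling rate, time axis and locking event, and a tab-delimited per-trial
#' label table (`<path>.trials.tsv`).
#'
#' @param object An `EpochSet`.
#' @param path Path prefix (no extension).
#' @return `writeEpochs()` returns `path` invisibly; `readEpochs()` the
#'   reconstructed `EpochSet`.
#' @export
writeEpochs <- function(object, path) {
  stopifnot(methods::is(object, "EpochSet"))
  d <- dim(object@voltages)
  meta <- list(dims = as.integer(d),
               channel_names = as.list(object@channelNames),
               sampling_rate = object@samplingRate,
               time_zero = object@timeZero,
               time_start_ms = object@times[1],
               time_step_ms = if (d[2] > 1) diff(object@times[1:2]) else 0,
               n_times = d[2])
  yaml::write_yaml(meta, paste0(path, ".yml"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(object@voltages), con, size = 8, endian = "little")
  info <- object@trialInfo
  if (ncol(info) == 0) info <- data.frame(trial = seq_len(d[3]))
  utils::write.table(info, paste0(path, ".trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  d <- as.integer(unlist(meta$dims))
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  if (length(v) != prod(d)) stop("epoch data file is truncated")
  info <- utils::read.delim(paste0(path, ".trials.tsv"),
                            stringsAsFactors = FALSE)
  times <- meta$time_start_ms + (seq_len(d[2]) - 1) * meta$time_step_ms
  EpochSet(array(v, dim = d), samplingRate = meta$sampling_rate,
           times = times, channelNames = unlist(meta$channel_names),
           trialInfo = info, timeZero = meta$time_zero)
}
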
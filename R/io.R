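# Plain-text session container: a directory with meta.json, signal.csv,
# resting.csv (one row per channel, %.17g so doubles round-trip exactly)
# and events.csv (onset_sample, label).

.writeMatrixTxt <- function(m, path) {
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), path)
}

.readMatrixTxt <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = ",")
  as.matrix(dt)
}

#' Write a session to a directory container
#'
#' @param session a [RecordingSession-class].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, dir) {
  stopifnot(is(session, "RecordingSession"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(samplingRate = session@samplingRate,
               channelLabels = as.list(session@channelLabels),
               nSamples = ncol(session@signal),
               nRestingSamples = ncol(session@resting))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  .writeMatrixTxt(session@signal, file.path(dir, "signal.csv"))
  .writeMatrixTxt(session@resting, file.path(dir, "resting.csv"))
  utils::write.csv(
    data.frame(onset_sample = session@events$onset,
               label = session@events$label),
    file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a session from a directory container
#'
#' @param dir directory written by [writeSession()]. An `events.csv` is
#'   required; a session without events is an error, never silently
#'   empty.
#' @return A [RecordingSession-class].
#' @export
readSession <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("parse error: missing meta.json in ", dir)
  meta <- jsonlite::fromJSON(metaPath)
  evPath <- file.path(dir, "events.csv")
  if (!file.exists(evPath))
    stop("missing events: ", evPath, " not found")
  ev <- utils::read.csv(evPath, stringsAsFactors = FALSE)
  if (!nrow(ev)) stop("missing events: ", evPath, " is empty")
  signal <- .readMatrixTxt(file.path(dir, "signal.csv"))
  resting <- .readMatrixTxt(file.path(dir, "resting.csv"))
  dimnames(signal) <- NULL
  dimnames(resting) <- NULL
  if (ncol(signal) != meta$nSamples)
    stop("parse error: signal.csv has ", ncol(signal),
         " samples, meta.json declares ", meta$nSamples)
  new("RecordingSession",
      signal = signal,
      samplingRate = meta$samplingRate,
      channelLabels = unlist(meta$channelLabels),
      events = data.frame(onset = ev$onset_sample, label = ev$label,
                          stringsAsFactors = FALSE),
      resting = resting)
}

#' Export band-power features as a long table
#'
#' Columns: trial, channel, band, window, value, label.
#'
#' @param features a [BandPowerFeatures-class].
#' @param path output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "BandPowerFeatures"))
  x <- features@matrix
  fi <- features@featureIndex
  out <- do.call(rbind, lapply(seq_len(ncol(x)), function(j)
    data.frame(trial = seq_len(nrow(x)),
               channel = fi$channel[j],
               band = fi$band[j],
               window = fi$window[j],
               value = x[, j],
               label = as.character(features@labels),
               stringsAsFactors = FALSE)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
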
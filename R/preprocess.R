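# Re-referencing, epoching and amplitude screening.

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the channel mean of the output is exactly zero. The resting segment is
#' re-referenced the same way (same montage), keeping baseline power in
#' the same reference as the task data.
#'
#' @param session a [RecordingSession-class] with at least 2 channels.
#' @return The re-referenced [RecordingSession-class].
#' @export
commonAverageReference <- function(session) {
  stopifnot(is(session, "RecordingSession"))
  if (nChannels(session) < 2L)
    stop("reference error: common average reference undefined for a single channel")
  car <- function(m) if (ncol(m)) sweep(m, 2, colMeans(m)) else m
  session@signal <- car(session@signal)
  session@resting <- car(session@resting)
  session
}

#' Cut a continuous recording into trials
#'
#' Trial t covers samples `onset + round(start * fs)` to
#' `onset + round(end * fs) - 1` (half-open window, 0 on the time axis at
#' the onset sample, rounding half away from zero), so a (-1, 1) s window
#' at 1600 Hz yields 3200 samples and (-1, 1.5) yields 4000.
#'
#' @param session a [RecordingSession-class].
#' @param window length-2 seconds, `start < 0 < end`.
#' @return An [EpochSet-class] with labels carried over and all trials
#'   initially kept.
#' @export
epochize <- function(session, window = c(-1, 1.5)) {
  stopifnot(is(session, "RecordingSession"), length(window) == 2L,
            window[1] < 0, window[2] > 0)
  fs <- session@samplingRate
  s0 <- as.integer(roundHalfAway(window[1] * fs))
  s1 <- as.integer(roundHalfAway(window[2] * fs))
  len <- s1 - s0
  ev <- session@events
  if (!nrow(ev)) stop("no events to epoch")
  nS <- ncol(session@signal)
  bad <- which(ev$onset + s0 < 1L | ev$onset + s1 - 1L > nS)
  if (length(bad))
    stop("boundary error: trial(s) ", paste(bad, collapse = ", "),
         " extend beyond the recording")
  nC <- nChannels(session)
  data <- array(0, c(nrow(ev), nC, len))
  for (t in seq_len(nrow(ev))) {
    idx <- (ev$onset[t] + s0):(ev$onset[t] + s1 - 1L)
    data[t, , ] <- session@signal[, idx, drop = FALSE]
  }
  new("EpochSet",
      data = data,
      samplingRate = fs,
      timeAxis = (s0:(s1 - 1L)) / fs,
      labels = factor(ev$label, levels = .classLevels),
      keptMask = rep(TRUE, nrow(ev)))
}

#' Amplitude-threshold trial screening
#'
#' Automatic stand-in for manual artifact review: a trial is rejected when
#' its peak absolute value on any channel exceeds `threshold` times that
#' channel's robust SD (1.4826 x median absolute deviation, estimated over
#' all trials and samples). Labels are unchanged; only `keptMask` is
#' updated.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold positive multiple of the per-channel robust SD
#'   (default 8).
#' @return The [EpochSet-class] with an updated `keptMask`.
#' @export
screenTrials <- function(epochs, threshold = 8) {
  stopifnot(is(epochs, "EpochSet"), threshold > 0)
  d <- dim(epochs@data)
  keep <- rep(TRUE, d[1])
  if (is.finite(threshold)) {
    for (c in seq_len(d[2])) {
      robustSD <- stats::mad(as.vector(epochs@data[, c, ]))
      if (robustSD <= 0) next
      peaks <- apply(abs(epochs@data[, c, , drop = FALSE]), 1, max)
      keep <- keep & (peaks <= threshold * robustSD)
    }
  }
  if (!any(keep))
    stop("empty-set error: all trials rejected at threshold ", threshold)
  epochs@keptMask <- keep
  epochs
}
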
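#' Accessors for gammaSME objects
#'
#' Small accessor generics used in place of direct slot access: trial and
#' channel counts, labels, time axes, feature matrices, t/p values and
#' accuracy summaries.
#'
#' @param x a gammaSME object.
#' @return The corresponding slot or derived summary.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nChannels", "RecordingSession", function(x) nrow(x@signal))
#' @rdname accessors
setMethod("samplingRate", "RecordingSession", function(x) x@samplingRate)
#' @rdname accessors
setMethod("nTrials", "RecordingSession", function(x) nrow(x@events))

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])
#' @rdname accessors
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname accessors
setMethod("timeAxis", "EpochSet", function(x) x@timeAxis)
#' @rdname accessors
setMethod("keptMask", "EpochSet", function(x) x@keptMask)

#' @rdname accessors
setMethod("nTrials", "TFRPower", function(x) dim(x@power)[1])
#' @rdname accessors
setMethod("nChannels", "TFRPower", function(x) dim(x@power)[2])
#' @rdname accessors
setMethod("trialLabels", "TFRPower", function(x) x@labels)
#' @rdname accessors
setMethod("timeAxis", "TFRPower", function(x) x@timeAxis)
#' @rdname accessors
setMethod("isNormalized", "TFRPower", function(x) x@normalized)
#' @rdname accessors
setMethod("baselinePower", "TFRPower", function(x) x@baseline)

#' @rdname accessors
setMethod("nTrials", "BandPowerFeatures", function(x) nrow(x@matrix))
#' @rdname accessors
setMethod("trialLabels", "BandPowerFeatures", function(x) x@labels)
#' @rdname accessors
setMethod("featureMatrix", "BandPowerFeatures", function(x) x@matrix)
#' @rdname accessors
setMethod("featureIndex", "BandPowerFeatures", function(x) x@featureIndex)

#' @rdname accessors
setMethod("tValues", "SMEMap", function(x) x@tValues)
#' @rdname accessors
setMethod("pValues", "SMEMap", function(x) x@pValues)
#' @rdname accessors
setMethod("featureIndex", "SMEMap", function(x) x@featureIndex)

#' @rdname accessors
setMethod("selectedFeatures", "FeatureSelection", function(x) x@selected)

#' @rdname accessors
setMethod("accuracies", "CVResult", function(x) x@accuracies)
#' @rdname accessors
setMethod("balancedAccuracies", "CVResult", function(x) x@balancedAccuracies)
#' @rdname accessors
setMethod("meanAccuracy", "CVResult", function(x) mean(x@accuracies))
#' @rdname accessors
setMethod("maxAccuracy", "CVResult", function(x) max(x@accuracies))
#' @rdname accessors
setMethod("sdAccuracy", "CVResult", function(x) stats::sd(x@accuracies))

#' Subset an epoch set by trial
#'
#' @param epochs an [EpochSet-class].
#' @param keep logical or integer trial index.
#' @return An [EpochSet-class] restricted to the kept trials.
#' @export
subsetTrials <- function(epochs, keep) {
  stopifnot(is(epochs, "EpochSet"))
  new("EpochSet",
      data = epochs@data[keep, , , drop = FALSE],
      samplingRate = epochs@samplingRate,
      timeAxis = epochs@timeAxis,
      labels = epochs@labels[keep],
      keptMask = epochs@keptMask[keep])
}

setMethod("show", "RecordingSession", function(object) {
  cat("RecordingSession:", nChannels(object), "channels x",
      ncol(object@signal), "samples @", object@samplingRate, "Hz\n")
  cat("  events:", nrow(object@events), "(",
      sum(object@events$label == "remembered"), "remembered /",
      sum(object@events$label == "forgotten"), "forgotten )\n")
  cat("  resting:", ncol(object@resting), "samples (",
      round(ncol(object@resting) / object@samplingRate, 1), "s )\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3], "samples,",
      "t = [", min(object@timeAxis), ",", max(object@timeAxis), "] s\n")
  cat("  kept:", sum(object@keptMask), "/", d[1], "trials\n")
})

setMethod("show", "TFRPower", function(object) {
  d <- dim(object@power)
  cat("TFRPower:", d[1], "trials x", d[2], "channels x", d[3],
      "frequencies x", d[4], "samples",
      if (object@normalized) "(baseline-normalized)" else "(raw)", "\n")
})

setMethod("show", "BandPowerFeatures", function(object) {
  cat("BandPowerFeatures:", nrow(object@matrix), "trials x",
      ncol(object@matrix), "features (",
      paste(unique(object@featureIndex$band), collapse = ", "), "x",
      paste(unique(object@featureIndex$window), collapse = ", "), ")\n")
})

setMethod("show", "SMEMap", function(object) {
  cat("SMEMap:", length(object@tValues), "features, df =", object@df, "\n")
  cat("  significant (uncorrected, alpha =", object@alpha, "):",
      sum(object@pValues < object@alpha, na.rm = TRUE), "\n")
  if (!all(is.na(object@adjustedP)))
    cat("  significant (Bonferroni):", sum(object@correctedMask), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d splits (%d train / %d test), mean %.3f, max %.3f, sd %.3f\n",
    length(object@accuracies), object@nTrain, object@nTest,
    meanAccuracy(object), maxAccuracy(object), sdAccuracy(object)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult (%s): observed %.3f, null mean %.3f, p = %.4g (%d permutations)\n",
    object@statistic, object@observed, mean(object@nullAccuracies),
    object@pValue, length(object@nullAccuracies)))
})
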
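#' @import methods
NULL

.classLevels <- c("remembered", "forgotten")

# ---------------------------------------------------------------------------
# configuration classes
# ---------------------------------------------------------------------------

#' Synthetic recording configuration
#'
#' Parameters of the synthetic electrocorticography generator. The defaults
#' reproduce the acquisition conditions the analysis assumes: 1,600 Hz
#' sampling, a 1/f background band-limited to 0.1--150 Hz, a 5-minute
#' resting segment, epochs from 1 s before word onset to 1.5 s after, and
#' an imbalanced 43 remembered / 10 forgotten trial count.
#'
#' @slot nChannels number of channels.
#' @slot samplingRate sampling rate in Hz.
#' @slot spectralExponent exponent beta of the 1/f^beta background power
#'   spectrum.
#' @slot bandLimits length-2 Hz vector; the background is band-limited to
#'   this range.
#' @slot nRemembered,nForgotten trial counts per outcome class.
#' @slot effectChannels 1-based indices of channels carrying the gamma
#'   effect.
#' @slot effectBand length-2 Hz vector; band of the induced power increase.
#' @slot effectSize fractional post-onset band-power increase on remembered
#'   trials (0.5 = +50%).
#' @slot preEffectSize fractional band-power increase applied over the
#'   pre-stimulus portion of remembered epochs (default 0; the effect is
#'   post-onset only).
#' @slot restingDuration resting-segment duration in seconds.
#' @slot epochWindow length-2 seconds vector around word onset.
#' @slot interTrialInterval onset-to-onset spacing in seconds.
#' @slot seed integer RNG seed.
#' @seealso [synthConfig()], [generateSession()]
#' @export
setClass("SynthConfig", slots = c(
  nChannels = "integer",
  samplingRate = "numeric",
  spectralExponent = "numeric",
  bandLimits = "numeric",
  nRemembered = "integer",
  nForgotten = "integer",
  effectChannels = "integer",
  effectBand = "numeric",
  effectSize = "numeric",
  preEffectSize = "numeric",
  restingDuration = "numeric",
  epochWindow = "numeric",
  interTrialInterval = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  fs <- object@samplingRate
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be positive")
  if (fs <= 0) msg <- c(msg, "samplingRate must be positive")
  if (object@nRemembered < 1L || object@nForgotten < 1L)
    msg <- c(msg, "trial counts must be positive")
  if (object@effectSize < 0 || object@preEffectSize < 0)
    msg <- c(msg, "effect sizes must be >= 0")
  if (length(object@bandLimits) != 2L ||
      object@bandLimits[1] <= 0 || object@bandLimits[2] >= fs / 2 ||
      diff(object@bandLimits) <= 0)
    msg <- c(msg, "bandLimits must be increasing and within (0, samplingRate/2)")
  if (length(object@effectChannels) &&
      (any(object@effectChannels < 1L) ||
       any(object@effectChannels > object@nChannels)))
    msg <- c(msg, "effectChannels must be within 1..nChannels")
  if (length(object@effectBand) != 2L || diff(object@effectBand) <= 0 ||
      object@effectBand[1] < object@bandLimits[1] ||
      object@effectBand[2] > object@bandLimits[2])
    msg <- c(msg, "configuration error: effectBand must lie within bandLimits")
  if (length(object@epochWindow) != 2L ||
      !(object@epochWindow[1] < 0 && object@epochWindow[2] > 0))
    msg <- c(msg, "epochWindow must satisfy start < 0 < end")
  if (object@restingDuration <= 0)
    msg <- c(msg, "restingDuration must be positive")
  if (object@interTrialInterval <= 0)
    msg <- c(msg, "interTrialInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SynthConfig-class
#' @param nChannels,samplingRate,spectralExponent,bandLimits,nRemembered,nForgotten,effectChannels,effectBand,effectSize,preEffectSize,restingDuration,epochWindow,interTrialInterval,seed see slot documentation.
#' @return `synthConfig()` returns a validated `SynthConfig`.
#' @examples
#' cfg <- synthConfig(nChannels = 4, nRemembered = 8, nForgotten = 8,
#'                    samplingRate = 400, restingDuration = 10,
#'                    epochWindow = c(-0.5, 1), interTrialInterval = 2)
#' @export
synthConfig <- function(nChannels = 20L,
                        samplingRate = 1600,
                        spectralExponent = 1,
                        bandLimits = c(0.1, 150),
                        nRemembered = 43L,
                        nForgotten = 10L,
                        effectChannels = integer(),
                        effectBand = c(60, 150),
                        effectSize = 0,
                        preEffectSize = 0,
                        restingDuration = 300,
                        epochWindow = c(-1, 1.5),
                        interTrialInterval = 5,
                        seed = 1L) {
  new("SynthConfig",
      nChannels = as.integer(nChannels),
      samplingRate = samplingRate,
      spectralExponent = spectralExponent,
      bandLimits = bandLimits,
      nRemembered = as.integer(nRemembered),
      nForgotten = as.integer(nForgotten),
      effectChannels = as.integer(effectChannels),
      effectBand = effectBand,
      effectSize = effectSize,
      preEffectSize = preEffectSize,
      restingDuration = restingDuration,
      epochWindow = epochWindow,
      interTrialInterval = interTrialInterval,
      seed = as.integer(seed))
}

#' Morlet wavelet specification
#'
#' The wavelet at frequency f is a complex sinusoid under a Gaussian
#' envelope with temporal SD `sigma_t = cycles / (2 * pi * f)`, normalized
#' to unit energy. The default grid covers the gamma range, 30--150 Hz in
#' 2-Hz steps, with 7 cycles.
#'
#' @slot frequencies strictly increasing Hz grid.
#' @slot cycles number of cycles in the Gaussian envelope.
#' @slot coverage probability mass used when reporting the effective window
#'   length (default 0.95).
#' @seealso [morletPower()], [effectiveWindow()]
#' @export
setClass("WaveletSpec", slots = c(
  frequencies = "numeric",
  cycles = "numeric",
  coverage = "numeric"
))

setValidity("WaveletSpec", function(object) {
  msg <- character()
  f <- object@frequencies
  if (!length(f) || any(f <= 0) || is.unsorted(f, strictly = TRUE))
    msg <- c(msg, "frequencies must be positive and strictly increasing")
  if (object@cycles <= 0) msg <- c(msg, "cycles must be positive")
  if (object@coverage <= 0 || object@coverage >= 1)
    msg <- c(msg, "coverage must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname WaveletSpec-class
#' @param frequencies,cycles,coverage see slot documentation.
#' @export
waveletSpec <- function(frequencies = seq(30, 150, by = 2),
                        cycles = 7, coverage = 0.95) {
  new("WaveletSpec", frequencies = as.numeric(frequencies),
      cycles = cycles, coverage = coverage)
}

#' RBF-SVM specification
#'
#' Kernel `K(x, y) = exp(-||x - y||^2 / (2 * sigma^2))` with soft-margin
#' cost `C`; defaults sigma = 2, cost = 1. `standardize` controls
#' per-feature z-scoring with mean/SD estimated on the training fold only.
#'
#' @slot sigma RBF kernel width.
#' @slot cost soft-margin constant.
#' @slot standardize logical; per-training-fold feature standardization.
#' @export
setClass("SVMSpec", slots = c(
  sigma = "numeric", cost = "numeric", standardize = "logical"
))

setValidity("SVMSpec", function(object) {
  if (object@sigma <= 0 || object@cost <= 0)
    "sigma and cost must be positive" else TRUE
})

#' @rdname SVMSpec-class
#' @param sigma,cost,standardize see slot documentation.
#' @export
svmSpec <- function(sigma = 2, cost = 1, standardize = TRUE) {
  new("SVMSpec", sigma = sigma, cost = cost, standardize = standardize)
}

#' Repeated random split specification
#'
#' @slot trainFraction fraction of trials in the training fold (default
#'   0.8).
#' @slot iterations number of random splits (default 10,000; reduce for
#'   quick runs).
#' @slot stratified logical; draw the training fold per class so both
#'   classes appear in both folds.
#' @slot seed integer RNG seed for the split stream.
#' @export
setClass("CVSpec", slots = c(
  trainFraction = "numeric", iterations = "integer",
  stratified = "logical", seed = "integer"
))

setValidity("CVSpec", function(object) {
  msg <- character()
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname CVSpec-class
#' @param trainFraction,iterations,stratified,seed see slot documentation.
#' @export
cvSpec <- function(trainFraction = 0.8, iterations = 10000L,
                   stratified = TRUE, seed = 1L) {
  new("CVSpec", trainFraction = trainFraction,
      iterations = as.integer(iterations),
      stratified = stratified, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# data classes
# ---------------------------------------------------------------------------

#' Continuous multichannel recording with events
#'
#' @slot signal channels x samples matrix (arbitrary amplitude units).
#' @slot samplingRate Hz.
#' @slot channelLabels character channel names.
#' @slot events data.frame with columns `onset` (1-based sample index) and
#'   `label` (`"remembered"` or `"forgotten"`).
#' @slot resting channels x samples matrix recorded before the task, used
#'   for baseline power.
#' @export
setClass("RecordingSession", slots = c(
  signal = "matrix",
  samplingRate = "numeric",
  channelLabels = "character",
  events = "data.frame",
  resting = "matrix"
))

setValidity("RecordingSession", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (length(object@channelLabels) != nrow(object@signal))
    msg <- c(msg, "channelLabels must match signal rows")
  ev <- object@events
  if (!all(c("onset", "label") %in% names(ev)))
    msg <- c(msg, "events must have columns onset and label")
  else {
    if (!all(ev$label %in% .classLevels))
      msg <- c(msg, "event labels restricted to remembered/forgotten")
    if (nrow(ev) && (any(ev$onset < 1) || any(ev$onset > ncol(object@signal))))
      msg <- c(msg, "event onsets must index into the signal")
  }
  if (nrow(object@resting) && nrow(object@resting) != nrow(object@signal))
    msg <- c(msg, "resting must have the same channels as signal")
  if (length(msg)) msg else TRUE
})

#' Epoched trials around word onsets
#'
#' @slot data trials x channels x time array.
#' @slot samplingRate Hz.
#' @slot timeAxis seconds relative to onset (onset = 0; onset sample on the
#'   post-stimulus side).
#' @slot labels per-trial factor with levels remembered/forgotten.
#' @slot keptMask per-trial logical after artifact screening.
#' @export
setClass("EpochSet", slots = c(
  data = "array",
  samplingRate = "numeric",
  timeAxis = "numeric",
  labels = "factor",
  keptMask = "logical"
))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be trials x channels x time")
  else {
    if (length(object@timeAxis) != d[3])
      msg <- c(msg, "timeAxis must match the time dimension")
    if (length(object@labels) != d[1])
      msg <- c(msg, "labels length must equal number of trials")
    if (length(object@keptMask) != d[1])
      msg <- c(msg, "keptMask length must equal number of trials")
  }
  if (!identical(levels(object@labels), .classLevels))
    msg <- c(msg, "labels must have levels remembered, forgotten")
  if (length(msg)) msg else TRUE
})

#' Time-frequency power
#'
#' @slot power trials x channels x frequencies x time nonnegative array;
#'   dimensionless ratios once normalized.
#' @slot frequencies Hz grid.
#' @slot timeAxis seconds relative to onset.
#' @slot samplingRate Hz.
#' @slot normalized logical; TRUE after division by resting baseline power.
#' @slot baseline channels x frequencies mean resting power (empty before
#'   normalization).
#' @slot edgeCounts per-frequency number of samples at each epoch edge that
#'   lie within half the kernel support and are excluded from window means.
#' @slot labels per-trial factor.
#' @export
setClass("TFRPower", slots = c(
  power = "array",
  frequencies = "numeric",
  timeAxis = "numeric",
  samplingRate = "numeric",
  normalized = "logical",
  baseline = "matrix",
  edgeCounts = "integer",
  labels = "factor"
))

setValidity("TFRPower", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 4L)
    msg <- c(msg, "power must be trials x channels x frequencies x time")
  else {
    if (length(object@frequencies) != d[3])
      msg <- c(msg, "frequencies must match dim 3")
    if (length(object@timeAxis) != d[4])
      msg <- c(msg, "timeAxis must match dim 4")
    if (length(object@labels) != d[1])
      msg <- c(msg, "labels must match trials")
    if (length(object@edgeCounts) != d[3])
      msg <- c(msg, "edgeCounts must be per-frequency")
  }
  if (any(object@power < 0)) msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Band/window aggregated power features
#'
#' One feature per (channel, band, window): the mean of normalized power
#' over the band's frequencies and the window's (edge-valid) samples.
#'
#' @slot matrix trials x features.
#' @slot featureIndex data.frame with columns `channel`, `band`, `window`,
#'   `bandIdx`, `windowIdx`, aligned to the matrix columns.
#' @slot labels per-trial factor.
#' @export
setClass("BandPowerFeatures", slots = c(
  matrix = "matrix",
  featureIndex = "data.frame",
  labels = "factor"
))

setValidity("BandPowerFeatures", function(object) {
  msg <- character()
  if (nrow(object@featureIndex) != ncol(object@matrix))
    msg <- c(msg, "featureIndex rows must equal feature columns")
  if (length(object@labels) != nrow(object@matrix))
    msg <- c(msg, "labels must match trials")
  if (length(msg)) msg else TRUE
})

#' Subsequent-memory-effect map
#'
#' Per-feature pooled-variance two-sample t statistics contrasting
#' remembered vs forgotten trials; positive t means remembered > forgotten.
#'
#' @slot tValues per-feature t.
#' @slot pValues two-sided p in (0, 1].
#' @slot adjustedP Bonferroni-adjusted p (NA before correction).
#' @slot df degrees of freedom, n1 + n2 - 2.
#' @slot alpha significance level.
#' @slot correctedMask logical significance after Bonferroni.
#' @slot degenerate logical; TRUE where the pooled variance is zero and t
#'   is undefined (excluded from ranking).
#' @slot featureIndex copy of the feature index.
#' @export
setClass("SMEMap", slots = c(
  tValues = "numeric",
  pValues = "numeric",
  adjustedP = "numeric",
  df = "numeric",
  alpha = "numeric",
  correctedMask = "logical",
  degenerate = "logical",
  featureIndex = "data.frame"
))

setValidity("SMEMap", function(object) {
  n <- length(object@tValues)
  if (length(object@pValues) != n || length(object@degenerate) != n ||
      nrow(object@featureIndex) != n)
    "tValues, pValues, degenerate and featureIndex must align" else TRUE
})

#' Ranked feature selection
#'
#' @slot selected column indices ordered by decreasing |t|.
#' @slot fraction fraction of features retained.
#' @slot statistic |t| of the selected features, decreasing.
#' @export
setClass("FeatureSelection", slots = c(
  selected = "integer",
  fraction = "numeric",
  statistic = "numeric"
))

#' Repeated-split cross-validation result
#'
#' @slot accuracies per-iteration test accuracy in `[0, 1]`.
#' @slot balancedAccuracies per-iteration mean of per-class accuracies.
#' @slot nTrain,nTest fold sizes.
#' @export
setClass("CVResult", slots = c(
  accuracies = "numeric",
  balancedAccuracies = "numeric",
  nTrain = "integer",
  nTest = "integer"
))

setValidity("CVResult", function(object) {
  a <- c(object@accuracies, object@balancedAccuracies)
  if (length(a) && (any(a < 0) || any(a > 1)))
    "accuracies must lie in [0, 1]" else TRUE
})

#' Label-permutation chance calibration result
#'
#' @slot nullAccuracies per-permutation mean statistic under shuffled
#'   labels.
#' @slot observed the statistic on the true labels.
#' @slot pValue empirical p, `(1 + #\{null >= observed\}) / (nPerm + 1)`.
#' @slot statistic `"balanced"` or `"accuracy"`.
#' @export
setClass("PermutationResult", slots = c(
  nullAccuracies = "numeric",
  observed = "numeric",
  pValue = "numeric",
  statistic = "character"
))

#' End-to-end pipeline configuration
#'
#' @slot synth [SynthConfig-class] for the generator.
#' @slot wavelet [WaveletSpec-class].
#' @slot svm [SVMSpec-class].
#' @slot cv [CVSpec-class].
#' @slot windows named list of length-2 second vectors (defaults: pre
#'   -0.5--0 s, early 0--1 s, late 0--1.5 s).
#' @slot bands named list of length-2 Hz vectors (defaults: lowGamma
#'   30--60, highGamma 60--150).
#' @slot selectionFraction top fraction of |t| kept (default 0.2).
#' @slot selectionMode `"within-fold"` (selection recomputed inside each
#'   training fold; leakage-free default) or `"pooled"` (selection on all
#'   trials before cross-validation).
#' @slot screenThreshold robust-SD multiple for amplitude screening.
#' @slot masterSeed integer; all stage seeds derive from it via
#'   [stageSeed()].
#' @export
setClass("PipelineConfig", slots = c(
  synth = "SynthConfig",
  wavelet = "WaveletSpec",
  svm = "SVMSpec",
  cv = "CVSpec",
  windows = "list",
  bands = "list",
  selectionFraction = "numeric",
  selectionMode = "character",
  screenThreshold = "numeric",
  masterSeed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!length(object@windows) || is.null(names(object@windows)))
    msg <- c(msg, "windows must be a named list")
  if (!length(object@bands) || is.null(names(object@bands)))
    msg <- c(msg, "bands must be a named list")
  if (object@selectionFraction <= 0 || object@selectionFraction > 1)
    msg <- c(msg, "selectionFraction must be in (0, 1]")
  if (!object@selectionMode %in% c("within-fold", "pooled"))
    msg <- c(msg, "selectionMode must be 'within-fold' or 'pooled'")
  if (object@screenThreshold <= 0)
    msg <- c(msg, "screenThreshold must be positive")
  if (length(msg)) msg else TRUE
})
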
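# Shared fixtures: reduced problem sizes so the whole suite stays fast;
# the scientific structure (1/f background, gamma bands, imbalance,
# stratified splits) matches the full-scale defaults.

smallConfig <- function(...) {
  args <- list(nChannels = 6L, samplingRate = 400, nRemembered = 10L,
               nForgotten = 10L, restingDuration = 20,
               epochWindow = c(-0.6, 1.2), interTrialInterval = 2.5,
               seed = 1L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(synthConfig, args)
}

smallWavelet <- function(step = 12) waveletSpec(seq(30, 150, by = step))

# hand-built session with known content for index arithmetic tests
handSession <- function(nSamples = 8000, fs = 1600, onsets = 3201L,
                        labels = "remembered", nChannels = 2L) {
  signal <- matrix(seq_len(nChannels * nSamples), nChannels, nSamples)
  new("RecordingSession",
      signal = signal, samplingRate = fs,
      channelLabels = sprintf("ch%02d", seq_len(nChannels)),
      events = data.frame(onset = as.integer(onsets),
                          label = rep(labels, length.out = length(onsets)),
                          stringsAsFactors = FALSE),
      resting = matrix(0, nChannels, 100))
}

# Gaussian feature sets for decoder tests; first n1 trials are remembered
makeFeatures <- function(n1 = 20, n2 = 20, p = 10, delta = 0,
                         effectCols = integer(), seed = 1) {
  x <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm((n1 + n2) * p), n1 + n2, p)
    if (length(effectCols))
      m[seq_len(n1), effectCols] <- m[seq_len(n1), effectCols] + delta
    m
  })
  fi <- data.frame(channel = seq_len(p), band = "lowGamma",
                   window = "early", bandIdx = 1L, windowIdx = 1L,
                   stringsAsFactors = FALSE)
  new("BandPowerFeatures", matrix = x, featureIndex = fi,
      labels = factor(rep(c("remembered", "forgotten"), c(n1, n2)),
                      levels = c("remembered", "forgotten")))
}

# uniform TFRPower with no edge exclusion, for aggregation arithmetic
flatTFR <- function(value = 1, nTrials = 3, nChannels = 2,
                    freqs = seq(30, 150, by = 30),
                    times = seq(-0.5, 1.495, by = 0.005), fs = 200) {
  new("TFRPower",
      power = array(value, c(nTrials, nChannels, length(freqs),
                             length(times))),
      frequencies = freqs, timeAxis = times, samplingRate = fs,
      normalized = TRUE,
      baseline = matrix(1, nChannels, length(freqs)),
      edgeCounts = rep(0L, length(freqs)),
      labels = factor(rep(c("remembered", "forgotten"),
                          length.out = nTrials),
                      levels = c("remembered", "forgotten")))
}
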
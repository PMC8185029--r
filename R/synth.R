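# Synthetic ECoG generator: 1/f^beta band-limited background with
# condition-dependent gamma-band power increases on selected channels.

# per-bin spectral amplitude weights for frequency-domain synthesis;
# bin k (0-based) maps to frequency min(k, n-k) * fs / n
.spectralWeights <- function(n, fs, beta, band) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  w <- numeric(n)
  sel <- f >= band[1] & f <= band[2]
  w[sel] <- f[sel]^(-beta / 2)
  w
}

# one realization of band-limited 1/f^beta Gaussian noise with the given
# target variance; Var(y) = (1/n) * sum(w^2) for unit-variance white input
.bandNoise <- function(n, fs, beta, band, targetVar = 1) {
  w <- .spectralWeights(n, fs, beta, band)
  rawVar <- sum(w^2) / n
  if (rawVar <= 0) stop("configuration error: empty synthesis band")
  x <- stats::rnorm(n)
  y <- Re(ifft(stats::fft(x) * w))
  y * sqrt(targetVar / rawVar)
}

# fraction of background variance contributed by frequency bins in `band`
.bandVarFraction <- function(n, fs, beta, fullBand, band) {
  w2 <- .spectralWeights(n, fs, beta, fullBand)^2
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  sum(w2[f >= band[1] & f <= band[2]]) / sum(w2)
}

#' Generate a synthetic recording session
#'
#' Simulates a multichannel recording whose background is band-limited
#' 1/f^beta Gaussian noise (unit variance per channel, arbitrary units),
#' with remembered/forgotten word-onset events at fixed inter-trial
#' intervals and an independent resting segment drawn from the same
#' background process. On remembered trials, each effect channel receives
#' an additional, independent band-limited noise burst in `effectBand`
#' over the post-onset portion of the epoch, scaled so that the expected
#' band power is `(1 + effectSize)` times the forgotten-trial level
#' (induced, non-phase-locked activity). An optional `preEffectSize`
#' applies the same construction over the pre-stimulus portion.
#'
#' @param config a [SynthConfig-class].
#' @return A [RecordingSession-class]; bit-identical across calls with the
#'   same config (the RNG state is restored afterwards).
#' @examples
#' cfg <- synthConfig(nChannels = 4, samplingRate = 400,
#'                    nRemembered = 6, nForgotten = 6,
#'                    restingDuration = 10, epochWindow = c(-0.5, 1),
#'                    interTrialInterval = 2, seed = 7)
#' generateSession(cfg)
#' @export
generateSession <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  fs <- config@samplingRate
  pre <- as.integer(roundHalfAway(-config@epochWindow[1] * fs))
  post <- as.integer(roundHalfAway(config@epochWindow[2] * fs))
  iti <- as.integer(roundHalfAway(config@interTrialInterval * fs))
  if (iti < pre + post)
    stop("scheduling error: inter-trial interval (", iti,
         " samples) shorter than the epoch window (", pre + post, ")")
  nTrial <- config@nRemembered + config@nForgotten
  lead <- pre + as.integer(fs)            # 1 s guard before the first epoch
  onsets <- lead + 1L + (seq_len(nTrial) - 1L) * iti   # 1-based
  total <- lead + (nTrial - 1L) * iti + post + as.integer(fs)
  nRest <- as.integer(roundHalfAway(config@restingDuration * fs))
  beta <- config@spectralExponent
  band <- config@bandLimits

  withr::with_seed(config@seed, {
    labels <- sample(rep(.classLevels, c(config@nRemembered,
                                         config@nForgotten)))
    signal <- matrix(0, config@nChannels, total)
    for (c in seq_len(config@nChannels))
      signal[c, ] <- .bandNoise(total, fs, beta, band)
    resting <- matrix(0, config@nChannels, nRest)
    for (c in seq_len(config@nChannels))
      resting[c, ] <- .bandNoise(nRest, fs, beta, band)

    fB <- .bandVarFraction(total, fs, beta, band, config@effectBand)
    addBurst <- function(idx, size) {
      L <- length(idx)
      for (t in which(labels == "remembered"))
        for (c in config@effectChannels)
          signal[c, onsets[t] + idx] <<- signal[c, onsets[t] + idx] +
            .bandNoise(L, fs, beta, config@effectBand, targetVar = size * fB)
    }
    if (length(config@effectChannels)) {
      if (config@effectSize > 0) addBurst(0:(post - 1L), config@effectSize)
      if (config@preEffectSize > 0) addBurst(-(pre:1L), config@preEffectSize)
    }
  })

  new("RecordingSession",
      signal = signal,
      samplingRate = fs,
      channelLabels = sprintf("ch%02d", seq_len(config@nChannels)),
      events = data.frame(onset = onsets, label = labels,
                          stringsAsFactors = FALSE),
      resting = resting)
}
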
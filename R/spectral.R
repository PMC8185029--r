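# Morlet-wavelet time-frequency power, resting-baseline normalization and
# band/window aggregation.

# unit-energy complex Morlet kernel; Gaussian envelope SD
# sigma_t = cycles / (2*pi*f), truncated at +/- nsd sigma
.morletKernel <- function(f, fs, cycles, nsd = 5) {
  sigma <- cycles / (2 * pi * f)
  h <- max(1L, as.integer(ceiling(nsd * sigma * fs)))
  t <- (-h:h) / fs
  k <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
  k / sqrt(sum(Mod(k)^2))
}

# precomputed kernel FFT bank for signals of length n
.morletBank <- function(spec, fs, n) {
  if (max(spec@frequencies) >= fs / 2)
    stop("spectral error: frequencies must be below the Nyquist rate")
  kernels <- lapply(spec@frequencies, .morletKernel,
                    fs = fs, cycles = spec@cycles)
  h <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  if (n < 2L * (2L * max(h) + 1L))
    stop("support error: signal shorter than twice the kernel support at ",
         spec@frequencies[which.max(h)], " Hz")
  m <- as.integer(nextPow2(n + 2L * max(h)))
  Kf <- lapply(kernels, function(k)
    stats::fft(c(k, complex(m - length(k)))))
  list(Kf = Kf, h = h, m = m)
}

#' Morlet-wavelet power of epoched data
#'
#' Convolves every trial and channel with unit-energy complex Morlet
#' kernels on the frequency grid of `spec` and squares the magnitude.
#' Samples within half the kernel support of an epoch edge are unreliable
#' (the kernel overlaps zero padding); their per-frequency count is stored
#' in `edgeCounts` and they are excluded from downstream window means.
#'
#' @param epochs an [EpochSet-class].
#' @param spec a [WaveletSpec-class].
#' @param downsample integer decimation factor for the power time axis
#'   (default 1, no decimation). The squared envelope is band-limited well
#'   below the sampling rate (its bandwidth is of order f/cycles), so
#'   decimating the stored power leaves band/window means unchanged while
#'   dividing memory by the factor.
#' @return A raw (unnormalized) [TFRPower-class].
#' @export
morletPower <- function(epochs, spec = waveletSpec(), downsample = 1L) {
  stopifnot(is(epochs, "EpochSet"), is(spec, "WaveletSpec"))
  validObject(spec)
  ds <- as.integer(downsample)
  stopifnot(ds >= 1L)
  d <- dim(epochs@data)
  n <- d[3]
  fs <- epochs@samplingRate
  bank <- .morletBank(spec, fs, n)
  nF <- length(spec@frequencies)
  keep <- seq(1L, n, by = ds)
  pow <- array(0, c(d[1], d[2], nF, length(keep)))
  pad <- numeric(bank$m - n)
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      X <- stats::fft(c(epochs@data[t, c, ], pad))
      for (f in seq_len(nF)) {
        cc <- ifft(X * bank$Kf[[f]])
        h <- bank$h[f]
        pow[t, c, f, ] <- Mod(cc[h + keep])^2
      }
    }
  }
  # per-frequency count of decimated samples overlapping the zero-padded
  # edges (conservative: max of the leading and trailing counts)
  edges <- vapply(bank$h, function(h)
    max(sum(keep <= h), sum(keep > n - h)), integer(1))
  new("TFRPower",
      power = pow,
      frequencies = spec@frequencies,
      timeAxis = epochs@timeAxis[keep],
      samplingRate = fs / ds,
      normalized = FALSE,
      baseline = matrix(0, 0, 0),
      edgeCounts = edges,
      labels = epochs@labels)
}

#' Effective wavelet window length
#'
#' Width of the central `coverage` probability mass of the Gaussian
#' envelope: `2 * z * sigma_t` with `z = qnorm((1 + coverage) / 2)` and
#' `sigma_t = cycles / (2 * pi * f)`. With 7 cycles and 95% coverage this
#' is approximately 87 ms at 50 Hz, halving when f doubles.
#'
#' @param f frequency in Hz (vectorized), must be positive.
#' @param spec a [WaveletSpec-class]; `cycles` and `coverage` are used.
#' @return Window length(s) in seconds.
#' @export
effectiveWindow <- function(f, spec = waveletSpec()) {
  stopifnot(is(spec, "WaveletSpec"))
  if (any(f <= 0)) stop("domain error: f must be positive")
  if (spec@coverage <= 0 || spec@coverage >= 1)
    stop("domain error: coverage must be in (0, 1)")
  2 * stats::qnorm((1 + spec@coverage) / 2) * spec@cycles / (2 * pi * f)
}

#' Normalize power by mean resting power
#'
#' Computes, per channel and frequency, the time-mean Morlet power of the
#' pre-task resting segment (excluding edge-flagged samples) and divides
#' the trial power by it, yielding dimensionless ratios comparable across
#' frequencies and channels.
#'
#' @param tfr a raw [TFRPower-class].
#' @param resting a [RecordingSession-class] (its resting segment is used)
#'   or a channels x samples matrix.
#' @param spec the [WaveletSpec-class] used for `tfr`.
#' @param restingRate sampling rate of the resting segment in Hz; defaults
#'   to the session's rate (or, for a bare matrix, to the power time-axis
#'   rate, which is the acquisition rate unless the power was decimated).
#' @return The normalized [TFRPower-class] with the baseline stored.
#' @export
baselineNormalize <- function(tfr, resting, spec = waveletSpec(),
                              restingRate = NULL) {
  stopifnot(is(tfr, "TFRPower"))
  if (tfr@normalized) stop("power is already normalized")
  rest <- if (is(resting, "RecordingSession")) resting@resting else resting
  stopifnot(is.matrix(rest))
  if (nrow(rest) != nChannels(tfr))
    stop("resting segment must have the same channels as the power array")
  nR <- ncol(rest)
  fs <- if (!is.null(restingRate)) restingRate
        else if (is(resting, "RecordingSession")) resting@samplingRate
        else tfr@samplingRate
  bank <- .morletBank(spec, fs, nR)
  if (!identical(as.numeric(spec@frequencies), as.numeric(tfr@frequencies)))
    stop("spec frequencies must match the power array")
  nF <- length(spec@frequencies)
  baseline <- matrix(0, nrow(rest), nF,
                     dimnames = list(NULL, as.character(spec@frequencies)))
  pad <- numeric(bank$m - nR)
  for (c in seq_len(nrow(rest))) {
    X <- stats::fft(c(rest[c, ], pad))
    for (f in seq_len(nF)) {
      h <- bank$h[f]
      cc <- ifft(X * bank$Kf[[f]])[(h + 1L):(h + nR)]
      baseline[c, f] <- mean(Mod(cc[(h + 1L):(nR - h)])^2)
    }
  }
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline error: nonpositive or non-finite resting power")
  # divide per frequency slice (avoids sweep's full-size temporary)
  p <- tfr@power
  tfr@power <- array(0, c(1, 1, 1, 1))
  nT <- dim(p)[1]
  for (f in seq_len(nF))
    p[, , f, ] <- p[, , f, ] / rep(baseline[, f], each = nT)
  tfr@power <- p
  tfr@baseline <- baseline
  tfr@normalized <- TRUE
  tfr
}

#' Aggregate normalized power into band/window features
#'
#' One feature per (channel, band, window): the mean of normalized power
#' over the band's frequencies and the window's samples, excluding
#' per-frequency edge-flagged samples. Bands are half-open `[lo, hi)`
#' except that the upper edge of the grid is included (so 150 Hz belongs
#' to high gamma); windows are half-open `[start, end)` with the onset
#' sample on the post-stimulus side.
#'
#' @param tfr a normalized [TFRPower-class].
#' @param bands named list of length-2 Hz vectors; defaults are the two
#'   nonoverlapping gamma sub-bands, low gamma 30--60 and high gamma
#'   60--150 Hz.
#' @param windows named list of length-2 second vectors; defaults are the
#'   pre-stimulus (-0.5--0 s) and during-stimulus (0--1 s, 0--1.5 s)
#'   analysis windows.
#' @return A [BandPowerFeatures-class] with
#'   `channels * bands * windows` columns.
#' @export
bandFeatures <- function(tfr,
                         bands = list(lowGamma = c(30, 60),
                                      highGamma = c(60, 150)),
                         windows = list(pre = c(-0.5, 0),
                                        early = c(0, 1),
                                        late = c(0, 1.5))) {
  stopifnot(is(tfr, "TFRPower"))
  if (!tfr@normalized)
    stop("band features require baseline-normalized power")
  if (is.null(names(bands)) || is.null(names(windows)))
    stop("bands and windows must be named lists")
  freqs <- tfr@frequencies
  ta <- tfr@timeAxis
  n <- length(ta)
  d <- dim(tfr@power)
  cols <- list()
  index <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    inWin <- which(ta >= w[1] & ta < w[2])
    if (!length(inWin))
      stop("range error: window [", w[1], ", ", w[2],
           ") outside the epoch time axis")
    for (bi in seq_along(bands)) {
      b <- bands[[bi]]
      sel <- freqs >= b[1] & freqs < b[2]
      if (b[2] >= max(freqs)) sel <- sel | freqs == b[2]
      fIdx <- which(sel)
      if (!length(fIdx))
        stop("band [", b[1], ", ", b[2], "] outside the frequency grid")
      acc <- matrix(0, d[1], d[2])
      for (f in fIdx) {
        e <- tfr@edgeCounts[f]
        valid <- inWin[inWin > e & inWin <= n - e]
        if (!length(valid))
          stop("range error: window entirely edge-flagged at ",
               freqs[f], " Hz")
        acc <- acc + rowMeans(tfr@power[, , f, valid, drop = FALSE],
                              dims = 2)
      }
      cols[[length(cols) + 1L]] <- acc / length(fIdx)
      index[[length(index) + 1L]] <- data.frame(
        channel = seq_len(d[2]),
        band = names(bands)[bi],
        window = names(windows)[wi],
        bandIdx = bi,
        windowIdx = wi,
        stringsAsFactors = FALSE)
    }
  }
  new("BandPowerFeatures",
      matrix = do.call(cbind, cols),
      featureIndex = do.call(rbind, index),
      labels = tfr@labels)
}

#' Restrict a feature set to selected columns
#'
#' @param features a [BandPowerFeatures-class].
#' @param which a [FeatureSelection-class], integer column indices, or a
#'   window name (keeps all features of that analysis window).
#' @return The restricted [BandPowerFeatures-class].
#' @export
restrictFeatures <- function(features, which) {
  stopifnot(is(features, "BandPowerFeatures"))
  idx <- if (is(which, "FeatureSelection")) which@selected
         else if (is.character(which))
           base::which(features@featureIndex$window %in% which)
         else as.integer(which)
  if (!length(idx)) stop("empty feature restriction")
  new("BandPowerFeatures",
      matrix = features@matrix[, idx, drop = FALSE],
      featureIndex = features@featureIndex[idx, , drop = FALSE],
      labels = features@labels)
}
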
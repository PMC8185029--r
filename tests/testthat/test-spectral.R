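toneEpochs <- function(freqHz = 50, fs = 400, dur = 2, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freqHz * t)
  new("EpochSet",
      data = array(x, c(1, 1, length(t))),
      samplingRate = fs, timeAxis = t - dur / 2,
      labels = factor("remembered", levels = c("remembered", "forgotten")),
      keptMask = TRUE)
}

test_that("wavelet power recovers a pure tone's frequency by grid argmax", {
  spec <- waveletSpec(seq(30, 150, by = 2))
  tfr <- morletPower(toneEpochs(50), spec)
  n <- length(tfr@timeAxis)
  avg <- vapply(seq_along(spec@frequencies), function(f) {
    e <- tfr@edgeCounts[f]
    mean(tfr@power[1, 1, f, (e + 1):(n - e)])
  }, numeric(1))
  expect_equal(spec@frequencies[which.max(avg)], 50)
})

test_that("power is zero for zero signal and scales quadratically with amplitude", {
  spec <- smallWavelet()
  zero <- toneEpochs(50, amp = 0)
  expect_true(all(morletPower(zero, spec)@power == 0))
  p1 <- morletPower(toneEpochs(50, amp = 1), spec)@power
  p2 <- morletPower(toneEpochs(50, amp = 2), spec)@power
  expect_equal(p2, 4 * p1)
})

test_that("frequencies at or above Nyquist and too-short epochs are rejected", {
  expect_error(morletPower(toneEpochs(50, fs = 200), waveletSpec(seq(30, 150, 2))),
               "spectral error")
  short <- toneEpochs(50, dur = 0.4)
  expect_error(morletPower(short, waveletSpec(c(30, 40))), "support error")
})

test_that("effective window length follows the closed form and 1/f scaling", {
  spec <- waveletSpec(cycles = 7, coverage = 0.95)
  w50 <- effectiveWindow(50, spec)
  expect_equal(w50, 2 * qnorm(0.975) * 7 / (2 * pi * 50), tolerance = 1e-12)
  expect_equal(round(w50, 4), 0.0873)
  expect_equal(effectiveWindow(100, spec), w50 / 2)
  # window shrinks to zero as coverage does
  expect_lt(effectiveWindow(50, waveletSpec(cycles = 7, coverage = 1e-9)), 1e-6)
  expect_error(effectiveWindow(-1, spec), "domain error")
})

test_that("baseline normalization round-trips and rejects degenerate baselines", {
  cfg <- smallConfig(seed = 11L)
  s <- generateSession(cfg)
  ep <- epochize(s, c(-0.6, 1.2))
  spec <- smallWavelet()
  raw <- morletPower(ep, spec)
  norm <- baselineNormalize(raw, s, spec)
  expect_true(norm@normalized)
  back <- sweep(norm@power, c(2, 3), norm@baseline, "*")
  expect_equal(back, raw@power, tolerance = 1e-12)
  expect_error(baselineNormalize(norm, s, spec), "already normalized")
  zeros <- matrix(0, nChannels(s), 4000)
  expect_error(baselineNormalize(raw, zeros, spec), "baseline error")
})

test_that("epochs from the resting process have grand-mean normalized power near one", {
  # long resting segment so the shared baseline-estimation error is small
  # relative to the between-trial SEM the tolerance is built from
  cfg <- smallConfig(nRemembered = 14L, nForgotten = 14L,
                     restingDuration = 120, interTrialInterval = 2.5,
                     seed = 21L)
  s <- generateSession(cfg)
  ep <- epochize(s, c(-0.6, 1.2))
  spec <- smallWavelet()
  fx <- bandFeatures(baselineNormalize(morletPower(ep, spec), s, spec),
                     windows = list(early = c(0, 1)))
  trialMeans <- rowMeans(featureMatrix(fx))
  sem <- sd(trialMeans) / sqrt(length(trialMeans))
  expect_lt(abs(mean(trialMeans) - 1), 3 * sem)
})

test_that("band/window aggregation has the documented arithmetic", {
  tfr <- flatTFR(1)
  fx <- bandFeatures(tfr)
  expect_equal(ncol(featureMatrix(fx)), 2 * 2 * 3)   # 2 ch x 2 bands x 3 windows
  expect_true(all(featureMatrix(fx) == 1))
  expect_equal(nrow(featureIndex(fx)), 12L)
  # 150 Hz belongs to high gamma, 60 Hz is not double-counted
  expect_error(bandFeatures(tfr, windows = list(bad = c(5, 6))), "range error")
  raw <- flatTFR(1); raw@normalized <- FALSE
  expect_error(bandFeatures(raw), "normalized")
})

test_that("feature restriction by window and selection indexes correctly", {
  fx <- bandFeatures(flatTFR(1))
  early <- restrictFeatures(fx, "early")
  expect_true(all(featureIndex(early)$window == "early"))
  expect_equal(ncol(featureMatrix(early)), 4L)
  byIdx <- restrictFeatures(fx, c(1L, 3L))
  expect_equal(ncol(featureMatrix(byIdx)), 2L)
  expect_error(restrictFeatures(fx, integer()), "empty")
})
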
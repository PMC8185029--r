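test_that("common average reference removes the channel mean exactly and is idempotent", {
  s <- handSession()
  s@signal <- matrix(rnorm(4 * 1000), 4, 1000)
  s@channelLabels <- sprintf("ch%02d", 1:4)
  s@resting <- matrix(rnorm(4 * 100), 4, 100)
  r <- commonAverageReference(s)
  expect_true(all(abs(colMeans(r@signal)) < 1e-12))
  expect_true(all(abs(colMeans(r@resting)) < 1e-12))
  r2 <- commonAverageReference(r)
  expect_equal(r2@signal, r@signal)

  # constant channels go to zero; an already zero-mean pair is unchanged
  s@signal <- matrix(1, 4, 1000)
  expect_true(all(commonAverageReference(s)@signal == 0))
  a <- sin(seq_len(1000) / 50)
  s2 <- handSession(nSamples = 1000, onsets = 500L)
  s2@signal <- rbind(a, -a)
  expect_equal(commonAverageReference(s2)@signal, s2@signal)

  s1 <- handSession(nChannels = 1L)
  s1@channelLabels <- "ch01"
  s1@signal <- s1@signal[1, , drop = FALSE]
  s1@resting <- s1@resting[1, , drop = FALSE]
  expect_error(commonAverageReference(s1), "reference error")
})

test_that("epoch sample arithmetic matches the half-open window convention", {
  s <- handSession(nSamples = 8000, fs = 1600, onsets = 3201L)
  ep <- epochize(s, c(-1, 1))
  expect_equal(dim(ep@data)[3], 3200L)
  # 0-based onset 3200 with window (-1, 1): covers samples 1601..4800 (1-based)
  expect_equal(ep@data[1, 1, ], unname(s@signal[1, 1601:4800]))
  expect_equal(ep@timeAxis[1], -1)
  expect_equal(sum(ep@timeAxis == 0), 1L)  # onset sample on the post side

  ep2 <- epochize(s, c(-1, 1.5))
  expect_equal(dim(ep2@data)[3], 4000L)

  s@events$onset <- 101L
  expect_error(epochize(s, c(-1, 1)), "boundary error.*1")
})

test_that("epoching non-overlapping trials then concatenating recovers the signal", {
  s <- handSession(nSamples = 4000, fs = 400, onsets = c(501L, 1501L, 2501L),
                   labels = c("remembered", "forgotten", "remembered"))
  ep <- epochize(s, c(-1, 1.5))
  recon <- c(t(ep@data[, 1, ]))
  expect_equal(recon, unname(s@signal[1, 101:3100]))
})

test_that("amplitude screening rejects only spiked trials", {
  cfg <- smallConfig(seed = 8L)
  ep <- epochize(generateSession(cfg), c(-0.6, 1.2))
  clean <- screenTrials(ep, 8)
  expect_true(all(keptMask(clean)))

  ep@data[7, 3, 100] <- 50 * stats::sd(ep@data)
  screened <- screenTrials(ep, 8)
  expect_identical(which(!keptMask(screened)), 7L)

  expect_true(all(keptMask(screenTrials(ep, Inf))))
  expect_error(screenTrials(ep, 1e-6), "empty-set error")
  expect_error(screenTrials(ep, 0), "threshold > 0")
})
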
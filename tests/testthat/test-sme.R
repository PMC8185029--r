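twoGroupFeatures <- function(rem, forg) {
  x <- cbind(c(rem, forg))
  fi <- data.frame(channel = 1L, band = "lowGamma", window = "early",
                   bandIdx = 1L, windowIdx = 1L, stringsAsFactors = FALSE)
  new("BandPowerFeatures", matrix = x, featureIndex = fi,
      labels = factor(rep(c("remembered", "forgotten"),
                          c(length(rem), length(forg))),
                      levels = c("remembered", "forgotten")))
}

test_that("pooled t matches the closed form and the stats::t.test oracle", {
  m <- smeTMap(twoGroupFeatures(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(m@df, 4)
  expect_equal(tValues(m), 3.674, tolerance = 1e-3)

  for (seed in 1:5) {
    vals <- withr::with_seed(seed, list(r = rnorm(9), f = rnorm(7, sd = 2)))
    m <- smeTMap(twoGroupFeatures(vals$r, vals$f))
    tt <- t.test(vals$r, vals$f, var.equal = TRUE)
    expect_equal(tValues(m), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pValues(m), tt$p.value, tolerance = 1e-10)
  }
})

test_that("t map is antisymmetric in labels, affine-invariant, and zero for identical groups", {
  r <- c(1.2, 3.4, 0.7, 2.2); f <- c(0.3, 1.1, 2.9, 0.4)
  a <- smeTMap(twoGroupFeatures(r, f))
  b <- smeTMap(twoGroupFeatures(f, r))
  expect_equal(tValues(a), -tValues(b))
  expect_equal(pValues(a), pValues(b))
  scaled <- smeTMap(twoGroupFeatures(5 * r - 2, 5 * f - 2))
  expect_equal(tValues(scaled), tValues(a), tolerance = 1e-10)
  same <- smeTMap(twoGroupFeatures(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(tValues(same), 0)
})

test_that("degenerate features are flagged and never ranked", {
  fx <- makeFeatures(n1 = 6, n2 = 6, p = 4, seed = 2)
  fx@matrix[, 2] <- 7   # zero pooled variance
  m <- smeTMap(fx)
  expect_true(m@degenerate[2])
  expect_true(is.na(tValues(m)[2]))
  sel <- selectFeatures(m, fraction = 1)
  expect_false(2L %in% selectedFeatures(sel))
  expect_error(smeTMap(makeFeatures(n1 = 1, n2 = 6, p = 2)),
               "sample-size error")
})

test_that("Bonferroni adjusts p, uses strict inequality, and is monotone", {
  m <- smeTMap(makeFeatures(n1 = 8, n2 = 8, p = 5, seed = 3))
  m@pValues <- c(0.01, 0.001, 1, 0.2, 0.04)
  m@alpha <- 0.05
  b5 <- bonferroniCorrect(m, 5)
  expect_equal(b5@adjustedP, c(0.05, 0.005, 1, 1, 0.2))
  expect_false(b5@correctedMask[1])   # 0.01 * 5 = 0.05, not < 0.05
  expect_true(b5@correctedMask[2])
  expect_true(all(which(b5@correctedMask) %in% which(m@pValues < m@alpha)))
  expect_error(bonferroniCorrect(m, 3), "correction error")
  m@pValues <- rep(1, 5)
  expect_false(any(bonferroniCorrect(m, 5)@correctedMask))
})

test_that("top-fraction selection counts, orders and tie-breaks deterministically", {
  fx <- makeFeatures(n1 = 10, n2 = 10, p = 20, seed = 4)
  m <- smeTMap(fx)
  sel <- selectFeatures(m, fraction = 0.2)
  expect_length(selectedFeatures(sel), 4L)  # ceiling(0.2 * 20)
  expect_true(all(diff(sel@statistic) <= 0))
  all20 <- selectFeatures(m, fraction = 1)
  expect_length(selectedFeatures(all20), 20L)
  expect_equal(selectedFeatures(all20), order(-abs(tValues(m))))

  # exact |t| ties resolve to the lower channel index
  m@tValues <- rep(2, 20)
  tied <- selectFeatures(m, fraction = 0.2)
  expect_equal(selectedFeatures(tied), 1:4)
  expect_error(selectFeatures(m, fraction = 0), "domain error")
  expect_error(selectFeatures(m, fraction = 1.5), "domain error")
  expect_length(selectedFeatures(selectFeatures(m, k = 10)), 10L)
})

test_that("a strong confined effect concentrates selection on effect channels", {
  hits <- vapply(1:5, function(seed) {
    cfg <- smallConfig(effectChannels = 1:2, effectBand = c(30, 150),
                       effectSize = 2, seed = seed)
    s <- generateSession(cfg)
    ep <- epochize(s, c(-0.6, 1.2))
    spec <- smallWavelet()
    fx <- bandFeatures(baselineNormalize(morletPower(ep, spec), s, spec),
                       windows = list(early = c(0, 1)))
    sel <- selectFeatures(smeTMap(fx), fraction = 0.2)  # 3 of 12
    all(featureIndex(fx)$channel[selectedFeatures(sel)] %in% 1:2)
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("Monte-Carlo Lilliefors agrees with the analytic oracle and flags non-normal data", {
  x <- withr::with_seed(1, rnorm(60))
  ours <- lillieforsTest(x, draws = 4000)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p.value - ref$p.value), 0.08)

  normalFlags <- vapply(1:3, function(s)
    lillieforsTest(withr::with_seed(s, rnorm(500)), draws = 2000)$p.value <= 0.01,
    logical(1))
  expect_false(any(normalFlags))
  expFlags <- vapply(1:3, function(s)
    lillieforsTest(withr::with_seed(s, rexp(500)), draws = 2000)$p.value <= 0.01,
    logical(1))
  expect_true(all(expFlags))
  expect_equal(lillieforsTest(rep(3, 10))$p.value, 0)
  expect_error(lillieforsTest(c(1, 2, 3)), "sample-size error")
})

test_that("normalityCheck screens per feature and class", {
  fx <- makeFeatures(n1 = 40, n2 = 40, p = 3, seed = 6)
  fx@matrix[fx@labels == "forgotten", 3] <-
    withr::with_seed(7, rexp(40, rate = 0.2)^2)
  chk <- normalityCheck(fx, draws = 2000)
  expect_equal(nrow(chk), 3L)
  expect_true(chk$flagged[3])
  expect_false(any(chk$flagged[1:2]))
  tiny <- makeFeatures(n1 = 3, n2 = 10, p = 2)
  expect_error(normalityCheck(tiny), "sample-size error")
})

test_that("SME t-table export has the expected shape", {
  m <- bonferroniCorrect(smeTMap(makeFeatures(n1 = 10, n2 = 10, p = 6, seed = 8)))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- writeSMETable(m, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6L)
  expect_named(back, c("window", "band", "channel", "t", "p", "adjustedP",
                       "significance"))
  expect_equal(back$t, unname(tValues(m)), tolerance = 1e-12)
})
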
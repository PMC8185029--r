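test_that("RBF kernel closed form and monotonicity", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2)), 1)
  # squared distance 8 at sigma 2 -> exp(-1)
  expect_equal(rbfKernel(c(0, 0), c(2, 2), sigma = 2), exp(-1))
  d <- seq(0.5, 5, by = 0.5)
  k <- vapply(d, function(dd) rbfKernel(0, dd, sigma = 2), numeric(1))
  expect_true(all(diff(k) < 0))
  expect_error(rbfKernel(1:3, 1:2), "shape error")
  expect_error(rbfKernel(1, 2, sigma = 0), "sigma")
})

test_that("SVM separates well-separated clouds and refuses single-class folds", {
  fx <- makeFeatures(n1 = 40, n2 = 40, p = 2, delta = 6, effectCols = 1:2,
                     seed = 1)
  x <- featureMatrix(fx); g <- fx@labels
  pred <- fitPredictSvm(x, g, x)
  expect_equal(mean(pred == g), 1)
  # a test point identical to a deep training point gets that class
  deep <- x[which.max(x[, 1]), , drop = FALSE]
  expect_equal(as.character(fitPredictSvm(x, g, deep)), "remembered")
  expect_error(fitPredictSvm(x[1:40, ], g[1:40], x), "class-coverage error")
})

test_that("uninformative features decode at chance", {
  fx <- makeFeatures(n1 = 30, n2 = 30, p = 4, seed = 2)
  r <- repeatedSplitCv(fx, cvSpec(iterations = 200, seed = 3), svmSpec())
  expect_gt(meanAccuracy(r), 0.3)
  expect_lt(meanAccuracy(r), 0.7)
})

test_that("stratified 80/20 splits of 55 trials give 44 train / 11 test", {
  fx <- makeFeatures(n1 = 45, n2 = 10, p = 3, seed = 4)
  r <- repeatedSplitCv(fx, cvSpec(iterations = 20, seed = 5), svmSpec())
  expect_equal(r@nTrain, 44L)
  expect_equal(r@nTest, 11L)
  expect_true(all(accuracies(r) >= 0 & accuracies(r) <= 1))
  expect_lte(meanAccuracy(r), maxAccuracy(r))
  tiny <- makeFeatures(n1 = 2, n2 = 1, p = 2)
  expect_error(repeatedSplitCv(tiny, cvSpec(iterations = 5)), "split error")
})

test_that("cross-validation is bit-reproducible and column-order invariant", {
  fx <- makeFeatures(n1 = 20, n2 = 20, p = 5, delta = 1, effectCols = 1:2,
                     seed = 6)
  cv <- cvSpec(iterations = 50, seed = 7)
  a <- repeatedSplitCv(fx, cv, svmSpec())
  b <- repeatedSplitCv(fx, cv, svmSpec())
  expect_identical(accuracies(a), accuracies(b))

  perm <- c(4, 2, 5, 1, 3)
  shuffled <- fx
  shuffled@matrix <- fx@matrix[, perm]
  shuffled@featureIndex <- fx@featureIndex[perm, ]
  c2 <- repeatedSplitCv(shuffled, cv, svmSpec())
  expect_equal(accuracies(c2), accuracies(a))
})

test_that("perfectly separable features give mean accuracy 1", {
  fx <- makeFeatures(n1 = 25, n2 = 25, p = 3, delta = 8, effectCols = 1,
                     seed = 8)
  r <- repeatedSplitCv(fx, cvSpec(iterations = 50, seed = 9), svmSpec())
  expect_equal(meanAccuracy(r), 1)
})

test_that("optimal-candidate selection prefers effect features and tie-breaks first", {
  fx <- makeFeatures(n1 = 25, n2 = 25, p = 10, delta = 3, effectCols = 1:3,
                     seed = 10)
  effectCand <- new("FeatureSelection", selected = 1:3, fraction = 0.3,
                    statistic = rep(3, 3))
  nullCand <- new("FeatureSelection", selected = 7:9, fraction = 0.3,
                  statistic = rep(0, 3))
  pick <- selectOptimal(list(nullCand, effectCand), fx,
                        cvSpec(iterations = 60, seed = 11), svmSpec())
  expect_equal(pick$best, 2L)
  expect_gt(pick$meanAccuracies[2], pick$meanAccuracies[1])

  one <- selectOptimal(list(effectCand), fx, cvSpec(iterations = 10, seed = 1))
  expect_equal(one$best, 1L)
  twins <- selectOptimal(list(effectCand, effectCand), fx,
                         cvSpec(iterations = 10, seed = 1))
  expect_equal(twins$best, 1L)
  expect_error(selectOptimal(list(), fx), "input error")
})

test_that("permutation null centers at 0.5 balanced and at the majority rate unbalanced", {
  fx <- makeFeatures(n1 = 15, n2 = 15, p = 3, seed = 12)
  pr <- permutationChance(fx, cvSpec(iterations = 40, seed = 13), svmSpec(),
                          nPermutations = 60, permIterations = 40)
  expect_lt(abs(mean(pr@nullAccuracies) - 0.5), 0.1)

  imb <- makeFeatures(n1 = 45, n2 = 10, p = 3, seed = 14)
  prAcc <- permutationChance(imb, cvSpec(iterations = 30, seed = 15),
                             svmSpec(), nPermutations = 40,
                             statistic = "accuracy", permIterations = 30)
  expect_lt(abs(mean(prAcc@nullAccuracies) - 45 / 55), 0.07)
  prBal <- permutationChance(imb, cvSpec(iterations = 30, seed = 15),
                             svmSpec(), nPermutations = 40,
                             statistic = "balanced", permIterations = 30)
  expect_lt(abs(mean(prBal@nullAccuracies) - 0.5), 0.1)
})

test_that("a genuine effect yields a small empirical permutation p", {
  fx <- makeFeatures(n1 = 25, n2 = 25, p = 6, delta = 2.5, effectCols = 1:2,
                     seed = 16)
  pr <- permutationChance(fx, cvSpec(iterations = 60, seed = 17), svmSpec(),
                          nPermutations = 120, permIterations = 40)
  expect_lt(pr@pValue, 0.01)
})

test_that("LDA and FLDA agree with each other and with the MASS oracle", {
  fx <- makeFeatures(n1 = 30, n2 = 30, p = 4, delta = 1.5, effectCols = 1:2,
                     seed = 18)
  tab <- compareClassifiers(fx, cvSpec(iterations = 80, seed = 19), svmSpec())
  expect_setequal(tab$method, c("svm", "lda", "flda"))
  lda <- tab$meanAccuracy[tab$method == "lda"]
  flda <- tab$meanAccuracy[tab$method == "flda"]
  expect_lt(abs(lda - flda), 0.01)

  # pooled-covariance discriminant vs MASS::lda with equal priors
  x <- featureMatrix(fx); g <- fx@labels
  tr <- seq(1, 60, by = 2); te <- seq(2, 60, by = 2)
  ours <- gammaSME:::.fitPredictLda(x[tr, ], g[tr], x[te, ])
  ref <- predict(MASS::lda(x[tr, ], grouping = g[tr],
                           prior = c(0.5, 0.5)), x[te, ])$class
  expect_equal(as.character(ours), as.character(ref))
})

test_that("all three classifiers solve a linearly separable problem", {
  fx <- makeFeatures(n1 = 20, n2 = 20, p = 3, delta = 8, effectCols = 1,
                     seed = 20)
  tab <- compareClassifiers(fx, cvSpec(iterations = 40, seed = 21), svmSpec())
  expect_true(all(tab$meanAccuracy > 0.99))
})
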
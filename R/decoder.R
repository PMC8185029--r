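# Remembered/forgotten classification: RBF-SVM under repeated stratified
# random splits, optimal-candidate selection, label-permutation chance
# calibration, and LDA/FLDA comparison.

#' Gaussian RBF kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 * sigma^2))`, in (0, 1], strictly
#' decreasing in the distance.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma positive kernel width (default 2).
#' @return The kernel value.
#' @export
rbfKernel <- function(x, y, sigma = 2) {
  if (length(x) != length(y)) stop("shape error: x and y must have equal length")
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# per-training-fold standardization; zero-variance features left unscaled
.standardize <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       test = sweep(sweep(test, 2, mu), 2, s, "/"))
}

#' Fit an RBF-SVM and predict test labels
#'
#' Soft-margin C-classification SVM with kernel
#' `exp(-||x - y||^2 / (2 * sigma^2))` (passed to the solver as
#' `gamma = 1 / (2 * sigma^2)`). When `spec@standardize` is on,
#' per-feature mean and SD are estimated on the training fold only and
#' applied to both folds.
#'
#' @param trainX,trainY training feature matrix and labels (both classes
#'   must be present).
#' @param testX test feature matrix.
#' @param spec an [SVMSpec-class].
#' @return Factor of predicted labels for `testX`.
#' @export
fitPredictSvm <- function(trainX, trainY, testX, spec = svmSpec()) {
  stopifnot(is(spec, "SVMSpec"))
  trainY <- factor(trainY, levels = .classLevels)
  if (length(unique(trainY)) < 2L)
    stop("class-coverage error: training fold contains a single class")
  if (spec@standardize) {
    st <- .standardize(trainX, testX)
    trainX <- st$train; testX <- st$test
  }
  fit <- e1071::svm(x = trainX, y = trainY, scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * spec@sigma^2), cost = spec@cost)
  stats::predict(fit, testX)
}

# pooled-covariance Gaussian discriminant (equal priors) and Fisher
# discriminant; ridge 1e-6 * trace/d added when the pooled covariance is
# numerically singular
.pooledCovInv <- function(x1, x2) {
  d <- ncol(x1)
  s1 <- stats::cov(x1) * (nrow(x1) - 1)
  s2 <- stats::cov(x2) * (nrow(x2) - 1)
  S <- (s1 + s2) / (nrow(x1) + nrow(x2) - 2)
  tryCatch(solve(S), error = function(e)
    solve(S + diag(1e-6 * sum(diag(S)) / d, d)))
}

.fitPredictLda <- function(trainX, trainY, testX, fisher = FALSE) {
  x1 <- trainX[trainY == "remembered", , drop = FALSE]
  x2 <- trainX[trainY == "forgotten", , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  Sinv <- .pooledCovInv(x1, x2)
  if (fisher) {
    w <- Sinv %*% (mu1 - mu2)
    thr <- sum(w * (mu1 + mu2)) / 2
    pred <- ifelse(testX %*% w > thr, "remembered", "forgotten")
  } else {
    s1 <- testX %*% (Sinv %*% mu1) - 0.5 * sum(mu1 * (Sinv %*% mu1))
    s2 <- testX %*% (Sinv %*% mu2) - 0.5 * sum(mu2 * (Sinv %*% mu2))
    pred <- ifelse(s1 > s2, "remembered", "forgotten")
  }
  factor(pred, levels = .classLevels)
}

.fitPredict <- function(method, trainX, trainY, testX, svm) {
  switch(method,
         svm = fitPredictSvm(trainX, trainY, testX, svm),
         lda = .fitPredictLda(trainX, trainY, testX, fisher = FALSE),
         flda = .fitPredictLda(trainX, trainY, testX, fisher = TRUE),
         stop("unknown classifier: ", method))
}

# random train-fold index streams; stratified folds keep both classes in
# both folds
.makeSplits <- function(labels, cv) {
  n <- length(labels)
  withr::with_seed(cv@seed, {
    if (cv@stratified) {
      byClass <- lapply(.classLevels, function(l) which(labels == l))
      nTr <- vapply(byClass, function(idx) {
        k <- as.integer(roundHalfAway(cv@trainFraction * length(idx)))
        if (length(idx) < 2L || k < 1L || k >= length(idx))
          stop("split error: class too small to appear in both folds")
        k
      }, integer(1))
      lapply(seq_len(cv@iterations), function(i)
        sort(unlist(mapply(function(idx, k) sample(idx, k),
                           byClass, nTr, SIMPLIFY = FALSE))))
    } else {
      k <- as.integer(roundHalfAway(cv@trainFraction * n))
      lapply(seq_len(cv@iterations), function(i) sort(sample(n, k)))
    }
  })
}

# within-training-fold top-k ranking by |pooled t| with the deterministic
# tie-break (channel, band, window)
.rankTopK <- function(x, g, fi, k) {
  st <- .pooledT(x[g == "remembered", , drop = FALSE],
                 x[g == "forgotten", , drop = FALSE])
  ok <- which(!st$degenerate)
  if (!length(ok)) return(seq_len(min(k, ncol(x))))
  ord <- ok[order(-abs(st$t[ok]), fi$channel[ok], fi$bandIdx[ok],
                  fi$windowIdx[ok])]
  ord[seq_len(min(k, length(ord)))]
}

.cvRun <- function(x, g, fi, splits, svm, selection, method) {
  n <- nrow(x)
  acc <- bal <- numeric(length(splits))
  k <- if (is.null(selection)) 0L
       else if (!is.null(selection$k)) selection$k
       else ceiling(selection$fraction * ncol(x))
  for (i in seq_along(splits)) {
    tr <- splits[[i]]
    te <- setdiff(seq_len(n), tr)
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (!is.null(selection)) {
      keep <- .rankTopK(xtr, g[tr], fi, k)
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    pred <- .fitPredict(method, xtr, g[tr], xte, svm)
    truth <- g[te]
    acc[i] <- mean(pred == truth)
    perClass <- vapply(.classLevels[table(truth)[.classLevels] > 0],
                       function(l) mean(pred[truth == l] == l), numeric(1))
    bal[i] <- mean(perClass)
  }
  list(acc = acc, bal = bal,
       nTrain = length(splits[[1]]), nTest = n - length(splits[[1]]))
}

#' Repeated random-split cross-validation
#'
#' Evaluates a classifier over `cv@iterations` random train/test
#' partitions (default 80/20, stratified by outcome class so both classes
#' appear in both folds). Per-iteration test accuracy and balanced
#' accuracy (mean of per-class accuracies, the appropriate summary under
#' the 43/10-style trial imbalance) are recorded; the whole stream is
#' reproducible from `cv@seed`.
#'
#' @param features a [BandPowerFeatures-class] (typically already
#'   restricted to a [FeatureSelection-class] via [restrictFeatures()]).
#' @param cv a [CVSpec-class].
#' @param svm an [SVMSpec-class].
#' @param selection optional list with `fraction` or `k`: feature
#'   selection is then recomputed by |t| ranking inside each training fold
#'   (leakage-free mode). `NULL` uses the columns as given.
#' @param method `"svm"` (default), `"lda"`, or `"flda"`.
#' @return A [CVResult-class].
#' @export
repeatedSplitCv <- function(features, cv = cvSpec(), svm = svmSpec(),
                            selection = NULL, method = "svm") {
  stopifnot(is(features, "BandPowerFeatures"), is(cv, "CVSpec"),
            is(svm, "SVMSpec"))
  g <- features@labels
  if (min(table(g)) < 2L)
    stop("split error: need at least 2 trials per class")
  splits <- .makeSplits(g, cv)
  r <- .cvRun(features@matrix, g, features@featureIndex, splits, svm,
              selection, method)
  new("CVResult", accuracies = r$acc, balancedAccuracies = r$bal,
      nTrain = as.integer(r$nTrain), nTest = as.integer(r$nTest))
}

#' Select the optimal candidate feature set
#'
#' Runs [repeatedSplitCv()] on each candidate with the same split stream
#' and returns the candidate with the highest mean accuracy; ties are
#' broken by fewer features, then by lower first feature index.
#'
#' @param candidates list of [FeatureSelection-class] objects.
#' @param features the full [BandPowerFeatures-class].
#' @param cv a [CVSpec-class].
#' @param svm an [SVMSpec-class].
#' @return A list with `best` (index into `candidates`), `candidate`,
#'   `result` (its [CVResult-class]) and `meanAccuracies`.
#' @export
selectOptimal <- function(candidates, features, cv = cvSpec(),
                          svm = svmSpec()) {
  if (!length(candidates)) stop("input error: empty candidate list")
  results <- lapply(candidates, function(cand)
    repeatedSplitCv(restrictFeatures(features, cand), cv, svm))
  means <- vapply(results, meanAccuracy, numeric(1))
  sizes <- vapply(candidates, function(cand) length(cand@selected),
                  integer(1))
  firsts <- vapply(candidates, function(cand) min(cand@selected), integer(1))
  best <- order(-means, sizes, firsts)[1]
  list(best = best, candidate = candidates[[best]],
       result = results[[best]], meanAccuracies = means)
}

#' Label-permutation chance calibration
#'
#' Estimates the empirical null distribution of the cross-validated
#' accuracy by permuting outcome labels. Note the caveat for imbalanced
#' designs (e.g. 45/10): the null *plain* accuracy concentrates near the
#' majority-class proportion, not 50%; the null *balanced* accuracy
#' concentrates near 50%, which is why `statistic = "balanced"` is the
#' default.
#'
#' @param features a [BandPowerFeatures-class].
#' @param cv a [CVSpec-class] for the observed statistic.
#' @param svm an [SVMSpec-class].
#' @param nPermutations number of label permutations (>= 100 recommended).
#' @param selection optional within-fold selection, as in
#'   [repeatedSplitCv()].
#' @param statistic `"balanced"` (default) or `"accuracy"`.
#' @param permIterations CV iterations per permutation (default 100; the
#'   Monte-Carlo error of a null mean over 100 splits is a fraction of a
#'   percentage point).
#' @return A [PermutationResult-class]; the empirical p value is
#'   `(1 + #\{null >= observed\}) / (nPermutations + 1)`.
#' @export
permutationChance <- function(features, cv = cvSpec(), svm = svmSpec(),
                              nPermutations = 200L, selection = NULL,
                              statistic = c("balanced", "accuracy"),
                              permIterations = 100L) {
  stopifnot(is(features, "BandPowerFeatures"))
  statistic <- match.arg(statistic)
  observedResult <- repeatedSplitCv(features, cv, svm, selection)
  obs <- if (statistic == "balanced")
    mean(balancedAccuracies(observedResult)) else meanAccuracy(observedResult)
  permCv <- new("CVSpec", trainFraction = cv@trainFraction,
                iterations = as.integer(permIterations),
                stratified = cv@stratified, seed = cv@seed)
  perms <- withr::with_seed(stageSeed(cv@seed, "permute"), {
    lapply(seq_len(nPermutations), function(i) sample(length(features@labels)))
  })
  null <- vapply(perms, function(p) {
    shuffled <- features
    shuffled@labels <- features@labels[p]
    r <- repeatedSplitCv(shuffled, permCv, svm, selection)
    if (statistic == "balanced") mean(balancedAccuracies(r))
    else meanAccuracy(r)
  }, numeric(1))
  new("PermutationResult",
      nullAccuracies = null, observed = obs,
      pValue = (1 + sum(null >= obs)) / (nPermutations + 1),
      statistic = statistic)
}

#' Compare RBF-SVM, LDA and FLDA on identical splits
#'
#' LDA is the pooled-covariance Gaussian discriminant with equal priors;
#' FLDA is Fisher's direction `w = S_W^{-1} (mu1 - mu2)` with a midpoint
#' threshold (equivalent to LDA under equal priors). All three
#' classifiers see exactly the same split stream.
#'
#' @param features a [BandPowerFeatures-class].
#' @param cv a [CVSpec-class].
#' @param svm an [SVMSpec-class] (used by the SVM arm; standardization
#'   applies to the SVM only, the discriminants are affine-invariant).
#' @param selection optional within-fold selection, as in
#'   [repeatedSplitCv()].
#' @return A data.frame with mean, balanced-mean and SD of accuracy per
#'   method.
#' @export
compareClassifiers <- function(features, cv = cvSpec(), svm = svmSpec(),
                               selection = NULL) {
  stopifnot(is(features, "BandPowerFeatures"))
  g <- features@labels
  if (min(table(g)) < 2L)
    stop("split error: need at least 2 trials per class")
  splits <- .makeSplits(g, cv)
  methods <- c("svm", "lda", "flda")
  rows <- lapply(methods, function(m) {
    r <- .cvRun(features@matrix, g, features@featureIndex, splits, svm,
                selection, m)
    data.frame(method = m, meanAccuracy = mean(r$acc),
               meanBalancedAccuracy = mean(r$bal), sdAccuracy = stats::sd(r$acc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
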
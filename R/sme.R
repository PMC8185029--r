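# Subsequent-memory-effect statistics: per-feature pooled t maps,
# Bonferroni correction, top-fraction feature filtering, and a
# Monte-Carlo Lilliefors normality screen.

#' Per-feature two-sample t map (remembered vs forgotten)
#'
#' Pooled-variance (equal-variance) independent two-sample t statistic per
#' feature, with df = n1 + n2 - 2 and two-sided p. The sign convention is
#' positive t for remembered > forgotten. Features with zero pooled
#' variance are flagged degenerate (t undefined, excluded from ranking).
#'
#' @param features a [BandPowerFeatures-class]; both classes need >= 2
#'   trials.
#' @param alpha significance level stored with the map (default 0.05).
#' @return An [SMEMap-class].
#' @export
smeTMap <- function(features, alpha = 0.05) {
  stopifnot(is(features, "BandPowerFeatures"))
  x <- features@matrix
  g <- features@labels
  n1 <- sum(g == "remembered")
  n2 <- sum(g == "forgotten")
  if (n1 < 2L || n2 < 2L)
    stop("sample-size error: each class needs at least 2 trials")
  st <- .pooledT(x[g == "remembered", , drop = FALSE],
                 x[g == "forgotten", , drop = FALSE])
  new("SMEMap",
      tValues = st$t, pValues = st$p,
      adjustedP = rep(NA_real_, ncol(x)),
      df = st$df, alpha = alpha,
      correctedMask = rep(FALSE, ncol(x)),
      degenerate = st$degenerate,
      featureIndex = features@featureIndex)
}

# vectorized pooled two-sample t over columns
.pooledT <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  df <- n1 + n2 - 2
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(sweep(a, 2, m1)^2)
  v2 <- colSums(sweep(b, 2, m2)^2)
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- se == 0 | !is.finite(se)
  t <- (m1 - m2) / se
  t[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df, degenerate = degenerate)
}

#' Bonferroni correction of an SME map
#'
#' Adjusted p values `min(p * m, 1)`; the corrected mask uses the strict
#' inequality `p * m < alpha`.
#'
#' @param map an [SMEMap-class].
#' @param m number of comparisons in the family; must be at least the
#'   number of features in the map (defaults to exactly that).
#' @return The [SMEMap-class] with `adjustedP` and `correctedMask` filled.
#' @export
bonferroniCorrect <- function(map, m = length(map@pValues)) {
  stopifnot(is(map, "SMEMap"))
  if (m < length(map@pValues))
    stop("correction error: m must be >= the number of features tested")
  adj <- pmin(map@pValues * m, 1)
  map@adjustedP <- adj
  mask <- map@pValues * m < map@alpha
  mask[is.na(mask)] <- FALSE
  map@correctedMask <- mask
  map
}

#' Select the top fraction of features by |t|
#'
#' Features are ranked by decreasing absolute t; `ceiling(fraction * n)`
#' are retained. Ties are broken deterministically by lower channel index,
#' then lower band index, then lower window index. Degenerate features
#' never rank.
#'
#' @param map an [SMEMap-class].
#' @param fraction fraction in (0, 1] (default 0.2, the top 20%).
#' @param k optional explicit number of features, overriding `fraction`
#'   (e.g. a fixed top-10 rule).
#' @return A [FeatureSelection-class] with column indices in rank order.
#' @export
selectFeatures <- function(map, fraction = 0.2, k = NULL) {
  stopifnot(is(map, "SMEMap"))
  if (is.null(k)) {
    if (fraction <= 0 || fraction > 1)
      stop("domain error: fraction must be in (0, 1]")
    k <- ceiling(fraction * length(map@tValues))
  }
  ok <- which(!map@degenerate)
  if (!length(ok)) stop("no non-degenerate features to rank")
  fi <- map@featureIndex
  ord <- ok[order(-abs(map@tValues[ok]), fi$channel[ok],
                  fi$bandIdx[ok], fi$windowIdx[ok])]
  sel <- ord[seq_len(min(k, length(ord)))]
  new("FeatureSelection",
      selected = as.integer(sel),
      fraction = fraction,
      statistic = abs(map@tValues[sel]))
}

# Monte-Carlo null tables for the Lilliefors statistic, cached per
# (sample size, draws)
.lillieforsCache <- new.env(parent = emptyenv())

.lillieforsStat <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(Inf)   # degenerate sample
  z <- sort((x - mean(x)) / s)
  F <- stats::pnorm(z)
  max(seq_len(n) / n - F, F - (seq_len(n) - 1) / n)
}

.lillieforsNull <- function(n, draws = 10000L) {
  key <- paste0("n", n, "_", draws)
  if (!is.null(.lillieforsCache[[key]])) return(.lillieforsCache[[key]])
  null <- withr::with_seed(n * 7919L + draws, {
    vapply(seq_len(draws),
           function(i) .lillieforsStat(stats::rnorm(n)), numeric(1))
  })
  null <- sort(null)
  .lillieforsCache[[key]] <- null
  null
}

#' Lilliefors normality test (Monte-Carlo null)
#'
#' Kolmogorov-Smirnov test against a normal with estimated mean and SD.
#' The null distribution of the statistic is obtained by Monte-Carlo
#' simulation at the observed sample size (cached), rather than from an
#' analytic table, so any n >= 4 is supported.
#'
#' @param x numeric sample, length >= 4.
#' @param draws Monte-Carlo draws for the null table (default 10,000).
#' @return A list with `statistic` and `p.value`. A constant sample is
#'   degenerate and returns p = 0.
#' @export
lillieforsTest <- function(x, draws = 10000L) {
  n <- length(x)
  if (n < 4L) stop("sample-size error: need at least 4 observations")
  D <- .lillieforsStat(x)
  if (!is.finite(D)) return(list(statistic = Inf, p.value = 0))
  null <- .lillieforsNull(n, draws)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  list(statistic = D, p.value = p)
}

#' Per-feature, per-class normality screen
#'
#' Applies [lillieforsTest()] to each feature within each outcome class
#' and flags features for which either class departs from normality at
#' `p <= alpha` (default 0.01). Degenerate (constant) samples are flagged.
#'
#' @param features a [BandPowerFeatures-class] with >= 4 trials per class.
#' @param alpha flagging level (default 0.01).
#' @param draws Monte-Carlo draws per null table.
#' @return A data.frame with per-feature p values for both classes and a
#'   logical `flagged` column.
#' @export
normalityCheck <- function(features, alpha = 0.01, draws = 10000L) {
  stopifnot(is(features, "BandPowerFeatures"))
  x <- features@matrix
  g <- features@labels
  if (min(table(g)) < 4L)
    stop("sample-size error: need at least 4 observations per class")
  pRem <- apply(x[g == "remembered", , drop = FALSE], 2,
                function(v) lillieforsTest(v, draws)$p.value)
  pFor <- apply(x[g == "forgotten", , drop = FALSE], 2,
                function(v) lillieforsTest(v, draws)$p.value)
  data.frame(feature = seq_len(ncol(x)),
             pRemembered = pRem, pForgotten = pFor,
             flagged = pRem <= alpha | pFor <= alpha)
}

#' Export an SME map as a t-table
#'
#' Writes a CSV shaped like a per-feature t-table: time window, band,
#' channel, t value, two-sided p, and a significance marker (`**` p <
#' 0.01, `*` p < 0.05 after Bonferroni when available, otherwise
#' uncorrected).
#'
#' @param map an [SMEMap-class].
#' @param path output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
writeSMETable <- function(map, path) {
  stopifnot(is(map, "SMEMap"))
  p <- if (all(is.na(map@adjustedP))) map@pValues else map@adjustedP
  marker <- ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                   ifelse(p < 0.05, "*", "")))
  out <- data.frame(window = map@featureIndex$window,
                    band = map@featureIndex$band,
                    channel = map@featureIndex$channel,
                    t = map@tValues, p = map@pValues,
                    adjustedP = map@adjustedP,
                    significance = marker,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
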
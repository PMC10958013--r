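#' Bayesian binomial credible interval
#'
#' Equal-tailed credible interval for a binomial proportion under a
#' uniform prior: the posterior is Beta(k + 1, n - k + 1). With no data
#' the interval is simply the prior's quantiles.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param level credible level (default 0.95).
#' @return List with \code{lower}, \code{upper}, \code{level}.
#' @export
bayesianBinomialCI <- function(k, n, level = 0.95) {
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    nsError("domainError", "need 0 <= k <= n")
  }
  alpha <- (1 - level) / 2
  list(lower = qbeta(alpha, k + 1, n - k + 1),
       upper = qbeta(1 - alpha, k + 1, n - k + 1),
       level = level)
}

#' Two-alternative forced-choice comparison curve
#'
#' Replays the classic relative-numerosity task: on each trial a test
#' image and a reference image are embedded and the model answers
#' "more" when the test image's perceived numerosity is larger (ties
#' answered "more" with probability 1/2). Returns, per test count, the
#' proportion of "more" responses with a 95% Bayesian binomial interval.
#'
#' @param line a calibrated [NumberLine-class].
#' @param model a trained [SiameseModel-class].
#' @param imageSet an [ImageSet-class] covering the reference and test
#'   counts.
#' @param referenceCount the reference numerosity (default 16).
#' @param testCounts integer vector of test numerosities.
#' @param trials sampled image pairs per test count (default 200).
#' @return Data frame with columns \code{testCount},
#'   \code{proportionMore}, \code{n}, \code{lower}, \code{upper}.
#' @export
comparisonCurve <- function(line, model, imageSet, referenceCount = 16L,
                            testCounts = seq(8L, 30L, 2L), trials = 200L) {
  counts <- imageSet@counts
  need <- c(referenceCount, testCounts)
  missing <- setdiff(need, counts)
  if (length(missing)) {
    nsError("missingCountError",
            sprintf("image set lacks counts: %s",
                    paste(missing, collapse = ", ")))
  }
  perceived <- perceivedNumerosity(line, embedImages(model, imageSet))
  refIdx <- which(counts == referenceCount)
  out <- do.call(rbind, lapply(testCounts, function(k) {
    tIdx <- which(counts == k)
    ti <- sample(tIdx, trials, replace = TRUE)
    ri <- sample(refIdx, trials, replace = TRUE)
    more <- perceived[ti] > perceived[ri]
    tie <- perceived[ti] == perceived[ri]
    if (any(tie)) more[tie] <- runif(sum(tie)) < 0.5
    ci <- bayesianBinomialCI(sum(more), trials)
    data.frame(testCount = k, proportionMore = mean(more), n = trials,
               lower = ci$lower, upper = ci$upper)
  }))
  out
}

#' Absolute numerosity estimation report
#'
#' Per-count distribution of perceived numerosity (mean, standard
#' deviation, relative error), the overall mean absolute relative error
#' over counts >= 1, and a power-law fit of perceived against true
#' count.
#'
#' @param line a calibrated [NumberLine-class].
#' @param model a trained [SiameseModel-class].
#' @param imageSet an [ImageSet-class].
#' @return List with \code{perCount} (data frame), \code{meanAbsRelError},
#'   and \code{powerLaw} (see [fitPowerLaw()]).
#' @export
estimationReport <- function(line, model, imageSet) {
  counts <- imageSet@counts
  perceived <- perceivedNumerosity(line, embedImages(model, imageSet))
  perCount <- do.call(rbind, lapply(sort(unique(counts)), function(k) {
    v <- perceived[counts == k]
    data.frame(count = k, mean = mean(v), sd = sd(v),
               relError = if (k > 0) mean(abs(v - k)) / k else NA_real_,
               n = length(v))
  }))
  pos <- counts >= 1
  mare <- mean(abs(perceived[pos] - counts[pos]) / counts[pos])
  pl <- tryCatch(fitPowerLaw(counts, perceived), numerosenseError = function(e) NULL)
  list(perCount = perCount, meanAbsRelError = mare, powerLaw = pl,
       perceived = perceived)
}
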
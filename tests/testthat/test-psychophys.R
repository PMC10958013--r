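test_that("binomial credible intervals match the uniform-prior posterior", {
  # no data: the interval is the prior's quantiles
  ci0 <- bayesianBinomialCI(0, 0)
  expect_equal(ci0$lower, 0.025)
  expect_equal(ci0$upper, 0.975)
  # k = 0, n = 299: upper bound frozen from an independent quadrature of
  # the Beta(1, 300) density (301 * ... integral solved by uniroot)
  ci <- bayesianBinomialCI(0, 299)
  expect_equal(ci$upper, 0.012221, tolerance = 1e-4)
  expect_equal(ci$lower, qbeta(0.025, 1, 300))
  # symmetric data give an interval symmetric about 1/2
  ci5 <- bayesianBinomialCI(150, 300)
  expect_equal(ci5$lower + ci5$upper, 1, tolerance = 1e-6)
  expect_error(bayesianBinomialCI(5, 3), class = "domainError")
  expect_error(bayesianBinomialCI(-1, 3), class = "domainError")
})

test_that("interval coverage is near nominal in simulation", {
  set.seed(12)
  for (p in c(0.05, 0.5, 0.95)) {
    k <- rbinom(1000, 200, p)
    ci <- bayesianBinomialCI(k, 200)
    cover <- mean(ci$lower <= p & p <= ci$upper)
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.97)
  }
})

test_that("2AFC proportion at the reference count is one half by exchangeability", {
  set.seed(13)
  cfg <- sceneConfig("A", "desk", imageSize = 48L, sizeRange = c(4, 4),
                     margin = 1)
  model <- calibrateModel(buildModel(
    modelConfig(inputSize = 48L, frozenChannels = 4L, trainChannels = 8L,
                fcHidden = 32L, clfHidden = 32L), seed = 14), cfg)
  bs <- balancedImageSet(cfg, c(4L, 16L, 24L), 40L, seed = 15)
  line <- new("NumberLine", origin = c(0, 0), direction = c(1, 0), unit = 1,
              zeroCluster = 1L, oneCluster = 2L)
  curve <- comparisonCurve(line, model, bs, referenceCount = 16L,
                           testCounts = c(4L, 16L, 24L), trials = 400L)
  at16 <- curve$proportionMore[curve$testCount == 16L]
  expect_gt(at16, 0.5 - 4 * sqrt(0.25 / 400))
  expect_lt(at16, 0.5 + 4 * sqrt(0.25 / 400))
  expect_error(
    comparisonCurve(line, model, bs, referenceCount = 9L, trials = 10L),
    class = "missingCountError")
})

test_that("estimation report is exact for an oracle line on exact embeddings", {
  # images embedded exactly at count * unit along a line
  counts <- rep(0:10, each = 5L)
  emb <- cbind(counts * 2.5, 0)
  line <- new("NumberLine", origin = c(0, 0), direction = c(1, 0), unit = 2.5,
              zeroCluster = 1L, oneCluster = 2L)
  perceived <- perceivedNumerosity(line, emb)
  expect_equal(perceived, counts)
  pl <- fitPowerLaw(counts, perceived)
  expect_equal(pl$b, 1, tolerance = 1e-10)
  expect_equal(pl$a, 1, tolerance = 1e-10)
})
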
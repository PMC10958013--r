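## fixtures: embeddings laid out exactly on a number line, with a
## degenerate zero cluster (as produced by identical empty images)

lineFixture <- function(nPer = 30L, counts = 0:6, unit = 3, noise = 0.05,
                        seed = 30) {
  set.seed(seed)
  truth <- rep(counts, each = nPer)
  emb <- cbind(truth * unit, 0)
  jitter <- cbind(rnorm(length(truth), 0, noise), rnorm(length(truth), 0, noise))
  jitter[truth == 0, ] <- 0  # empty scenes are identical
  emb <- emb + jitter
  labels <- as.integer(factor(truth))
  list(emb = emb, truth = truth,
       clustering = new("NumberClustering", labels = labels,
                        minClusterSize = 10L,
                        nClusters = length(unique(labels))))
}

test_that("confusion matrix and subitization limit follow their definitions", {
  fx <- lineFixture()
  nc <- numberConfusion(fx$clustering, fx$truth)
  expect_true(all(nc$matrix[cbind(seq_len(7), seq_len(7))] == 30L))
  expect_equal(sum(nc$matrix), length(fx$truth))
  expect_equal(nc$purity, setNames(rep(1, 7), rownames(nc$matrix)))
  expect_equal(nc$subitizationLimit, 6L)

  # merge counts 5 and 6 into one cluster: limit drops to 4
  merged <- fx$clustering@labels
  merged[merged == 7L] <- 6L
  nc2 <- numberConfusion(merged, fx$truth)
  expect_lt(min(nc2$purity), 1)
  expect_equal(nc2$subitizationLimit, 4L)

  expect_error(numberConfusion(fx$clustering, fx$truth[-1]),
               class = "lengthMismatchError")
})

test_that("the zero cluster is found by minimal spread, ties are errors", {
  fx <- lineFixture()
  expect_equal(findZeroCluster(fx$emb, fx$clustering), 1L)
  # adversarial: two zero-variance clusters tie
  emb <- rbind(matrix(0, 20, 2), matrix(5, 20, 2))
  cl <- new("NumberClustering", labels = rep(1:2, each = 20L),
            minClusterSize = 5L, nClusters = 2L)
  expect_error(findZeroCluster(emb, cl), class = "ambiguityError")
})

test_that("line calibration recovers origin and unit and is scale invariant", {
  fx <- lineFixture(noise = 0.02)
  line <- calibrateLine(fx$emb, fx$clustering)
  expect_equal(line@zeroCluster, 1L)
  expect_equal(line@oneCluster, 2L)
  expect_equal(line@origin, c(0, 0), tolerance = 1e-8)
  expect_equal(line@unit, 3, tolerance = 0.05)
  perceived <- perceivedNumerosity(line, fx$emb)
  expect_equal(perceived, fx$truth, tolerance = 0.05)
  # the one cluster averages exactly 1 under the cross-pair unit with a
  # degenerate zero cluster
  expect_equal(mean(perceived[fx$truth == 1]), 1, tolerance = 1e-10)

  line10 <- calibrateLine(fx$emb * 10, fx$clustering)
  expect_equal(perceivedNumerosity(line10, fx$emb * 10), perceived,
               tolerance = 1e-10)

  oneCl <- new("NumberClustering", labels = rep(1L, nrow(fx$emb)),
               minClusterSize = 10L, nClusters = 1L)
  expect_error(calibrateLine(fx$emb, oneCl), class = "missingClusterError")
})

test_that("perceived numerosity is the signed origin distance in units", {
  line <- new("NumberLine", origin = c(1, 1), direction = c(1, 0) ,
              unit = 2, zeroCluster = 1L, oneCluster = 2L)
  expect_equal(perceivedNumerosity(line, c(1, 1)), 0)
  expect_equal(perceivedNumerosity(line, c(3, 1)), 1)
  expect_equal(perceivedNumerosity(line, c(-3, 1)), -2)  # behind the origin
})

test_that("rank-1 approximation error matches a brute-force reconstruction", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    d <- sample(2:8, 1)
    X <- matrix(rnorm(n * d), n, d) %*% diag(runif(d, 0.2, 3))
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc)
    rank1 <- sv$d[1] * sv$u[, 1, drop = FALSE] %*% t(sv$v[, 1, drop = FALSE])
    oracle <- sqrt(sum((Xc - rank1)^2) / sum(Xc^2))
    expect_equal(linearApproximationError(X), oracle, tolerance = 1e-10)
  }
})

test_that("rank-1 error is 0 on a line and sqrt(1/2) on an isotropic cloud", {
  t <- seq(-5, 5, length.out = 50)
  X <- cbind(1 + 2 * t, 3 - t, t)
  expect_equal(linearApproximationError(X), 0, tolerance = 1e-12)
  set.seed(32)
  G <- matrix(rnorm(2e5), ncol = 2)
  expect_equal(linearApproximationError(G), sqrt(0.5), tolerance = 1e-2)
  expect_error(linearApproximationError(matrix(1, 5, 2)),
               class = "degenerateError")
})

test_that("action links recover the cluster order, shuffles do not", {
  set.seed(33)
  cfg <- tinySceneA(maxObjects = 3L)
  seqs <- lapply(1:4, function(i) simulateSequence(cfg, 40))
  truth <- unlist(lapply(seqs, function(s) s@counts))
  clustering <- new("NumberClustering", labels = truth + 1L,
                    minClusterSize = 5L, nClusters = 4L)
  g <- clusterGraphFromActions(seqs, clustering, zeroCluster = 1L)
  expect_equal(g@order, 1:4)
  expect_true(all(g@edges$agreement == 1))

  # shuffled actions destroy the order: either an explicit cycle/conflict
  # error, or the conflicting edges fall below the agreement threshold and
  # no full chain survives
  shuffled <- lapply(seqs, function(s) {
    s@actions <- sample(s@actions)
    s
  })
  res <- tryCatch(clusterGraphFromActions(shuffled, clustering, 1L),
                  numerosenseError = function(e) e)
  if (is(res, "ClusterGraph")) {
    expect_lt(length(res@order), 4L)
  } else {
    expect_s3_class(res, "numerosenseError")
  }
})

test_that("power-law fits recover exact log-linear data", {
  n <- rep(1:20, each = 3)
  y <- 2 * n^0.8
  fit <- fitPowerLaw(n, y)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.8, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-12)
  expect_error(fitPowerLaw(rep(1:2, 5), rep(1:2, 5)),
               class = "insufficientDataError")
})
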
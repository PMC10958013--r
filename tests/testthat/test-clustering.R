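## density clustering on fixtures with known ground truth

blobs <- function(centers, n, spread, seed) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n, centers[i, 1], spread), rnorm(n, centers[i, 2], spread))
  }))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n))
}

test_that("well-separated blobs are recovered exactly", {
  b <- blobs(rbind(c(0, 0), c(20, 0), c(0, 20)), 200L, 1, seed = 20)
  cl <- clusterEmbeddings(b$X, minClusterSize = 50L)
  expect_equal(cl@nClusters, 3L)
  lb <- clusterLabels(cl)
  expect_false(anyNA(lb))
  # labels are a relabeling of the truth: zero misassignments
  expect_equal(length(unique(paste(lb, b$truth))), 3L)
})

test_that("identical points collapse to a single cluster", {
  X <- matrix(1.5, nrow = 120, ncol = 2)
  cl <- clusterEmbeddings(X, minClusterSize = 30L)
  expect_equal(cl@nClusters, 1L)
  expect_false(anyNA(clusterLabels(cl)))
})

test_that("sparse background points are excluded as outliers", {
  b <- blobs(rbind(c(0, 0), c(30, 0)), 150L, 1, seed = 21)
  set.seed(22)
  noise <- cbind(runif(20, -10, 40), runif(20, 5, 40))
  X <- rbind(b$X, noise)
  cl <- clusterEmbeddings(X, minClusterSize = 50L)
  expect_equal(cl@nClusters, 2L)
  lb <- clusterLabels(cl)
  expect_false(anyNA(lb[1:300]))
  expect_gt(sum(is.na(lb[301:320])), 10)
})

test_that("too few points is an error", {
  expect_error(clusterEmbeddings(matrix(rnorm(20), 10), minClusterSize = 90L),
               class = "tooFewPointsError")
})

test_that("small-cluster structure is stable over a range of minimum sizes", {
  b <- blobs(rbind(c(0, 0), c(12, 0), c(24, 0), c(40, 0)), 120L, 0.8,
             seed = 23)
  ref <- NULL
  for (m in c(20L, 60L, 100L)) {
    cl <- clusterEmbeddings(b$X, minClusterSize = m)
    expect_equal(cl@nClusters, 4L)
    part <- split(seq_along(b$truth), clusterLabels(cl))
    sig <- lapply(part[order(vapply(part, min, 1L))], identity)
    if (is.null(ref)) ref <- sig else expect_identical(sig, ref)
  }
})
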
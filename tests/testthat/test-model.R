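test_that("configs are validated", {
  expect_error(modelConfig(embeddingDim = 0L), class = "configError")
  expect_error(modelConfig(frontend = "file"), class = "configError")
  expect_error(sceneConfig("A", maxObjects = 0L))
  tc <- trainingConfig()
  expect_equal(tc$epochs * tc$minibatches * tc$actionsPerMinibatch, 162000L)
})

test_that("the Siamese branches share weights exactly", {
  set.seed(40)
  cfg <- tinySceneA()
  m <- calibrateModel(buildModel(tinyModelConfig(), seed = 41), cfg)
  img <- renderScene(data.frame(x = 16, y = 16, size = 4, contrast = 1), cfg)
  z1 <- embedImages(m, img)
  z2 <- embedImages(m, img)
  expect_identical(z1, z2)
  expect_equal(ncol(z1), 2L)
  m8 <- buildModel(tinyModelConfig(embeddingDim = 8L), seed = 41)
  expect_equal(ncol(embedImages(m8, img)), 8L)
})

test_that("gradients match finite differences on a tiny network", {
  ns <- asNamespace("numerosense")
  set.seed(42)
  cfg <- modelConfig(inputSize = 16L, frozenLayers = 1L, frozenChannels = 2L,
                     trainableConvLayers = 2L, trainChannels = 3L,
                     fcLayers = 2L, fcHidden = 6L, clfLayers = 2L,
                     clfHidden = 4L)
  m <- buildModel(cfg, seed = 43)
  N <- 4L
  X <- array(runif(16 * 16 * (N + 1)), c(16, 16, N + 1))
  labels <- sample(1:3, N, replace = TRUE)
  mode <- m@config$clfInput
  lossOf <- function(ext, clf) {
    Z <- ns$stackForward(ext, X)$out
    logits <- ns$stackForward(
      clf, ns$pairFeatures(mode, Z[1:N, , drop = FALSE],
                           Z[2:(N + 1), , drop = FALSE]))$out
    ns$nllLoss(ns$logSoftmax(logits), labels)
  }
  fwd <- ns$stackForward(m@extractor, X, cache = TRUE)
  Z <- fwd$out
  cf <- ns$stackForward(m@classifier,
                        ns$pairFeatures(mode, Z[1:N, , drop = FALSE],
                                        Z[2:(N + 1), , drop = FALSE]),
                        cache = TRUE)
  dl <- ns$nllGrad(ns$logSoftmax(cf$out), labels)
  cb <- ns$stackBackward(m@classifier, cf$caches, dl, N, needInputGrad = TRUE)
  pg <- ns$pairFeaturesBackward(mode, cb$dIn, 2L)
  dZ <- matrix(0, N + 1L, 2L)
  dZ[1:N, ] <- pg$before
  dZ[2:(N + 1), ] <- dZ[2:(N + 1), ] + pg$after
  eb <- ns$stackBackward(m@extractor, fwd$caches, dZ, N + 1L)
  eps <- 1e-6
  checkSome <- function(layers, grads, other, isExt) {
    for (li in seq_along(layers)) {
      g <- grads[[li]]
      if (is.null(g)) next
      set.seed(li)
      for (r in 1:4) {
        i <- sample(nrow(layers[[li]]$W), 1)
        j <- sample(ncol(layers[[li]]$W), 1)
        lp <- layers; lp[[li]]$W[i, j] <- lp[[li]]$W[i, j] + eps
        lm <- layers; lm[[li]]$W[i, j] <- lm[[li]]$W[i, j] - eps
        num <- if (isExt) (lossOf(lp, other) - lossOf(lm, other)) / (2 * eps)
               else (lossOf(other, lp) - lossOf(other, lm)) / (2 * eps)
        expect_equal(g$W[i, j], num, tolerance = 1e-5)
      }
    }
  }
  checkSome(m@extractor, eb$grads, m@classifier, TRUE)
  checkSome(m@classifier, cb$grads, m@extractor, FALSE)
})

test_that("frozen front-end parameters never change during training", {
  cfg <- tinySceneA()
  m0 <- calibrateModel(buildModel(tinyModelConfig(), seed = 44), cfg)
  set.seed(45)
  m1 <- trainModel(m0, cfg, tinyTraining(1L))
  frozenSum <- function(m) {
    sum(vapply(m@extractor, function(l) {
      if (isTRUE(l$frozen)) sum(l$W) + sum(l$b) else 0
    }, numeric(1)))
  }
  expect_identical(frozenSum(m0), frozenSum(m1))
  # trainable parameters did change
  expect_false(identical(m0@extractor[[length(m0@extractor)]]$W,
                         m1@extractor[[length(m1@extractor)]]$W))
})

test_that("training consumes exactly the scheduled number of pairs", {
  cfg <- tinySceneA()
  m <- buildModel(tinyModelConfig(), seed = 46)
  tr <- tinyTraining(2L)
  m <- trainModel(m, cfg, tr, seed = 47)
  expect_identical(attr(m@history, "pairsConsumed"),
                   tr$epochs * tr$minibatches * tr$actionsPerMinibatch)
  expect_equal(nrow(m@history), 2L)
})

test_that("an untrained model predicts at chance on random pairs", {
  set.seed(48)
  cfg <- tinySceneA()
  m <- calibrateModel(buildModel(tinyModelConfig(), seed = 49), cfg)
  sq <- simulateSequence(cfg, 300)
  nP <- length(sq@actions)
  pred <- predictAction(m, sq@images[, , 1:nP], sq@images[, , 2:(nP + 1)])
  expect_equal(rowSums(pred$probabilities), rep(1, nP), tolerance = 1e-6)
  # an untrained model has no signal: its argmax collapses to a near-
  # constant class, so accuracy lands near that class's base rate
  acc <- mean(pred$action == sq@actions)
  expect_gt(acc, 0.1)
  expect_lt(acc, 0.55)
})

test_that("models survive a save/load round trip bit for bit", {
  cfg <- tinySceneA()
  m <- trainModel(buildModel(tinyModelConfig(), seed = 50), cfg,
                  tinyTraining(1L), seed = 51)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  sq <- simulateSequence(cfg, 10, seed = 52)
  expect_identical(embedImages(m, sq), embedImages(m2, sq))
})

test_that("per-count error evaluation matches a hand recount", {
  set.seed(53)
  cfg <- tinySceneA()
  m <- calibrateModel(buildModel(tinyModelConfig(), seed = 54), cfg)
  seqs <- actionTestSet(cfg, nSequences = 2L, nActions = 50L)
  tab <- actionErrorByCount(m, seqs)
  # brute-force recount
  before <- unlist(lapply(seqs, function(s) s@counts[seq_along(s@actions)]))
  wrong <- unlist(lapply(seqs, function(s) {
    nP <- length(s@actions)
    pred <- predictAction(m, s@images[, , 1:nP], s@images[, , 2:(nP + 1)])$action
    pred != s@actions
  }))
  for (r in seq_len(nrow(tab))) {
    idx <- before == tab$count[r]
    expect_equal(tab$n[r], sum(idx))
    expect_equal(tab$error[r], sum(wrong[idx]) / sum(idx))
  }
  # intervals are non-degenerate and ordered (the equal-tailed interval
  # need not contain a boundary MLE of 0 or 1)
  expect_true(all(tab$lower < tab$upper))
})

test_that("image size mismatches are shape errors", {
  m <- buildModel(tinyModelConfig())
  expect_error(embedImages(m, array(0, c(64, 64, 2))), class = "shapeError")
})
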
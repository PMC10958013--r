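#' Architecture settings for the Siamese perception network
#'
#' The feature extractor is a convolutional stack followed by fully
#' connected layers, ending in a low-dimensional embedding. Its first
#' \code{frozenLayers} convolutional layers form a fixed front-end that
#' is never updated during training: by default their weights are drawn
#' once from a seeded He-normal initialization (random convolutional
#' features are known to carry quantity-sensitive units); a
#' user-supplied frozen front-end can be loaded from a file instead. The
#' remaining \code{trainableConvLayers} convolutional layers and
#' \code{fcLayers} fully connected layers are trained. The action
#' classifier is a \code{clfLayers}-layer fully connected network over
#' the concatenated pair of embeddings with a 3-way log-softmax output
#' (put/take/shake).
#'
#' @param embeddingDim dimension of the embedding (1--256; default 2).
#' @param inputSize image side in pixels (must match the scene config).
#' @param frontend \code{"random"} (seeded random frozen convolutions) or
#'   \code{"file"} (load frozen conv weights from \code{frontendPath},
#'   an RDS file holding a list of conv layers).
#' @param frontendPath path used when \code{frontend = "file"}.
#' @param frozenLayers,frozenChannels frozen front-end depth and width.
#' @param trainableConvLayers,trainChannels trainable conv depth and width.
#' @param fcLayers,fcHidden fully connected head depth and hidden width.
#' @param clfLayers,clfHidden classifier depth and hidden width.
#' @param pooling how the last feature map feeds the fully connected
#'   head: \code{"gap"} (global average pooling, translation invariant)
#'   or \code{"flatten"} (position-specific weights).
#' @return A named list of validated settings.
#' @export
modelConfig <- function(embeddingDim = 2L, inputSize = 96L,
                        frontend = c("random", "file"), frontendPath = NULL,
                        frozenLayers = 3L, frozenChannels = 8L,
                        trainableConvLayers = 4L, trainChannels = 32L,
                        fcLayers = 2L, fcHidden = 256L,
                        clfLayers = 2L, clfHidden = 16L,
                        pooling = c("gap", "flatten"),
                        poolStages = frozenLayers, poolKernel = 2L,
                        fullResStages = 0L,
                        clfInput = c("both", "diff", "concat")) {
  frontend <- match.arg(frontend)
  pooling <- match.arg(pooling)
  if (embeddingDim < 1L || embeddingDim > 256L) {
    nsError("configError", "embeddingDim must be between 1 and 256")
  }
  if (frontend == "file" && is.null(frontendPath)) {
    nsError("configError", "frontend = 'file' needs frontendPath")
  }
  list(embeddingDim = as.integer(embeddingDim),
       inputSize = as.integer(inputSize), frontend = frontend,
       frontendPath = frontendPath, frozenLayers = as.integer(frozenLayers),
       frozenChannels = as.integer(frozenChannels),
       trainableConvLayers = as.integer(trainableConvLayers),
       trainChannels = as.integer(trainChannels),
       fcLayers = as.integer(fcLayers), fcHidden = as.integer(fcHidden),
       clfLayers = as.integer(clfLayers), clfHidden = as.integer(clfHidden),
       pooling = pooling, poolStages = as.integer(poolStages),
       poolKernel = as.integer(poolKernel),
       fullResStages = as.integer(fullResStages),
       clfInput = match.arg(clfInput))
}

#' Training schedule
#'
#' The default schedule follows the study conditions: 30 epochs of 30
#' mini-batches, each mini-batch a fresh episode of 180 actions, i.e.
#' 30 x 30 x 180 = 162,000 distinct image pairs, optimized with Adam at
#' learning rate 1e-4 under a 3-class negative log-likelihood loss. The
#' desk profile (see [deskProfile()]) keeps the same total pair volume
#' but splits each epoch into 90 mini-batches of 60-action episodes.
#'
#' @param learningRate Adam learning rate.
#' @param epochs,minibatches,actionsPerMinibatch schedule; total pairs
#'   consumed is their product.
#' @param holdoutSequences episodes held out to track accuracy per epoch.
#' @return A named list.
#' @export
trainingConfig <- function(learningRate = 1e-4, epochs = 30L,
                           minibatches = 30L, actionsPerMinibatch = 180L,
                           holdoutSequences = 2L) {
  list(learningRate = learningRate, epochs = as.integer(epochs),
       minibatches = as.integer(minibatches),
       actionsPerMinibatch = as.integer(actionsPerMinibatch),
       holdoutSequences = as.integer(holdoutSequences))
}

## layer plan: each frozen layer is a stride-1 conv followed by 2x2
## average pooling (halving the spatial size additively); the trainable
## conv layers run at stride 1 on the resulting map
extractorPlan <- function(cfg) {
  cin <- c(1L, rep(cfg$frozenChannels, cfg$frozenLayers - 1L),
           cfg$frozenChannels,
           rep(cfg$trainChannels, cfg$trainableConvLayers - 1L))
  cout <- c(rep(cfg$frozenChannels, cfg$frozenLayers),
            rep(cfg$trainChannels, cfg$trainableConvLayers))
  frozen <- c(rep(TRUE, cfg$frozenLayers), rep(FALSE, cfg$trainableConvLayers))
  list(cin = cin, cout = cout, frozen = frozen)
}

#' Build an untrained Siamese model
#'
#' One shared feature extractor is used for both images of a pair, so the
#' two branches are identical by construction. Weights are drawn from the
#' current RNG state (use \code{seed} for reproducibility).
#'
#' @param config a [modelConfig()] list.
#' @param seed optional integer seed.
#' @return A [SiameseModel-class].
#' @export
buildModel <- function(config = modelConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- extractorPlan(config)
  extractor <- list()
  H <- config$inputSize
  nPool <- config$poolStages %||% config$frozenLayers
  pk <- config$poolKernel %||% 2L
  fullRes <- config$fullResStages %||% 1L
  for (i in seq_along(plan$cin)) {
    # frozen blocks downsample by 2x2 average pooling (alias-free). The
    # first `fullResStages` blocks convolve at full resolution before
    # pooling, so fine edges are encoded sharply; later blocks pool
    # first, keeping the heavier convolutions off large grids.
    poolHere <- plan$frozen[i] && i <= nPool
    if (poolHere && i > fullRes) {
      extractor[[length(extractor) + 1L]] <- mkAvgPool(plan$cin[i], pk)
      H <- convOutSize(H, pk, 2L, if (pk == 3L) 1L else 0L)
    }
    extractor[[length(extractor) + 1L]] <-
      mkConv(plan$cin[i], plan$cout[i], k = 3L, stride = 1L, pad = 1L,
             frozen = plan$frozen[i])
    if (poolHere && i <= fullRes) {
      extractor[[length(extractor) + 1L]] <- mkAvgPool(plan$cout[i], pk)
      H <- convOutSize(H, pk, 2L, if (pk == 3L) 1L else 0L)
    }
  }
  if (config$frontend == "file") {
    frozenW <- readRDS(config$frontendPath)
    convIdx <- which(vapply(extractor, function(l) {
      l$type == "conv" && isTRUE(l$frozen) && !isTRUE(l$pool)
    }, logical(1)))
    stopifnot(length(frozenW) >= length(convIdx))
    for (j in seq_along(convIdx)) {
      i <- convIdx[j]
      stopifnot(identical(dim(frozenW[[j]]$W), dim(extractor[[i]]$W)))
      extractor[[i]]$W <- frozenW[[j]]$W
      extractor[[i]]$b <- frozenW[[j]]$b
    }
  }
  pool <- config$pooling %||% "gap"
  extractor[[length(extractor) + 1L]] <- list(type = pool, frozen = FALSE)
  flat <- if (pool == "gap") config$trainChannels else
    H * H * config$trainChannels
  widths <- c(flat, rep(config$fcHidden, config$fcLayers - 1L),
              config$embeddingDim)
  for (i in seq_len(config$fcLayers)) {
    act <- if (i == config$fcLayers) "linear" else "relu"
    extractor[[length(extractor) + 1L]] <- mkFc(widths[i], widths[i + 1L], act)
  }
  cwidths <- c(clfInputWidth(config$clfInput %||% "diff", config$embeddingDim),
               rep(config$clfHidden, config$clfLayers - 1L), 3L)
  classifier <- list()
  for (i in seq_len(config$clfLayers)) {
    act <- if (i == config$clfLayers) "linear" else "relu"
    classifier[[i]] <- mkFc(cwidths[i], cwidths[i + 1L], act)
  }
  new("SiameseModel", config = config, extractor = extractor,
      classifier = classifier,
      history = data.frame(epoch = integer(), loss = numeric(),
                           holdoutAccuracy = numeric()),
      trained = FALSE)
}

actionToInt <- function(a) match(a, c("P", "T", "S"))

#' Calibrate layer scales on the scene statistics
#'
#' Layer-sequential scale calibration (LSUV-style, scale only): one
#' simulated episode is pushed through the extractor and each layer's
#' weights and biases are rescaled so its pre-activations have unit
#' standard deviation. Scenes are sparse (a few bright squares on a
#' black background), so untouched random initializations produce
#' vanishing activations; calibration restores well-scaled signals
#' before any training happens. The frozen front-end is rescaled here,
#' once, and then never changes again.
#'
#' Called automatically by [trainModel()] on uncalibrated models.
#'
#' @param model a [SiameseModel-class].
#' @param scene a [SceneConfig-class] providing the input statistics.
#' @param nImages number of calibration images.
#' @param targetSd pre-activation standard deviation to calibrate each
#'   layer to.
#' @return The rescaled [SiameseModel-class].
#' @export
calibrateModel <- function(model, scene, nImages = 61L, targetSd = 1) {
  sq <- simulateSequence(scene, nImages - 1L)
  layers <- model@extractor
  H <- model@config$inputSize
  N <- dim(sq@images)[3]
  A <- matrix(as.numeric(sq@images), ncol = 1L)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      cols <- nn_im2col(A, H, H, N, ly$k, ly$stride, ly$pad)
      Z <- addBias(cols %*% ly$W, ly$b)
      if (!isTRUE(ly$pool)) {  # pooling layers keep their fixed weights
        s <- stats::sd(as.numeric(Z)) / targetSd
        if (is.finite(s) && s > 0) {
          ly$W <- ly$W / s; ly$b <- ly$b / s; Z <- Z / s
        }
      }
      A <- applyAct(Z, ly$act)
      H <- convOutSize(H, ly$k, ly$stride, ly$pad)
    } else if (ly$type == "flatten") {
      C <- ncol(A)
      hw <- H * H
      Fm <- matrix(0, N, hw * C)
      for (c in seq_len(C)) {
        Fm[, ((c - 1L) * hw + 1L):(c * hw)] <- t(matrix(A[, c], hw, N))
      }
      A <- Fm
    } else if (ly$type == "gap") {
      hw <- H * H
      Fm <- matrix(0, N, ncol(A))
      for (c in seq_len(ncol(A))) Fm[, c] <- colMeans(matrix(A[, c], hw, N))
      A <- Fm
    } else {
      Z <- addBias(A %*% ly$W, ly$b)
      s <- stats::sd(as.numeric(Z)) / targetSd
      if (is.finite(s) && s > 0) {
        ly$W <- ly$W / s; ly$b <- ly$b / s; Z <- Z / s
      }
      A <- applyAct(Z, ly$act)
    }
    layers[[i]] <- ly
  }
  model@extractor <- layers
  model@config$calibrated <- TRUE
  model
}

## embeddings for an (H, W, N) image array
embedArray <- function(model, images) {
  if (dim(images)[1] != model@config$inputSize) {
    nsError("shapeError", sprintf("images are %d px but the model expects %d px",
                                  dim(images)[1], model@config$inputSize))
  }
  stackForward(model@extractor, images)$out
}

## classifier input modes: "diff" compares the two representations by
## their difference (translation-invariant along the embedding line),
## "concat" passes both embeddings, "both" passes both plus the
## difference
pairFeatures <- function(mode, zBefore, zAfter, cs = 1) {
  switch(mode,
         diff = zAfter - zBefore,
         concat = cbind(zBefore, zAfter),
         # "both": the comparison (difference) leads; the absolute
         # coordinates are passed at reduced scale so they inform the
         # embedding's layout without dominating the decision
         both = cbind(cs * zBefore, cs * zAfter, zAfter - zBefore))
}

## chain rule of pairFeatures: returns list(before, after) gradients
pairFeaturesBackward <- function(mode, dIn, d, cs = 1) {
  switch(mode,
         diff = list(before = -dIn, after = dIn),
         concat = list(before = dIn[, 1:d, drop = FALSE],
                       after = dIn[, (d + 1L):(2L * d), drop = FALSE]),
         both = {
           dDiff <- dIn[, (2L * d + 1L):(3L * d), drop = FALSE]
           list(before = cs * dIn[, 1:d, drop = FALSE] - dDiff,
                after = cs * dIn[, (d + 1L):(2L * d), drop = FALSE] + dDiff)
         })
}

clfInputWidth <- function(mode, d) {
  switch(mode, diff = d, concat = 2L * d, both = 3L * d)
}

## pair log-probabilities from embeddings of before/after images
classifyPairs <- function(model, zBefore, zAfter) {
  mode <- model@config$clfInput %||% "diff"
  logits <- stackForward(model@classifier,
                         pairFeatures(mode, zBefore, zAfter))$out
  logSoftmax(logits)
}

#' Train the model on action prediction
#'
#' Each mini-batch is one freshly simulated episode: the
#' \code{actionsPerMinibatch + 1} rendered states pass once through the
#' shared feature extractor and consecutive embeddings form the
#' before/after pairs for the classifier. The loss is the 3-class
#' negative log-likelihood of the true action; the frozen front-end
#' receives no updates. Per-epoch mean loss and held-out accuracy are
#' recorded in the model's \code{history}.
#'
#' @param model an untrained (or further-trainable) [SiameseModel-class].
#' @param scene a [SceneConfig-class] describing the training scenes.
#' @param training a [trainingConfig()] list.
#' @param seed optional integer seed covering simulation and optimization.
#' @param shuffleLabels permute action labels within every mini-batch
#'   (control experiment: destroys the learnable signal).
#' @param verbose print per-epoch progress.
#' @return The trained [SiameseModel-class].
#' @export
trainModel <- function(model, scene, training = trainingConfig(),
                       seed = NULL, shuffleLabels = FALSE, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (scene@imageSize != model@config$inputSize) {
    nsError("shapeError", "scene imageSize must match model inputSize")
  }
  if (!isTRUE(model@config$calibrated)) {
    model <- calibrateModel(model, scene)
  }
  clfMode <- model@config$clfInput %||% "diff"
  extractor <- model@extractor
  classifier <- model@classifier
  stExt <- adamInit(extractor)
  stClf <- adamInit(classifier)
  holdout <- lapply(seq_len(training$holdoutSequences), function(i) {
    simulateSequence(scene, training$actionsPerMinibatch)
  })
  history <- model@history
  pairsConsumed <- 0L
  step <- 0L
  for (epoch in seq_len(training$epochs)) {
    lossSum <- 0
    for (mb in seq_len(training$minibatches)) {
      sq <- simulateSequence(scene, training$actionsPerMinibatch)
      nP <- length(sq@actions)
      labels <- actionToInt(sq@actions)
      if (shuffleLabels) labels <- sample(labels)
      fwd <- stackForward(extractor, sq@images, cache = TRUE)
      Z <- fwd$out
      zB <- Z[1:nP, , drop = FALSE]
      zA <- Z[2:(nP + 1L), , drop = FALSE]
      cfwd <- stackForward(classifier,
                           pairFeatures(clfMode, zB, zA), cache = TRUE)
      logp <- logSoftmax(cfwd$out)
      loss <- nllLoss(logp, labels)
      if (!is.finite(loss)) {
        nsError("divergenceError", "training loss became non-finite")
      }
      lossSum <- lossSum + loss
      dLogits <- nllGrad(logp, labels)
      cbwd <- stackBackward(classifier, cfwd$caches, dLogits, nP,
                            needInputGrad = TRUE)
      d <- model@config$embeddingDim
      pg <- pairFeaturesBackward(clfMode, cbwd$dIn, d)
      dZ <- matrix(0, nP + 1L, d)
      dZ[1:nP, ] <- dZ[1:nP, ] + pg$before
      dZ[2:(nP + 1L), ] <- dZ[2:(nP + 1L), ] + pg$after
      ebwd <- stackBackward(extractor, fwd$caches, dZ, nP + 1L)
      step <- step + 1L
      up <- adamStep(extractor, ebwd$grads, stExt, training$learningRate, step)
      extractor <- up$layers; stExt <- up$state
      up <- adamStep(classifier, cbwd$grads, stClf, training$learningRate, step)
      classifier <- up$layers; stClf <- up$state
      pairsConsumed <- pairsConsumed + nP
    }
    model@extractor <- extractor
    model@classifier <- classifier
    acc <- holdoutAccuracy(model, holdout)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = lossSum / training$minibatches,
      holdoutAccuracy = acc))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, holdout accuracy %.3f",
                      epoch, lossSum / training$minibatches, acc))
    }
  }
  expected <- training$epochs * training$minibatches * training$actionsPerMinibatch
  stopifnot(pairsConsumed == expected)
  model@history <- history
  model@trained <- TRUE
  attr(model@history, "pairsConsumed") <- pairsConsumed
  model
}

holdoutAccuracy <- function(model, sequences) {
  ok <- 0L
  n <- 0L
  for (sq in sequences) {
    pred <- predictSequence(model, sq)
    ok <- ok + sum(pred == sq@actions)
    n <- n + length(sq@actions)
  }
  ok / n
}

## predicted action codes for every pair of an episode
predictSequence <- function(model, sq) {
  Z <- embedArray(model, sq@images)
  nP <- length(sq@actions)
  logp <- classifyPairs(model, Z[1:nP, , drop = FALSE],
                        Z[2:(nP + 1L), , drop = FALSE])
  c("P", "T", "S")[max.col(logp, ties.method = "first")]
}

#' Embed images into the representation space
#'
#' @param model a [SiameseModel-class].
#' @param x an [ImageSet-class], [ActionSequence-class], or a numeric
#'   array imageSize x imageSize x N (a single matrix is treated as one
#'   image).
#' @return N x embeddingDim numeric matrix.
#' @export
setGeneric("embedImages", function(model, x) standardGeneric("embedImages"))

#' @rdname embedImages
#' @export
setMethod("embedImages", signature("SiameseModel", "ImageSet"),
          function(model, x) embedBatched(model, x@images))

#' @rdname embedImages
#' @export
setMethod("embedImages", signature("SiameseModel", "ActionSequence"),
          function(model, x) embedBatched(model, x@images))

#' @rdname embedImages
#' @export
setMethod("embedImages", signature("SiameseModel", "array"),
          function(model, x) {
            if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
            embedBatched(model, x)
          })

## chunk large image sets so the im2col buffers stay modest
embedBatched <- function(model, images, chunk = 512L) {
  n <- dim(images)[3]
  out <- matrix(0, n, model@config$embeddingDim)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- embedArray(model, images[, , s:e, drop = FALSE])
  }
  out
}

#' Predict the action between two images
#'
#' @param model a trained [SiameseModel-class].
#' @param before,after imageSize x imageSize matrices (or arrays of them).
#' @return List with \code{probabilities} (rows on the 3-simplex, columns
#'   P/T/S) and \code{action} (argmax codes).
#' @export
predictAction <- function(model, before, after) {
  if (length(dim(before)) == 2L) dim(before) <- c(dim(before), 1L)
  if (length(dim(after)) == 2L) dim(after) <- c(dim(after), 1L)
  zB <- embedBatched(model, before)
  zA <- embedBatched(model, after)
  logp <- classifyPairs(model, zB, zA)
  p <- exp(logp)
  colnames(p) <- c("P", "T", "S")
  list(probabilities = p,
       action = c("P", "T", "S")[max.col(logp, ties.method = "first")])
}

#' Action-classification error binned by the before-image count
#'
#' Evaluates the trained classifier on action episodes and reports, for
#' every before-image object count, the error rate with a 95% Bayesian
#' binomial interval (uniform prior) and the sample size.
#'
#' @param model a trained [SiameseModel-class].
#' @param sequences list of [ActionSequence-class] episodes
#'   (e.g. from [actionTestSet()]).
#' @return Data frame with columns \code{count}, \code{n}, \code{errors},
#'   \code{error}, \code{lower}, \code{upper}.
#' @export
actionErrorByCount <- function(model, sequences) {
  if (is(sequences, "ActionSequence")) sequences <- list(sequences)
  before <- integer(0)
  wrong <- logical(0)
  for (sq in sequences) {
    pred <- predictSequence(model, sq)
    nP <- length(sq@actions)
    before <- c(before, sq@counts[1:nP])
    wrong <- c(wrong, pred != sq@actions)
  }
  counts <- sort(unique(before))
  out <- do.call(rbind, lapply(counts, function(k) {
    idx <- before == k
    n <- sum(idx)
    if (n == 0L) nsError("emptyBinError", sprintf("no samples at count %d", k))
    kErr <- sum(wrong[idx])
    ci <- bayesianBinomialCI(kErr, n)
    data.frame(count = k, n = n, errors = kErr, error = kErr / n,
               lower = ci$lower, upper = ci$upper)
  }))
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture config and package version;
#' loading restores a model that reproduces predictions exactly.
#'
#' @param model a [SiameseModel-class].
#' @param path file path.
#' @return \code{loadModel} returns the restored [SiameseModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(list(version = as.character(utils::packageVersion("numerosense")),
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj$model, "SiameseModel"))
  obj$model
}

#' Write the training history to CSV
#' @param model a trained [SiameseModel-class].
#' @param path file path.
#' @export
writeHistory <- function(model, path) {
  write.csv(model@history, path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "SiameseModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SiameseModel: %d px input, %d frozen + %d trainable conv, %d fc -> %d-d embedding (%s)\n",
    cfg$inputSize, cfg$frozenLayers, cfg$trainableConvLayers, cfg$fcLayers,
    cfg$embeddingDim, if (object@trained) "trained" else "untrained"))
  if (nrow(object@history)) {
    h <- tail(object@history, 1L)
    cat(sprintf("  last epoch %d: loss %.4f, holdout accuracy %.3f\n",
                h$epoch, h$loss, h$holdoutAccuracy))
  }
})
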
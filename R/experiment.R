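#' Experiment profiles
#'
#' Bundle the scene, model, training, analysis and psychophysics
#' settings for one reproduction run. The \code{"full"} profile matches
#' the study conditions (244 px images, 30-epoch schedule); the
#' \code{"desk"} profile scales the geometry and schedule down (96 px
#' images, 30 epochs of 90 short episodes) so a complete run fits comfortably on one CPU
#' while preserving the object-to-image proportions and every analysis
#' setting (minimum cluster size 90, reference numerosity 16, balanced
#' 0--30 test set with 200 images per count).
#'
#' @param regime scene appearance regime, \code{"A"} or \code{"B"}.
#' @param maxObjects training cap on the object count (default 3).
#' @param embeddingDim embedding dimension (default 2).
#' @return Named list with components \code{scene}, \code{model},
#'   \code{training}, \code{analysis}, \code{psychophys}, \code{test}.
#' @export
deskProfile <- function(regime = "A", maxObjects = 3L, embeddingDim = 2L) {
  list(
    name = "desk",
    scene = sceneConfig(regime, "desk", maxObjects = maxObjects),
    model = modelConfig(embeddingDim = embeddingDim, inputSize = 96L),
    # the full schedule's 5,400-pair epoch split into 60-action episodes,
    # so the optimizer takes the same 90 steps per epoch at every profile
    training = trainingConfig(epochs = 30L, minibatches = 90L,
                              actionsPerMinibatch = 60L,
                              holdoutSequences = 3L),
    analysis = list(minClusterSize = 90L, purityThreshold = 0.95,
                    largeMinClusterSize = 100L),
    psychophys = list(referenceCount = 16L, trials = 200L,
                      testCounts = seq(8L, 30L, 2L)),
    test = list(balancedCounts = 0:30, nPerCount = 200L,
                evalSequences = 15L, evalActions = 180L, evalMaxObjects = 8L)
  )
}

#' @rdname deskProfile
#' @export
fullProfile <- function(regime = "B", maxObjects = 3L, embeddingDim = 2L) {
  p <- deskProfile(regime, maxObjects, embeddingDim)
  p$name <- "full"
  p$scene <- sceneConfig(regime, "full", maxObjects = maxObjects)
  p$model <- modelConfig(embeddingDim = embeddingDim, inputSize = 244L)
  p$training <- trainingConfig(epochs = 30L)
  p
}

#' Run the complete reproduction pipeline
#'
#' Simulate, train, embed, analyse: trains the Siamese model on action
#' prediction, evaluates action classification by before-count, embeds a
#' balanced 0--30 test set, discovers number categories by density
#' clustering, calibrates the embedding line, and computes the
#' psychophysics-style summaries. All randomness is governed by
#' \code{seed}.
#'
#' @param profile a profile list from [deskProfile()] or [fullProfile()].
#' @param seed integer seed.
#' @param outDir optional directory; when given, the embeddings, cluster
#'   confusion, line model, psychometric and estimation tables, training
#'   history, model checkpoint and a machine-readable summary are
#'   written there.
#' @param verbose print stage progress.
#' @return List with the trained model, the analysis objects, and a
#'   \code{summary} list of the headline metrics.
#' @export
runExperiment <- function(profile = deskProfile(), seed = 1L, outDir = NULL,
                          verbose = FALSE) {
  set.seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("training (%s profile, regime %s)", profile$name, profile$scene@regime)
  model <- buildModel(profile$model)
  model <- trainModel(model, profile$scene, profile$training, verbose = verbose)

  say("evaluating action classification")
  # held-out error: fresh episodes from the training recipe itself
  heldOutSeqs <- actionTestSet(profile$scene, 8L, profile$test$evalActions)
  heldOutTab <- actionErrorByCount(model, heldOutSeqs)
  heldOutError <- sum(heldOutTab$errors) / sum(heldOutTab$n)
  # extrapolation: episodes allowed to exceed the training cap
  evalScene <- profile$scene
  evalScene@maxObjects <- as.integer(profile$test$evalMaxObjects)
  evalSeqs <- actionTestSet(evalScene, profile$test$evalSequences,
                            profile$test$evalActions)
  actionError <- actionErrorByCount(model, evalSeqs)
  low <- actionError$count <= profile$scene@maxObjects
  trainRangeError <- sum(actionError$errors[low]) / sum(actionError$n[low])

  say("embedding the balanced 0-%d set", max(profile$test$balancedCounts))
  balanced <- balancedImageSet(profile$scene, profile$test$balancedCounts,
                               profile$test$nPerCount)
  emb <- embedImages(model, balanced)

  say("clustering and calibrating")
  clustering <- clusterEmbeddings(emb, profile$analysis$minClusterSize)
  confusion <- numberConfusion(clustering, balanced@counts,
                               profile$analysis$purityThreshold)
  clusteringLarge <- clusterEmbeddings(
    emb, profile$analysis$largeMinClusterSize %||% 100L)
  line <- calibrateLine(emb, clustering)
  perceived <- perceivedNumerosity(line, emb)
  spearman <- cor(perceived, balanced@counts, method = "spearman")
  linError <- linearApproximationError(emb)

  say("psychophysics")
  curve <- comparisonCurve(line, model, balanced,
                           profile$psychophys$referenceCount,
                           profile$psychophys$testCounts,
                           profile$psychophys$trials)
  estim <- estimationReport(line, model, balanced)

  graph <- tryCatch(
    clusterGraphFromActions(evalSeqs,
      evalClustering(model, evalSeqs, emb, clustering),
      line@zeroCluster),
    numerosenseError = function(e) NULL)

  summary <- list(
    seed = seed, profile = profile$name, regime = profile$scene@regime,
    pairsConsumed = attr(model@history, "pairsConsumed"),
    finalHoldoutAccuracy = tail(model@history$holdoutAccuracy, 1L),
    heldOutErrorPct = 100 * heldOutError,
    trainRangeErrorPct = 100 * trainRangeError,
    nClusters = clustering@nClusters,
    nClustersLargeMin = clusteringLarge@nClusters,
    subitizationLimit = confusion$subitizationLimit,
    spearmanPerceivedCount = spearman,
    linearApproximationErrorPct = 100 * linError,
    meanAbsRelErrorPct = 100 * estim$meanAbsRelError,
    powerLawExponent = if (!is.null(estim$powerLaw)) estim$powerLaw$b else NA_real_,
    powerLawCoefficient = if (!is.null(estim$powerLaw)) estim$powerLaw$a else NA_real_,
    proportionMoreAtReference =
      curve$proportionMore[curve$testCount == profile$psychophys$referenceCount],
    orderChainLength = if (!is.null(graph)) length(graph@order) else 0L
  )

  result <- list(model = model, heldOutError = heldOutTab,
                 actionError = actionError,
                 balanced = balanced, embeddings = emb,
                 clustering = clustering, confusion = confusion,
                 line = line, curve = curve, estimation = estim,
                 graph = graph, summary = summary)
  if (!is.null(outDir)) writeExperiment(result, outDir)
  result
}

## cluster labels for the evaluation episodes, predicted by nearest
## selected-cluster centroid in the embedding (the clustering itself was
## fit on the balanced set)
evalClustering <- function(model, evalSeqs, emb, clustering) {
  ids <- sort(unique(clustering@labels[!is.na(clustering@labels)]))
  cent <- t(vapply(ids, function(cl) {
    colMeans(emb[which(clustering@labels == cl), , drop = FALSE])
  }, numeric(ncol(emb))))
  # assignment radius: generous envelope of each cluster's own spread
  radius <- vapply(seq_along(ids), function(i) {
    Z <- emb[which(clustering@labels == ids[i]), , drop = FALSE]
    3 * stats::quantile(sqrt(rowSums(sweep(Z, 2L, cent[i, ])^2)), 0.95) + 1e-9
  }, numeric(1))
  labels <- integer(0)
  for (sq in evalSeqs) {
    Z <- embedImages(model, sq)
    d2 <- -2 * tcrossprod(Z, cent) +
      outer(rowSums(Z^2), rep(1, nrow(cent))) +
      outer(rep(1, nrow(Z)), rowSums(cent^2))
    nearest <- max.col(-d2, ties.method = "first")
    dist <- sqrt(pmax(d2[cbind(seq_len(nrow(Z)), nearest)], 0))
    lb <- ids[nearest]
    lb[dist > radius[nearest]] <- NA_integer_
    labels <- c(labels, lb)
  }
  new("NumberClustering", labels = labels,
      minClusterSize = clustering@minClusterSize,
      nClusters = length(ids))
}

writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  saveModel(result$model, file.path(outDir, "model.rds"))
  writeHistory(result$model, file.path(outDir, "history.csv"))
  emb <- as.data.frame(result$embeddings)
  names(emb) <- paste0("z", seq_len(ncol(emb)))
  emb <- cbind(id = seq_len(nrow(emb)), true_count = result$balanced@counts,
               emb, cluster = result$clustering@labels)
  write.csv(emb, file.path(outDir, "embeddings.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$confusion$matrix),
            file.path(outDir, "confusion.csv"))
  write.csv(result$actionError, file.path(outDir, "action_error.csv"),
            row.names = FALSE)
  write.csv(result$curve, file.path(outDir, "psychometric.csv"),
            row.names = FALSE)
  write.csv(result$estimation$perCount, file.path(outDir, "estimation.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(origin = result$line@origin, direction = result$line@direction,
         unit = result$line@unit),
    file.path(outDir, "line_model.json"), auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(result$summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(outDir)
}
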
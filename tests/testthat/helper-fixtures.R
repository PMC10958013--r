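## shared fixtures: tiny configurations for fast unit tests and one
## cached desk-profile reproduction reused by the acceptance tests

tinySceneA <- function(maxObjects = 3L) {
  sceneConfig("A", "desk", maxObjects = maxObjects, imageSize = 32L,
              sizeRange = c(4, 4), margin = 1)
}

tinySceneB <- function(maxObjects = 3L) {
  sceneConfig("B", "desk", maxObjects = maxObjects, imageSize = 32L,
              sizeRange = c(3, 6), margin = 1)
}

tinyModelConfig <- function(embeddingDim = 2L) {
  modelConfig(embeddingDim = embeddingDim, inputSize = 32L,
              frozenChannels = 4L, trainChannels = 8L,
              fcHidden = 32L, clfHidden = 32L)
}

## small-but-real training used by several property tests
tinyTraining <- function(epochs = 2L) {
  trainingConfig(epochs = epochs, minibatches = 10L,
                 actionsPerMinibatch = 30L, holdoutSequences = 1L)
}

## the desk-profile reproduction shared by all acceptance tests: trained
## once per test run, then reused (training is the expensive stage)
.acceptanceCache <- new.env(parent = emptyenv())

deskRun <- function() {
  if (is.null(.acceptanceCache$run)) {
    .acceptanceCache$run <- runExperiment(deskProfile("A"), seed = 101L)
  }
  .acceptanceCache$run
}

## scaled-down scene/schedule for the embedding-dimension sweep
miniSceneA <- function() {
  sceneConfig("A", "desk", imageSize = 64L, sizeRange = c(4, 4), margin = 1)
}

miniTrainedModel <- function(embeddingDim, seed) {
  cfg <- modelConfig(embeddingDim = embeddingDim, inputSize = 64L)
  m <- buildModel(cfg, seed = seed)
  trainModel(m, miniSceneA(),
             trainingConfig(epochs = 10L, minibatches = 90L,
                            actionsPerMinibatch = 30L,
                            holdoutSequences = 1L), seed = seed + 1L)
}
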
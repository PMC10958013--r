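#' @import methods
#' @importFrom stats runif rnorm qbeta cor sd quantile
#' @importFrom utils head tail write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib numerosense, .registration = TRUE
NULL

#' Scene simulator configuration
#'
#' Describes one synthetic-scene regime: image geometry, the object
#' appearance ranges, the clearance margin between objects, the training
#' cap on the number of objects, and the action-multiplicity distribution
#' (imprecise put/take affecting several objects at once).
#'
#' Regime \code{"A"} draws identical full-contrast squares; regime
#' \code{"B"} draws squares of variable side length and contrast, which
#' makes total image intensity an ambiguous cue for the object count.
#'
#' @slot imageSize integer, image side in pixels.
#' @slot margin numeric, minimum clearance (bounding-box gap) between any
#'   two squares, in pixels.
#' @slot regime character, \code{"A"} or \code{"B"}.
#' @slot sizeRange numeric length-2, square side range in pixels.
#' @slot contrastRange numeric length-2, contrast range as a fraction of
#'   full scale, in (0, 1].
#' @slot maxObjects integer, cap on the object count for action sequences.
#' @slot multiplicity numeric vector of probabilities over multiplicities
#'   1, 2, ...; how many objects one put/take moves. The default
#'   \code{c(1)} makes every action move exactly one object.
#' @slot rearrange logical, whether the retained objects are re-placed at
#'   fresh uniform positions on every put/take (shake always re-places).
#' @slot maxTries integer, rejection-sampling cap per object placement.
#'
#' @seealso [sceneConfig()]
#' @export
setClass("SceneConfig",
  representation(
    imageSize = "integer", margin = "numeric", regime = "character",
    sizeRange = "numeric", contrastRange = "numeric", maxObjects = "integer",
    multiplicity = "numeric", rearrange = "logical", maxTries = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@imageSize < 8L) msg <- c(msg, "imageSize must be at least 8 px")
  if (object@margin < 0) msg <- c(msg, "margin must be non-negative")
  if (!object@regime %in% c("A", "B")) msg <- c(msg, "regime must be 'A' or 'B'")
  if (length(object@sizeRange) != 2L || diff(object@sizeRange) < 0 ||
      object@sizeRange[1] <= 0) {
    msg <- c(msg, "sizeRange must be a non-empty positive interval")
  }
  if (length(object@contrastRange) != 2L || diff(object@contrastRange) < 0 ||
      object@contrastRange[1] <= 0 || object@contrastRange[2] > 1) {
    msg <- c(msg, "contrastRange must be a non-empty interval in (0, 1]")
  }
  if (object@maxObjects < 1L) msg <- c(msg, "maxObjects must be >= 1")
  if (object@sizeRange[2] > object@imageSize) {
    msg <- c(msg, "largest object does not fit in the image")
  }
  if (length(object@multiplicity) < 1L || any(object@multiplicity < 0) ||
      abs(sum(object@multiplicity) - 1) > 1e-8) {
    msg <- c(msg, "multiplicity must be a probability vector over 1, 2, ...")
  }
  if (length(msg)) msg else TRUE
})

#' A simulated put/take/shake episode
#'
#' One episode of object manipulation: the sequence of scene states
#' (starting from the empty scene), the action taken between consecutive
#' states, and the rendered grayscale image of every state. Action
#' \code{i} transforms state \code{i} into state \code{i + 1}, so an
#' episode of \code{n} actions holds \code{n + 1} states/images and
#' \code{n} before/after image pairs.
#'
#' @slot config the [SceneConfig-class] used.
#' @slot actions character vector, \code{"P"}, \code{"T"} or \code{"S"}.
#' @slot counts integer vector, object count of every state
#'   (length \code{length(actions) + 1}).
#' @slot states list of data frames (columns \code{x}, \code{y},
#'   \code{size}, \code{contrast}), one per state.
#' @slot images numeric array, imageSize x imageSize x nStates, values in
#'   [0, 1] with background 0.
#' @export
setClass("ActionSequence",
  representation(
    config = "SceneConfig", actions = "character", counts = "integer",
    states = "list", images = "array"
  )
)

setValidity("ActionSequence", function(object) {
  n <- length(object@actions)
  if (length(object@counts) != n + 1L) return("counts must have length n_actions + 1")
  if (length(object@states) != n + 1L) return("states must have length n_actions + 1")
  if (!all(object@actions %in% c("P", "T", "S"))) return("unknown action code")
  if (any(object@counts < 0L)) return("negative object count")
  TRUE
})

#' A labeled set of rendered scenes
#'
#' Images with known object counts, generated either by direct placement
#' (balanced sets) or collected from action episodes.
#'
#' @slot config the [SceneConfig-class] used.
#' @slot images numeric array, imageSize x imageSize x nImages.
#' @slot counts integer vector of object counts, one per image.
#' @export
setClass("ImageSet",
  representation(config = "SceneConfig", images = "array", counts = "integer")
)

setValidity("ImageSet", function(object) {
  if (length(dim(object@images)) != 3L) return("images must be a 3-d array")
  if (dim(object@images)[3] != length(object@counts)) {
    return("counts must match the number of images")
  }
  TRUE
})

#' Siamese perception network plus action classifier
#'
#' A convolutional feature extractor mapping each image to a
#' low-dimensional embedding, applied with shared weights to the before
#' and after images (Siamese configuration), and a fully connected
#' classifier that predicts the action (put/take/shake) from the pair of
#' embeddings. The first convolutional layers are frozen: their weights
#' are drawn once (seeded) and never updated.
#'
#' @slot config list of architecture settings (see [modelConfig()]).
#' @slot extractor list of layer parameter lists for the feature extractor.
#' @slot classifier list of layer parameter lists for the action classifier.
#' @slot history data frame with per-epoch mean loss and held-out accuracy
#'   (empty until trained).
#' @slot trained logical.
#' @export
setClass("SiameseModel",
  representation(
    config = "list", extractor = "list", classifier = "list",
    history = "data.frame", trained = "logical"
  )
)

#' Unsupervised number-category labeling
#'
#' Cluster assignments of image embeddings from density-based
#' (HDBSCAN-style) clustering. Cluster ids are positive integers;
#' \code{NA} marks outliers excluded by the algorithm.
#'
#' @slot labels integer vector, cluster id per point or \code{NA} (outlier).
#' @slot minClusterSize integer, the clustering's main free parameter.
#' @slot nClusters integer.
#' @export
setClass("NumberClustering",
  representation(labels = "integer", minClusterSize = "integer",
                 nClusters = "integer")
)

#' Calibrated embedding line
#'
#' The one-dimensional structure of the embedding, calibrated without
#' supervision: the origin is the centroid of the zero cluster (the
#' cluster that collapses to a point because all empty images are
#' identical), the direction is the first right singular vector of the
#' mean-centered embeddings, and the unit is the zero-to-one inter-cluster
#' distance, used as a yardstick to convert line position into a perceived
#' number of objects.
#'
#' @slot origin numeric, embedding of the empty scene (zero-cluster centroid).
#' @slot direction numeric unit vector, oriented so counts increase along it.
#' @slot unit numeric scalar > 0, the zero-to-one distance.
#' @slot zeroCluster integer, id of the zero cluster.
#' @slot oneCluster integer, id of the one cluster.
#' @export
setClass("NumberLine",
  representation(origin = "numeric", direction = "numeric", unit = "numeric",
                 zeroCluster = "integer", oneCluster = "integer")
)

setValidity("NumberLine", function(object) {
  if (length(object@origin) != length(object@direction)) {
    return("origin and direction must have the same dimension")
  }
  if (!is.finite(object@unit) || object@unit <= 0) return("unit must be > 0")
  TRUE
})

#' Action-derived ordering of number clusters
#'
#' Directed links between clusters harvested from classified actions: a
#' put action links the before-image's cluster to the after-image's
#' cluster, a take action provides the same link reversed. Following
#' majority links from the zero cluster recovers the natural order of the
#' number categories.
#'
#' @slot edges data frame with columns \code{from}, \code{to},
#'   \code{n_forward}, \code{n_backward}, \code{agreement}.
#' @slot order integer vector, chain of cluster ids starting at zero, or
#'   length 0 when no consistent chain exists.
#' @export
setClass("ClusterGraph",
  representation(edges = "data.frame", order = "integer")
)
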
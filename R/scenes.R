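#' Build a scene simulator configuration
#'
#' The two appearance regimes follow the study conditions: regime
#' \code{"A"} uses identical squares (side 15 px, 100% contrast at the
#' full 244 px image size), regime \code{"B"} draws side lengths from
#' 10--30 px and contrasts from 9.8--100% of full scale. The
#' \code{"desk"} profile scales the geometry down (96 px images,
#' proportionally smaller squares and margin) so that CPU-only runs stay
#' cheap while keeping the object-to-image area ratio of the full
#' profile.
#'
#' @param regime \code{"A"} (identical squares) or \code{"B"} (variable
#'   size and contrast).
#' @param profile \code{"full"} (244 px) or \code{"desk"} (96 px).
#' @param maxObjects cap on the object count during action episodes
#'   (training default 3).
#' @param imageSize,margin,sizeRange,contrastRange overrides for the
#'   profile defaults.
#' @param multiplicity probability vector over action multiplicities
#'   1, 2, ...; \code{c(1)} (the default) makes every put/take move
#'   exactly one object; anything else models imprecise actions.
#' @param rearrange re-place the retained objects on every put/take
#'   (default \code{TRUE}); shake always re-places all objects.
#' @param maxTries rejection-sampling cap per object placement.
#' @return A [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig("A", profile = "desk")
#' seqs <- simulateSequence(cfg, nActions = 10, seed = 1)
#' @export
sceneConfig <- function(regime = c("A", "B"), profile = c("full", "desk"),
                        maxObjects = 3L, imageSize = NULL, margin = NULL,
                        sizeRange = NULL, contrastRange = NULL,
                        multiplicity = 1, rearrange = TRUE,
                        maxTries = 10000L) {
  regime <- match.arg(regime)
  profile <- match.arg(profile)
  if (profile == "full") {
    imageSize <- imageSize %||% 244L
    margin <- margin %||% 3
    sizeRange <- sizeRange %||% (if (regime == "A") c(15, 15) else c(10, 30))
  } else {
    imageSize <- imageSize %||% 96L
    margin <- margin %||% 1
    sizeRange <- sizeRange %||% (if (regime == "A") c(6, 6) else c(4, 12))
  }
  contrastRange <- contrastRange %||%
    (if (regime == "A") c(1, 1) else c(0.098, 1))
  new("SceneConfig",
    imageSize = as.integer(imageSize), margin = as.numeric(margin),
    regime = regime, sizeRange = as.numeric(sizeRange),
    contrastRange = as.numeric(contrastRange),
    maxObjects = as.integer(maxObjects),
    multiplicity = as.numeric(multiplicity) / sum(multiplicity),
    rearrange = isTRUE(rearrange), maxTries = as.integer(maxTries)
  )
}

emptyState <- function() {
  data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
             contrast = numeric(0))
}

## bounding-box gap between a candidate square and each existing square:
## positive when the extents are separated on at least one axis
boxGap <- function(x, y, size, state) {
  pmax(abs(x - state$x) - (size + state$size) / 2,
       abs(y - state$y) - (size + state$size) / 2)
}

placeGiven <- function(state, config, size, contrast) {
  half <- size / 2
  lo <- half
  hi <- config@imageSize - half
  if (hi < lo) nsError("placementError", "object larger than the image")
  tries <- 0L
  batch <- 64L
  while (tries < config@maxTries) {
    nb <- min(batch, config@maxTries - tries)
    cx <- runif(nb, lo, hi)
    cy <- runif(nb, lo, hi)
    if (nrow(state) == 0L) {
      return(data.frame(x = cx[1], y = cy[1], size = size, contrast = contrast))
    }
    for (i in seq_len(nb)) {
      if (all(boxGap(cx[i], cy[i], size, state) >= config@margin)) {
        return(data.frame(x = cx[i], y = cy[i], size = size,
                          contrast = contrast))
      }
    }
    tries <- tries + nb
  }
  nsError("placementError",
          sprintf("could not place a %.1f px object after %d attempts (scene too dense)",
                  size, config@maxTries))
}

#' Place one new object into a scene
#'
#' Draws size and contrast uniformly from the regime ranges and a
#' position uniformly over the image, rejecting candidates that leave the
#' image bounds or violate the clearance margin against existing objects.
#'
#' @param state data frame of existing objects (columns \code{x},
#'   \code{y}, \code{size}, \code{contrast}).
#' @param config a [SceneConfig-class].
#' @return One-row data frame describing the new object.
#' @export
placeObject <- function(state, config) {
  size <- runif(1, config@sizeRange[1], config@sizeRange[2])
  contrast <- runif(1, config@contrastRange[1], config@contrastRange[2])
  placeGiven(state, config, size, contrast)
}

## re-place every object of `state` at fresh uniform positions,
## keeping sizes and contrasts
rearrangeState <- function(state, config) {
  out <- emptyState()
  for (i in seq_len(nrow(state))) {
    out <- rbind(out, placeGiven(out, config, state$size[i], state$contrast[i]))
  }
  out
}

#' Apply one manipulation to a scene
#'
#' \code{"P"} (put) adds \code{m} objects, \code{"T"} (take) removes
#' \code{m} random objects, \code{"S"} (shake) re-randomizes positions
#' while keeping every object's size and contrast. Under the default
#' configuration the retained objects are also re-placed during put and
#' take, so no frame-differencing shortcut survives.
#'
#' @param state data frame of objects before the action.
#' @param action \code{"P"}, \code{"T"} or \code{"S"}.
#' @param config a [SceneConfig-class].
#' @param m action multiplicity (objects added/removed); default 1.
#' @return Data frame of objects after the action.
#' @export
applyAction <- function(state, action, config, m = 1L) {
  if (!action %in% c("P", "T", "S")) nsError("invalidActionError", "unknown action")
  if (action == "T" && nrow(state) < m) {
    nsError("invalidActionError",
            sprintf("take with multiplicity %d on a scene with %d objects", m,
                    nrow(state)))
  }
  if (action == "S") {
    return(rearrangeState(state, config))
  }
  retained <- if (action == "T") {
    state[-sample.int(nrow(state), m), , drop = FALSE]
  } else {
    state
  }
  out <- if (config@rearrange) rearrangeState(retained, config) else retained
  if (action == "P") {
    for (i in seq_len(m)) {
      obj <- placeObject(out, config)
      if (!config@rearrange && nrow(out) > 0L) {
        # keep existing positions; the new object already respects clearance
      }
      out <- rbind(out, obj)
    }
  }
  out
}

#' Sample a valid action for the current count
#'
#' Uniform over the subset of \{P, T, S\} that is meaningful: take is
#' excluded at count 0, put is excluded once the episode cap is reached.
#'
#' @param count current object count.
#' @param config a [SceneConfig-class].
#' @return \code{"P"}, \code{"T"} or \code{"S"}.
#' @export
sampleValidAction <- function(count, config) {
  valid <- c("P", "T", "S")
  if (count <= 0L) valid <- setdiff(valid, "T")
  if (count >= config@maxObjects) valid <- setdiff(valid, "P")
  valid[sample.int(length(valid), 1L)]
}

#' Render a scene to a grayscale image
#'
#' Deterministic rasterization: background 0, each square painted at its
#' contrast over the pixels whose centers fall inside the square's extent
#' (half-open, so an integer side length always covers exactly
#' \code{side^2} pixels). Pixel \code{p} (0-based) spans
#' \code{[p, p + 1)} with center \code{p + 0.5}.
#'
#' @param state data frame of objects.
#' @param config a [SceneConfig-class].
#' @return imageSize x imageSize numeric matrix; rows index y, columns x.
#' @export
renderScene <- function(state, config) {
  n <- config@imageSize
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(state))) {
    xs <- pixelSpan(state$x[i], state$size[i], n)
    ys <- pixelSpan(state$y[i], state$size[i], n)
    img[ys + 1L, xs + 1L] <- state$contrast[i]
  }
  img
}

## 0-based pixels whose centers lie in [c - s/2, c + s/2)
pixelSpan <- function(center, size, imageSize) {
  lo <- ceiling(center - size / 2 - 0.5)
  hi <- ceiling(center + size / 2 - 0.5) - 1
  seq.int(max(lo, 0), min(hi, imageSize - 1))
}

#' Simulate a manipulation episode
#'
#' Starts from the empty scene and applies \code{nActions} uniformly
#' sampled valid actions, rendering every intermediate state. Consecutive
#' images form the before/after pairs the Siamese network trains on.
#'
#' @param config a [SceneConfig-class].
#' @param nActions number of actions (and image pairs).
#' @param seed optional integer seed for reproducibility.
#' @return An [ActionSequence-class].
#' @export
simulateSequence <- function(config, nActions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nActions >= 1L)
  n <- config@imageSize
  states <- vector("list", nActions + 1L)
  images <- array(0, c(n, n, nActions + 1L))
  actions <- character(nActions)
  counts <- integer(nActions + 1L)
  state <- emptyState()
  states[[1L]] <- state
  for (t in seq_len(nActions)) {
    act <- sampleValidAction(nrow(state), config)
    m <- sampleMultiplicity(config@multiplicity)
    if (act == "T") m <- min(m, nrow(state))
    if (act == "P") m <- min(m, config@maxObjects - nrow(state))
    state <- applyAction(state, act, config, m = max(m, 1L))
    actions[t] <- act
    states[[t + 1L]] <- state
    counts[t + 1L] <- nrow(state)
    images[, , t + 1L] <- renderScene(state, config)
  }
  new("ActionSequence", config = config, actions = actions, counts = counts,
      states = states, images = images)
}

#' Generate a balanced labeled test set by direct placement
#'
#' Places exactly the requested number of objects per image without using
#' action chains, so the per-count sample sizes are exactly equal by
#' construction.
#'
#' @param config a [SceneConfig-class].
#' @param counts integer vector of object counts to cover.
#' @param nPerCount images per count.
#' @param seed optional integer seed.
#' @return An [ImageSet-class].
#' @export
balancedImageSet <- function(config, counts = 0:30, nPerCount = 100L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config@imageSize
  total <- length(counts) * nPerCount
  images <- array(0, c(n, n, total))
  lab <- integer(total)
  idx <- 0L
  for (k in counts) {
    for (r in seq_len(nPerCount)) {
      state <- emptyState()
      for (j in seq_len(k)) state <- rbind(state, placeObject(state, config))
      idx <- idx + 1L
      images[, , idx] <- renderScene(state, config)
      lab[idx] <- k
    }
  }
  new("ImageSet", config = config, images = images, counts = lab)
}

#' Collect before/after pairs from action episodes into a test set
#'
#' Generates fresh episodes with the same recipe as training (optionally
#' with a higher object cap) and returns the stacked images together with
#' pair bookkeeping, for action-classification evaluation binned by the
#' before-image count.
#'
#' @param config a [SceneConfig-class] (use a higher \code{maxObjects}
#'   than training to probe extrapolation).
#' @param nSequences number of episodes.
#' @param nActions actions per episode.
#' @param seed optional integer seed.
#' @return A list with the concatenated [ActionSequence-class] objects.
#' @export
actionTestSet <- function(config, nSequences = 15L, nActions = 180L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nSequences), function(i) simulateSequence(config, nActions))
}

#' Mean-intensity covariate report
#'
#' Summarizes the mean image intensity per object count and its rank
#' correlation with the count. Under regime A intensity is a perfect
#' count readout; under regime B the per-count intensity distributions
#' overlap, so intensity alone cannot explain count discrimination.
#'
#' @param imageSet an [ImageSet-class].
#' @return List with a per-count summary data frame and the Spearman
#'   correlation between count and mean intensity.
#' @export
intensityCovariates <- function(imageSet) {
  stopifnot(length(imageSet@counts) > 0L)
  m <- apply(imageSet@images, 3L, mean)
  cnt <- imageSet@counts
  per <- do.call(rbind, lapply(sort(unique(cnt)), function(k) {
    v <- m[cnt == k]
    data.frame(count = k, mean = mean(v), sd = sd(v),
               min = min(v), max = max(v), n = length(v))
  }))
  rho <- if (length(unique(cnt)) > 1L) {
    cor(cnt, m, method = "spearman")
  } else NA_real_
  list(perCount = per, correlation = rho)
}

#' Write an episode to disk as PNG images plus JSON-lines metadata
#'
#' @param seqs an [ActionSequence-class] or list of them.
#' @param dir output directory (created if needed).
#' @return Invisibly, the metadata file path.
#' @export
writeSequences <- function(seqs, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write image files")
  }
  if (is(seqs, "ActionSequence")) seqs <- list(seqs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metaPath <- file.path(dir, "metadata.jsonl")
  con <- file(metaPath, open = "wt")
  on.exit(close(con))
  for (s in seq_along(seqs)) {
    sq <- seqs[[s]]
    for (t in seq_along(sq@counts)) {
      fname <- sprintf("seq%03d_frame%04d.png", s, t - 1L)
      png::writePNG(sq@images[, , t], file.path(dir, fname))
      rec <- list(
        sequence = s, frame = t - 1L,
        action = if (t == 1L) NA_character_ else sq@actions[t - 1L],
        count = sq@counts[t], file = fname,
        objects = sq@states[[t]]
      )
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), con)
    }
  }
  invisible(metaPath)
}

#' Number of images in a set
#' @param x an [ImageSet-class]
#' @return integer
#' @export
setMethod("length", "ImageSet", function(x) length(x@counts))

#' Object counts of a labeled image set
#' @param x an [ImageSet-class] or [ActionSequence-class]
#' @return integer vector of per-image object counts.
#' @export
setGeneric("imageCounts", function(x) standardGeneric("imageCounts"))

#' @rdname imageCounts
#' @export
setMethod("imageCounts", "ImageSet", function(x) x@counts)

#' @rdname imageCounts
#' @export
setMethod("imageCounts", "ActionSequence", function(x) x@counts)

#' Image array of a scene container
#' @param x an [ImageSet-class] or [ActionSequence-class]
#' @return numeric array imageSize x imageSize x nImages.
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' @rdname imageArray
#' @export
setMethod("imageArray", "ImageSet", function(x) x@images)

#' @rdname imageArray
#' @export
setMethod("imageArray", "ActionSequence", function(x) x@images)

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig regime %s: %d px, squares %.3g-%.3g px, contrast %.3g-%.3g, margin %.3g px, cap %d\n",
    object@regime, object@imageSize, object@sizeRange[1], object@sizeRange[2],
    object@contrastRange[1], object@contrastRange[2], object@margin,
    object@maxObjects))
})

setMethod("show", "ActionSequence", function(object) {
  cat(sprintf("ActionSequence: %d actions (P=%d T=%d S=%d), counts 0-%d\n",
              length(object@actions), sum(object@actions == "P"),
              sum(object@actions == "T"), sum(object@actions == "S"),
              max(object@counts)))
})

setMethod("show", "ImageSet", function(object) {
  cat(sprintf("ImageSet: %d images of %d px, counts %d-%d\n",
              length(object@counts), object@config@imageSize,
              min(object@counts), max(object@counts)))
})
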
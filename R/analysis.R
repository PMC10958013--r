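#' Cluster embeddings into number categories
#'
#' Density-based hierarchical clustering (HDBSCAN semantics, Euclidean
#' metric) of the image embeddings. The one free parameter is the
#' minimum cluster size; all other settings follow the algorithm's
#' defaults (in particular the neighbourhood size for core distances
#' equals the minimum cluster size, and clusters are selected by excess
#' of mass). Points the algorithm excludes are labeled \code{NA}
#' (outliers).
#'
#' @param embeddings N x d numeric matrix (rows = images).
#' @param minClusterSize minimum cluster size (default 90).
#' @param minSamples neighbourhood size for core distances; defaults to
#'   \code{minClusterSize}.
#' @return A [NumberClustering-class].
#' @export
clusterEmbeddings <- function(embeddings, minClusterSize = 90L,
                              minSamples = minClusterSize) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < minClusterSize) {
    nsError("tooFewPointsError",
            sprintf("%d points but minClusterSize = %d", nrow(embeddings),
                    minClusterSize))
  }
  labels <- hdbscanFit(embeddings, as.integer(minClusterSize),
                       as.integer(minSamples))
  new("NumberClustering", labels = labels,
      minClusterSize = as.integer(minClusterSize),
      nClusters = length(unique(labels[!is.na(labels)])))
}

#' Cluster labels (NA = outlier)
#' @param x a [NumberClustering-class].
#' @return integer vector of cluster ids with \code{NA} for outliers.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "NumberClustering", function(x) x@labels)

setMethod("show", "NumberClustering", function(object) {
  cat(sprintf("NumberClustering: %d clusters (minClusterSize %d), %d outliers\n",
              object@nClusters, object@minClusterSize,
              sum(is.na(object@labels))))
})

#' Cluster-by-count confusion and the subitization limit
#'
#' Cross-tabulates cluster membership against the true object count,
#' computes each cluster's purity (fraction of members sharing the
#' cluster's dominant count), and derives the subitization limit: the
#' largest L such that every count 0..L maps one-to-one onto a single
#' pure cluster.
#'
#' @param clustering a [NumberClustering-class] (or an integer label
#'   vector with \code{NA} outliers).
#' @param trueCounts integer vector of per-image counts, aligned with the
#'   labels.
#' @param purityThreshold minimum purity for a cluster to count as a
#'   number category (default 0.95).
#' @return List with \code{matrix} (cluster x count), \code{purity},
#'   \code{dominantCount}, and \code{subitizationLimit}.
#' @export
numberConfusion <- function(clustering, trueCounts, purityThreshold = 0.95) {
  labels <- if (is(clustering, "NumberClustering")) clustering@labels else
    as.integer(clustering)
  if (length(labels) != length(trueCounts)) {
    nsError("lengthMismatchError", "labels and counts differ in length")
  }
  keep <- !is.na(labels)
  counts <- sort(unique(trueCounts))
  cl <- sort(unique(labels[keep]))
  mat <- matrix(0L, length(cl), length(counts),
                dimnames = list(cluster = cl, count = counts))
  tb <- table(labels[keep], trueCounts[keep])
  mat[rownames(tb), colnames(tb)] <- tb
  purity <- apply(mat, 1L, function(r) max(r) / sum(r))
  dominant <- counts[apply(mat, 1L, which.max)]
  # counts mapped one-to-one: the count's images land in one pure cluster
  # whose dominant count is that count, and no other count dominates it
  limit <- -1L
  for (k in counts[counts >= 0]) {
    owners <- which(dominant == k & purity >= purityThreshold)
    if (length(owners) != 1L) break
    inK <- mat[, as.character(k)]
    # the owning cluster must capture the bulk of count-k images
    if (inK[owners] / sum(inK) < purityThreshold) break
    limit <- k
  }
  list(matrix = mat, purity = purity, dominantCount = dominant,
       subitizationLimit = limit)
}

#' Identify the zero cluster
#'
#' The zero cluster is detectable without supervision: every empty image
#' is identical, so its embeddings collapse to a point and the cluster
#' has minimal internal spread (mean distance to its centroid).
#'
#' @param embeddings N x d matrix.
#' @param clustering a [NumberClustering-class].
#' @param tol spread difference below which two candidate clusters are
#'   considered tied (an error, since the zero cluster must be unique).
#' @return Integer cluster id.
#' @export
findZeroCluster <- function(embeddings, clustering, tol = 1e-9) {
  labels <- clustering@labels
  ids <- sort(unique(labels[!is.na(labels)]))
  if (!length(ids)) nsError("missingClusterError", "no clusters to search")
  spread <- vapply(ids, function(cl) {
    Z <- embeddings[which(labels == cl), , drop = FALSE]
    ctr <- colMeans(Z)
    mean(sqrt(rowSums(sweep(Z, 2L, ctr)^2)))
  }, numeric(1))
  ord <- order(spread)
  if (length(ids) > 1L && spread[ord[2L]] - spread[ord[1L]] < tol) {
    nsError("ambiguityError", "two clusters tie for minimal spread")
  }
  ids[ord[1L]]
}

#' Calibrate the embedding line
#'
#' Builds the self-calibrated number line: origin at the zero-cluster
#' centroid, direction along the first right singular vector of the
#' mean-centered embeddings (oriented so counts increase), and unit
#' length equal to the zero-to-one inter-cluster distance. The one
#' cluster is taken as the non-zero cluster whose centroid is nearest to
#' the origin along the principal direction. The unit is by default the
#' mean over all cross-pairs of point distances between the two clusters
#' (\code{unitMethod = "pairs"}); \code{"centroid"} uses the distance
#' between centroids instead.
#'
#' @param embeddings N x d matrix.
#' @param clustering a [NumberClustering-class].
#' @param unitMethod \code{"pairs"} or \code{"centroid"}.
#' @return A [NumberLine-class].
#' @export
calibrateLine <- function(embeddings, clustering,
                          unitMethod = c("pairs", "centroid")) {
  unitMethod <- match.arg(unitMethod)
  labels <- clustering@labels
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) < 2L) {
    nsError("missingClusterError", "need at least two clusters to calibrate")
  }
  zero <- findZeroCluster(embeddings, clustering)
  origin <- colMeans(embeddings[which(labels == zero), , drop = FALSE])
  ctr <- scale(embeddings, center = TRUE, scale = FALSE)
  direction <- svd(ctr, nu = 0L, nv = 1L)$v[, 1L]
  cent <- t(vapply(ids, function(cl) {
    colMeans(embeddings[which(labels == cl), , drop = FALSE])
  }, numeric(ncol(embeddings))))
  proj <- as.numeric((cent - rep(origin, each = nrow(cent))) %*% direction)
  others <- which(ids != zero)
  one <- ids[others[which.min(abs(proj[others]))]]
  # orient the line so the one cluster sits on the positive side
  if (proj[match(one, ids)] < 0) direction <- -direction
  Z0 <- embeddings[which(labels == zero), , drop = FALSE]
  Z1 <- embeddings[which(labels == one), , drop = FALSE]
  unit <- if (unitMethod == "pairs") {
    crossPairMeanDistance(Z0, Z1)
  } else {
    sqrt(sum((colMeans(Z1) - colMeans(Z0))^2))
  }
  if (!is.finite(unit) || unit <= 0) {
    nsError("degenerateUnitError", "zero and one clusters coincide")
  }
  new("NumberLine", origin = as.numeric(origin),
      direction = as.numeric(direction), unit = unit,
      zeroCluster = as.integer(zero), oneCluster = as.integer(one))
}

crossPairMeanDistance <- function(A, B) {
  cross <- -2 * tcrossprod(A, B) +
    outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  mean(sqrt(pmax(cross, 0)))
}

#' Perceived numerosity of embeddings
#'
#' Distance of each embedding from the line's origin in units of the
#' zero-to-one distance, signed by the side of the origin it falls on
#' (points behind the origin report negative values rather than being
#' clamped).
#'
#' @param line a [NumberLine-class].
#' @param z embedding matrix (N x d) or a single embedding vector.
#' @return Numeric vector of continuous count estimates.
#' @export
perceivedNumerosity <- function(line, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  rel <- sweep(as.matrix(z), 2L, line@origin)
  dist <- sqrt(rowSums(rel^2))
  sgn <- sign(as.numeric(rel %*% line@direction))
  sgn[sgn == 0] <- 1
  sgn * dist / line@unit
}

setMethod("show", "NumberLine", function(object) {
  cat(sprintf(
    "NumberLine: origin (%s), unit %.4g, zero cluster %d, one cluster %d\n",
    paste(sprintf("%.3g", object@origin), collapse = ", "), object@unit,
    object@zeroCluster, object@oneCluster))
})

#' Rank-1 linear approximation error
#'
#' Mean-centers the embedding matrix, computes its singular value
#' decomposition, zeroes every singular value beyond the first, and
#' returns the ratio of the Frobenius norm of the residual to the
#' Frobenius norm of the centered matrix. 0 means exactly collinear
#' points; an isotropic cloud in d dimensions approaches
#' sqrt((d-1)/d).
#'
#' @param embeddings N x d matrix (N >= 2).
#' @return Scalar in [0, 1].
#' @export
linearApproximationError <- function(embeddings) {
  X <- scale(as.matrix(embeddings), center = TRUE, scale = FALSE)
  if (nrow(X) < 2L) nsError("degenerateError", "need at least 2 points")
  total <- sum(X^2)
  if (total <= 0) nsError("degenerateError", "all points identical")
  s <- svd(X, nu = 0L, nv = 0L)$d
  sqrt(sum(s[-1L]^2) / sum(s^2))
}

#' Order number clusters by the actions linking them
#'
#' Every put pair whose two images both carry a (non-outlier) cluster
#' label votes for a directed link from the before-cluster to the
#' after-cluster; take pairs vote for the reverse link. Majority links
#' (at least \code{agreement} directional agreement) form a graph whose
#' chain, followed from the zero cluster, recovers the natural order of
#' the number categories.
#'
#' @param sequences list of [ActionSequence-class] episodes.
#' @param clustering a [NumberClustering-class] whose labels align with
#'   the concatenated images of \code{sequences}.
#' @param zeroCluster id of the zero cluster (chain start).
#' @param agreement minimum directional agreement for an edge (default 0.9).
#' @return A [ClusterGraph-class].
#' @export
clusterGraphFromActions <- function(sequences, clustering, zeroCluster,
                                    agreement = 0.9) {
  if (is(sequences, "ActionSequence")) sequences <- list(sequences)
  labels <- clustering@labels
  fromv <- integer(0); tov <- integer(0)
  off <- 0L
  for (sq in sequences) {
    nP <- length(sq@actions)
    lb <- labels[off + seq_len(nP + 1L)]
    off <- off + nP + 1L
    for (t in seq_len(nP)) {
      a <- lb[t]; b <- lb[t + 1L]
      if (is.na(a) || is.na(b) || a == b) next
      if (sq@actions[t] == "P") { fromv <- c(fromv, a); tov <- c(tov, b) }
      if (sq@actions[t] == "T") { fromv <- c(fromv, b); tov <- c(tov, a) }
    }
  }
  if (!length(fromv)) nsError("emptyGraphError", "no labeled P/T pairs")
  key <- paste(pmin(fromv, tov), pmax(fromv, tov))
  edges <- do.call(rbind, lapply(unique(key), function(kk) {
    idx <- key == kk
    lo <- pmin(fromv, tov)[idx][1L]
    hi <- pmax(fromv, tov)[idx][1L]
    nLoHi <- sum(fromv[idx] == lo)
    nHiLo <- sum(idx) - nLoHi
    if (nLoHi >= nHiLo) {
      data.frame(from = lo, to = hi, n_forward = nLoHi, n_backward = nHiLo,
                 agreement = nLoHi / sum(idx))
    } else {
      data.frame(from = hi, to = lo, n_forward = nHiLo, n_backward = nLoHi,
                 agreement = nHiLo / sum(idx))
    }
  }))
  strong <- edges[edges$agreement >= agreement, , drop = FALSE]
  ord <- integer(0)
  cur <- as.integer(zeroCluster)
  seen <- integer(0)
  repeat {
    if (cur %in% seen) {
      nsError("cycleError", "majority links form a cycle")
    }
    seen <- c(seen, cur)
    ord <- c(ord, cur)
    nxt <- strong$to[strong$from == cur]
    if (length(nxt) == 0L) break
    if (length(nxt) > 1L) {
      nsError("conflictError",
              sprintf("cluster %d has %d outgoing majority links", cur,
                      length(nxt)))
    }
    cur <- as.integer(nxt)
  }
  new("ClusterGraph", edges = edges, order = ord)
}

setMethod("show", "ClusterGraph", function(object) {
  cat(sprintf("ClusterGraph: %d linked cluster pairs, chain %s\n",
              nrow(object@edges),
              if (length(object@order)) paste(object@order, collapse = " -> ")
              else "(none)"))
})

#' Fit a power law perceived = a * n^b
#'
#' Least squares in log-log space over counts >= 1. An exponent b < 1
#' reflects the underestimation bias of numerosity perception at larger
#' counts.
#'
#' @param trueCounts integer vector (values >= 1 are used).
#' @param perceived numeric vector of perceived numerosities (positive
#'   values are used).
#' @return List with \code{a}, \code{b}, and the residual sum of squares
#'   of the log-log fit.
#' @export
fitPowerLaw <- function(trueCounts, perceived) {
  keep <- trueCounts >= 1 & is.finite(perceived) & perceived > 0
  x <- trueCounts[keep]
  y <- perceived[keep]
  if (length(unique(x)) < 3L) {
    nsError("insufficientDataError", "need at least 3 distinct counts >= 1")
  }
  fit <- stats::lm(log(y) ~ log(x))
  list(a = unname(exp(stats::coef(fit)[1L])), b = unname(stats::coef(fit)[2L]),
       residual = sum(stats::residuals(fit)^2))
}
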
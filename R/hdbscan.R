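## Density-based hierarchical clustering (HDBSCAN semantics).
##
## Pipeline: core distances (distance to the minSamples-th nearest
## neighbour, the point itself counted) -> mutual reachability distances
## -> single-linkage MST (Prim) -> condensed tree at minClusterSize ->
## cluster stabilities -> excess-of-mass cluster selection. Points not
## captured by a selected cluster are outliers. The O(n^2) dense-distance
## route is used throughout; embedding sets here are a few thousand
## points in a handful of dimensions.

hdbscanFit <- function(X, minClusterSize, minSamples = minClusterSize) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  k <- min(minSamples, n)
  core <- apply(D, 1L, function(r) sort.int(r, partial = k)[k])
  M <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  mst <- primMST(M)
  sl <- singleLinkage(mst, n)
  ct <- condenseTree(sl, n, minClusterSize)
  sel <- selectClustersEOM(ct)
  labelPoints(ct, sel, n)
}

## Prim's algorithm on a dense symmetric weight matrix; returns edges
## (from, to, weight) of the minimum spanning tree.
primMST <- function(M) {
  n <- nrow(M)
  inTree <- logical(n)
  inTree[1L] <- TRUE
  best <- M[1L, ]
  from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    best[inTree] <- Inf
    j <- which.min(best)
    edges[e, ] <- c(from[j], j, best[j])
    inTree[j] <- TRUE
    upd <- which(!inTree & M[j, ] < best)
    best[upd] <- M[j, upd]
    from[upd] <- j
  }
  edges
}

## Single-linkage dendrogram from sorted MST edges (union-find).
## Returns merges: (childA, childB, height, size); node ids 1..n are
## points, n+i is the node created by merge i.
singleLinkage <- function(edges, n) {
  ord <- order(edges[, 3L])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  node <- seq_len(n)          # current top node of each component root
  sizes <- rep(1L, 2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merges <- matrix(0, n - 1L, 4L)
  for (i in seq_len(n - 1L)) {
    ra <- find(edges[i, 1L])
    rb <- find(edges[i, 2L])
    newId <- n + i
    merges[i, ] <- c(node[ra], node[rb], edges[i, 3L],
                     sizes[node[ra]] + sizes[node[rb]])
    sizes[newId] <- merges[i, 4L]
    parent[ra] <- newId
    parent[rb] <- newId
    parent[newId] <- newId
    node[newId] <- newId
    node[ra] <- newId  # unused after union, kept for clarity
  }
  list(merges = merges, sizes = sizes)
}

leavesUnder <- function(sl, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) {
      out <- c(out, v)
    } else {
      stack <- c(stack, sl$merges[v - n, 1:2])
    }
  }
  out
}

## Condense the dendrogram: splits where both sides hold at least
## minClusterSize points create child clusters; smaller sides fall out of
## the running cluster as individual points at the split's density level
## lambda = 1/distance.
condenseTree <- function(sl, n, minClusterSize) {
  root <- 2L * n - 1L
  eps <- 1e-12
  # cluster bookkeeping: id 1 is the root cluster
  parentC <- 0L              # parent cluster of each cluster (0 for root)
  birth <- 0                 # lambda at which each cluster was born
  nClusters <- 1L
  rowsParent <- integer(0)   # condensed-tree point entries
  rowsPoint <- integer(0)
  rowsLambda <- numeric(0)
  childEdges <- list()       # per split: (parent, childA, childB, lambda)
  stack <- list(c(node = root, cluster = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1L]
    cl <- top[2L]
    if (v <= n) {  # singleton handed down as its own "cluster": degenerate
      rowsParent <- c(rowsParent, cl)
      rowsPoint <- c(rowsPoint, v)
      rowsLambda <- c(rowsLambda, birth[cl])
      next
    }
    m <- sl$merges[v - n, ]
    a <- m[1L]; b <- m[2L]
    lambda <- 1 / max(m[3L], eps)
    sa <- sl$sizes[a]; sb <- sl$sizes[b]
    if (sa >= minClusterSize && sb >= minClusterSize) {
      ca <- nClusters + 1L
      cb <- nClusters + 2L
      nClusters <- nClusters + 2L
      parentC[ca] <- cl; parentC[cb] <- cl
      birth[ca] <- lambda; birth[cb] <- lambda
      childEdges[[length(childEdges) + 1L]] <- c(cl, ca, cb, lambda,
                                                 sa, sb)
      stack[[length(stack) + 1L]] <- c(a, ca)
      stack[[length(stack) + 1L]] <- c(b, cb)
    } else {
      for (child in c(a, b)) {
        if (sl$sizes[child] < minClusterSize) {
          lv <- leavesUnder(sl, child, n)
          rowsParent <- c(rowsParent, rep(cl, length(lv)))
          rowsPoint <- c(rowsPoint, lv)
          rowsLambda <- c(rowsLambda, rep(lambda, length(lv)))
        } else {
          stack[[length(stack) + 1L]] <- c(child, cl)
        }
      }
    }
  }
  list(parentC = parentC, birth = birth, nClusters = nClusters,
       points = data.frame(parent = rowsParent, point = rowsPoint,
                           lambda = rowsLambda),
       edges = childEdges)
}

## Excess-of-mass selection over the condensed cluster tree. The root is
## never selected (a single all-encompassing cluster is not a finding).
selectClustersEOM <- function(ct) {
  nc <- ct$nClusters
  stability <- numeric(nc)
  if (nrow(ct$points)) {
    agg <- tapply(ct$points$lambda - ct$birth[ct$points$parent],
                  ct$points$parent, sum)
    stability[as.integer(names(agg))] <- as.numeric(agg)
  }
  for (e in ct$edges) {
    # child clusters leave the parent at the split level
    stability[e[1L]] <- stability[e[1L]] +
      (e[4L] - ct$birth[e[1L]]) * (e[5L] + e[6L])
  }
  childrenOf <- vector("list", nc)
  for (e in ct$edges) {
    childrenOf[[e[1L]]] <- c(childrenOf[[e[1L]]], e[2L], e[3L])
  }
  isCluster <- rep(TRUE, nc)
  isCluster[1L] <- FALSE
  for (cl in rev(seq_len(nc))) {
    if (cl == 1L) next
    kids <- childrenOf[[cl]]
    if (is.null(kids)) next
    subtree <- sum(stability[kids])
    if (subtree > stability[cl]) {
      stability[cl] <- subtree
      isCluster[cl] <- FALSE
    } else {
      # keep cl: deselect every descendant
      stack <- kids
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        isCluster[v] <- FALSE
        stack <- c(stack, childrenOf[[v]])
      }
    }
  }
  isCluster
}

## Map every point to its nearest selected ancestor cluster (NA = noise).
labelPoints <- function(ct, selected, n) {
  labels <- rep(NA_integer_, n)
  if (!any(selected)) {
    # degenerate data with no surviving split: the root is the one cluster
    if (length(ct$edges) == 0L) labels[ct$points$point] <- 1L
    return(labels)
  }
  up <- function(cl) {
    while (cl != 0L) {
      if (selected[cl]) return(as.integer(cl))
      cl <- ct$parentC[cl]
    }
    0L
  }
  anc <- vapply(seq_len(ct$nClusters), up, integer(1))
  ids <- sort(unique(anc[anc > 0L]))
  for (i in seq_len(nrow(ct$points))) {
    a <- anc[ct$points$parent[i]]
    if (a > 0L) labels[ct$points$point[i]] <- match(a, ids)
  }
  labels
}
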
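## Complete-linkage hierarchical clustering of abundance profiles (heatmap
## row order) and the within-sum-of-squares rule used to delineate vOTU
## guild clusters.  Implemented agglomeratively with an explicit
## deterministic tie-break so that leaf order does not depend on input
## order or on library internals; stats::hclust serves as a cross-check in
## the tests.

#' Log-transform a relative abundance matrix for profile clustering
#'
#' `log10(x + offset)` where the default offset is the smallest nonzero
#' value divided by 10, keeping zeros below every observed abundance on the
#' log scale.
#'
#' @param m features-by-samples matrix of relative abundances
#' @param offset pseudo-count; default smallest nonzero value / 10
#' @return transformed matrix
#' @export
logRelative <- function(m, offset = NULL) {
  m <- as.matrix(m)
  if (is.null(offset)) {
    nz <- m[m > 0]
    if (!length(nz)) stop("all-zero matrix")
    offset <- min(nz) / 10
  }
  log10(m + offset)
}

#' Complete-linkage agglomerative clustering
#'
#' Euclidean distance between feature profiles (rows), complete (maximum)
#' linkage, deterministic tie-breaking by smallest cluster index.  Returns a
#' base-R `hclust` object (so `cutree()` and plotting work), with the leaf
#' order derived from a left-before-right traversal of the merge tree.
#'
#' @param profiles features-by-samples numeric matrix (transform first with
#'   [logRelative()] when clustering relative abundances)
#' @return an object of class `hclust`
#' @export
hclustComplete <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least two features")
  if (!is.null(rownames(profiles))) {
    ## canonical row order makes the result invariant to input order
    profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  }
  labels <- rownames(profiles)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- as.matrix(stats::dist(profiles))
  ## active clusters are tracked by their creation index: singletons are
  ## -1..-n (hclust convention), merges 1..n-1
  active <- as.list(seq_len(n))      # member rows per active cluster
  ids <- -seq_len(n)                 # hclust node id per active cluster
  cd <- d                            # complete-linkage distances
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        if (cd[i, j] < bestd - 1e-12) {
          bestd <- cd[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- bestd
    ## complete linkage: distance of the merged cluster to any other is the
    ## max of the two previous distances
    newrow <- pmax(cd[i, ], cd[j, ])[-c(i, j)]
    cd <- cd[-c(i, j), -c(i, j), drop = FALSE]
    cd <- rbind(cbind(cd, newrow), c(newrow, 0))
    active[[i]] <- c(active[[i]], active[[j]])
    merged <- active[[i]]
    active <- active[-c(i, j)]
    active[[length(active) + 1]] <- merged
    ids <- c(ids[-c(i, j)], step)
  }
  order <- .leafOrder(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "complete",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

.leafOrder <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Within-sum-of-squares curve and elbow cluster count
#'
#' Cuts the complete-linkage dendrogram into k = 1..kMax clusters; the WSS
#' at k is the total squared Euclidean distance of each profile to its
#' cluster centroid.  The chosen k is the elbow, i.e. the k maximizing the
#' second difference of the WSS curve.
#'
#' @param profiles features-by-samples matrix (same transform as used for
#'   clustering)
#' @param kMax maximum number of clusters to examine (< number of features)
#' @param hc optional precomputed [hclustComplete()] result
#' @return list with `wss` (length kMax), `k` (chosen count) and
#'   `clusters` (membership at the chosen k)
#' @export
wssClusterCount <- function(profiles, kMax, hc = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  stopifnot(kMax < n, kMax >= 1)
  if (is.null(hc)) hc <- hclustComplete(profiles)
  wss <- vapply(seq_len(kMax), function(k) {
    cl <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(n), cl), function(idx) {
      centroid <- colMeans(profiles[idx, , drop = FALSE])
      sum(sweep(profiles[idx, , drop = FALSE], 2, centroid)^2)
    }, numeric(1)))
  }, numeric(1))
  if (kMax >= 3) {
    second <- wss[seq_len(kMax - 2)] - 2 * wss[seq.int(2, kMax - 1)] +
      wss[seq.int(3, kMax)]
    k <- which.max(second) + 1L
  } else {
    k <- kMax
  }
  list(wss = wss, k = k, clusters = stats::cutree(hc, k = k))
}
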
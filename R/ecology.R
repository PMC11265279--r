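## Diversity, ordination and permutation statistics, implemented from first
## principles.  Established implementations (vegan, base R) serve as
## independent cross-checks in the test suite, never as the computation
## path.

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \log p_i} with the convention \eqn{0 \log 0 = 0}.
#' Natural log by default: over ~150 effective taxa the index then falls in
#' the 2.5-3.5 range typical of cheese surface viromes.
#'
#' @param p relative-abundance vector (sums to 1), or a `ViromeCounts` in
#'   state `relative` (one index per sample)
#' @param base logarithm base (default `exp(1)`, i.e. nats)
#' @return numeric scalar, or named vector for a table
#' @export
shannonIndex <- function(p, base = exp(1)) {
  if (is(p, "ViromeCounts")) {
    .assertState(p, "relative", "shannonIndex")
    m <- countValues(p)
    return(apply(m, 2, shannonIndex, base = base))
  }
  if (any(p < 0)) stop("negative abundance")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{\sum |x_i - y_i| / \sum (x_i + y_i)}.
#'
#' @param x,y non-negative abundance vectors of equal length
#' @return dissimilarity in \[0, 1\]
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix over the samples of a table
#'
#' @param x `ViromeCounts` (any state) or a features-by-samples matrix
#' @return symmetric matrix with zero diagonal, sample ids as dimnames
#' @export
brayCurtisMatrix <- function(x) {
  m <- if (is(x, "ViromeCounts")) countValues(x) else as.matrix(x)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- brayCurtis(m[, i], m[, j])
    }
  }
  d
}

.asDistMatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \eqn{-d^2/2}, eigendecomposes, and keeps the
#' positive-eigenvalue axes ordered by eigenvalue.  Bray-Curtis is
#' semi-metric, so negative eigenvalues can occur; they are dropped and the
#' explained-variance fractions are computed over the positive eigenvalues
#' only.
#'
#' @param d symmetric distance matrix
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `explained` (fractions)
#' @export
pcoaOrdination <- function(d) {
  d <- .asDistMatrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- centering %*% a %*% centering
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  if (!length(pos)) {
    warning("degenerate distance matrix: no positive eigenvalues")
    return(list(coordinates = matrix(0, n, 0,
                                     dimnames = list(rownames(d), NULL)),
                eigenvalues = numeric(0), explained = numeric(0)))
  }
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_along(pos)))
  list(coordinates = coords, eigenvalues = e$values[pos],
       explained = e$values[pos] / sum(e$values[pos]))
}

## within/total sums of squared distances for a grouping (PERMANOVA core)
.permanovaF <- function(d2, groupIdx, nGroups, groupSizes, n) {
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in seq_len(nGroups)) {
    idx <- groupIdx[[g]]
    sub <- d2[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / groupSizes[g]
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (nGroups - 1)) / (ss_within / (n - nGroups))
  c(F = f, R2 = ss_between / ss_total)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix.  The pseudo-F is computed from sums of squared dissimilarities
#' (total SS = sum of squared distances over n; within SS summed per group)
#' and the p-value from free permutation of the group labels with the
#' estimator \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, so p can never be
#' 0.
#'
#' @param d symmetric distance matrix
#' @param groups group label per sample (>= 2 groups, each non-empty)
#' @param nPerm number of label permutations
#' @param seed optional integer seed
#' @return list with `pseudo_F`, `R2`, `p`, `n_permutations`
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = NULL) {
  d <- .asDistMatrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least two groups")
  if (any(table(groups) < 1)) stop("empty group")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  d2 <- d^2
  splitIdx <- function(g) split(seq_len(n), factor(g, levels = lev))
  sizes <- as.integer(table(factor(groups, levels = lev)))
  obs <- .permanovaF(d2, splitIdx(groups), length(lev), sizes, n)
  count <- 0L
  for (b in seq_len(nPerm)) {
    perm <- groups[sample.int(n)]
    f <- .permanovaF(d2, splitIdx(perm), length(lev), sizes, n)[["F"]]
    if (f >= obs[["F"]]) count <- count + 1L
  }
  list(pseudo_F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
       p = (1 + count) / (1 + nPerm), n_permutations = nPerm)
}

#' Mantel test between two distance matrices
#'
#' Rank (Spearman, default) or Pearson correlation of the strictly lower
#' triangles; the p-value permutes the rows/columns of `d2` jointly,
#' one-sided for positive association, with the \eqn{(1+c)/(1+n)}
#' estimator.
#'
#' @param d1,d2 symmetric distance matrices over the same samples (same
#'   order)
#' @param nPerm number of permutations
#' @param seed optional integer seed
#' @param method `"spearman"` (default) or `"pearson"`
#' @return list with `r`, `p`, `n_permutations`
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = NULL,
                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  d1 <- .asDistMatrix(d1); d2 <- .asDistMatrix(d2)
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 samples")
  stopifnot(nrow(d2) == n)
  if (!is.null(seed)) set.seed(seed)
  low <- lower.tri(d1)
  v1 <- d1[low]
  if (method == "spearman") {
    v1 <- rank(v1)
    ## joint row/column permutation preserves the multiset of off-diagonal
    ## values, so ranking the matrix once is exact
    r2m <- matrix(0, n, n)
    r2m[low] <- rank(d2[low])
    r2m <- r2m + t(r2m)  # mirror ranks into the upper triangle
  } else {
    r2m <- d2
  }
  v2 <- r2m[low]
  robs <- stats::cor(v1, v2)
  count <- 0L
  for (b in seq_len(nPerm)) {
    perm <- sample.int(n)
    count <- count + (stats::cor(v1, r2m[perm, perm][low]) >= robs)
  }
  list(r = robs, p = (1 + count) / (1 + nPerm), n_permutations = nPerm)
}

#' Kruskal-Wallis rank-sum statistic
#'
#' Rank-based H with the tie correction, p-value from the chi-square
#' approximation with (number of groups - 1) degrees of freedom.  All
#' values identical gives H = 0, p = 1.
#'
#' @param values numeric vector
#' @param groups group label per value (>= 2 groups)
#' @return list with `H`, `df`, `p`
#' @export
kruskalWallisTest <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least two groups")
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(z) length(z) * mean(z)^2)) -
    3 * (n + 1)
  ## tie correction
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {
    return(list(H = 0, df = length(lev) - 1, p = 1))
  }
  h <- h / correction
  df <- length(lev) - 1
  list(H = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Spearman correlation table between two abundance tables
#'
#' Correlates every feature of `a` (e.g. phage groups) with every feature of
#' `b` (e.g. bacterial genera) across the shared samples, with average-rank
#' tie handling.  Zero-variance features yield `NA` (undefined), never 0.
#'
#' @param a,b features-by-samples matrices or `ViromeCounts` over the same
#'   samples (same order)
#' @return matrix of Spearman r, rows = features of `a`, columns = features
#'   of `b`
#' @export
spearmanMatrix <- function(a, b) {
  ma <- if (is(a, "ViromeCounts")) countValues(a) else as.matrix(a)
  mb <- if (is(b, "ViromeCounts")) countValues(b) else as.matrix(b)
  if (ncol(ma) != ncol(mb)) stop("tables must share the same samples")
  if (!is.null(colnames(ma)) && !is.null(colnames(mb)) &&
      !identical(colnames(ma), colnames(mb))) {
    stop("tables must share the same samples in the same order")
  }
  ra <- t(apply(ma, 1, rank))
  rb <- t(apply(mb, 1, rank))
  out <- matrix(NA_real_, nrow(ma), nrow(mb),
                dimnames = list(rownames(ma), rownames(mb)))
  for (i in seq_len(nrow(ma))) {
    if (stats::var(ra[i, ]) == 0) next
    for (j in seq_len(nrow(mb))) {
      if (stats::var(rb[j, ]) == 0) next
      out[i, j] <- stats::cor(ra[i, ], rb[j, ])
    }
  }
  out
}
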
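## Negative-binomial Wald differential abundance (median-of-ratios
## normalization, method-of-moments dispersion with trend shrinkage,
## per-feature NB log-linear model fitted by IRLS).  Deliberate
## simplifications relative to full DESeq2: no Cox-Reid adjustment, no
## outlier (Cook's distance) handling, no independent filtering.  The test
## surface is calibration and recovery on synthetic data, not bit-equality
## with DESeq2.  The analysis always starts from RAW counts -- the
## normalization is built in.

#' Differential abundance configuration
#'
#' Defaults follow a strict adjusted-p cutoff of 0.01; a 0.05 variant is
#' available through `padjCutoff`.
#'
#' @param padjCutoff BH-adjusted p-value cutoff
#' @param lfcCutoff two-sided log2 fold-change cutoff (significant requires
#'   `|log2fc| > lfcCutoff`)
#' @param minMeanRawCount average raw count across all samples must be
#'   strictly above this
#' @param dispersionFloor lower bound for dispersion estimates
#' @param shrinkWeight weight of the gene-wise estimate in the shrunk
#'   dispersion (remainder goes to the fitted trend)
#' @return list of class `DAConfig`
#' @export
daConfig <- function(padjCutoff = 0.01, lfcCutoff = 3,
                     minMeanRawCount = 1500, dispersionFloor = 1e-8,
                     shrinkWeight = 0.5) {
  stopifnot(padjCutoff > 0, lfcCutoff > 0, minMeanRawCount >= 0,
            dispersionFloor > 0, shrinkWeight >= 0, shrinkWeight <= 1)
  structure(list(padjCutoff = padjCutoff, lfcCutoff = lfcCutoff,
                 minMeanRawCount = minMeanRawCount,
                 dispersionFloor = dispersionFloor,
                 shrinkWeight = shrinkWeight),
            class = "DAConfig")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (restricted to features with
#' all-positive counts) of the ratio of the sample's count to the feature's
#' geometric mean across samples.
#'
#' @param x `ViromeCounts` in state `raw`, or a raw count matrix
#' @return named numeric vector of per-sample factors
#' @export
sizeFactors <- function(x) {
  m <- if (is(x, "ViromeCounts")) {
    .assertState(x, "raw", "sizeFactors")
    countValues(x)
  } else {
    as.matrix(x)
  }
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stop("no feature with positive counts in every sample; ",
         "consider a pseudo-reference fallback")
  }
  logm <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
}

#' Method-of-moments dispersion estimation with trend shrinkage
#'
#' Gene-wise estimate on normalized counts
#' \eqn{\alpha_i = \max(floor, (s_i^2 - \bar\mu_i) / \bar\mu_i^2)}, a mean
#' dispersion trend \eqn{\bar\alpha(\mu) = a/\mu + b} fitted by least
#' squares over all features, and a weighted combination of the two
#' (gene-wise weight `shrinkWeight`).  With fewer than 3 features the trend
#' is skipped and gene-wise estimates are used.
#'
#' @param x `ViromeCounts` in state `raw` or raw count matrix
#' @param factors size factors from [sizeFactors()]
#' @param config a [daConfig()]
#' @return named vector of per-feature dispersions
#' @export
estimateDispersion <- function(x, factors = sizeFactors(x),
                               config = daConfig()) {
  m <- if (is(x, "ViromeCounts")) countValues(x) else as.matrix(x)
  norm <- sweep(m, 2, factors, "/")
  mu <- rowMeans(norm)
  s2 <- apply(norm, 1, stats::var)
  gene <- ifelse(mu > 0, pmax(config$dispersionFloor, (s2 - mu) / mu^2),
                 config$dispersionFloor)
  if (nrow(m) < 3) return(setNames(gene, rownames(m)))
  ## trend alpha(mu) = a/mu + b via least squares on informative features
  use <- mu > 0 & gene > config$dispersionFloor
  if (sum(use) >= 3) {
    fit <- stats::lm.fit(cbind(1 / mu[use], 1), gene[use])
    trend <- pmax(config$dispersionFloor,
                  fit$coefficients[1] / mu + fit$coefficients[2])
    trend[!is.finite(trend)] <- config$dispersionFloor
  } else {
    trend <- rep(stats::median(gene), length(gene))
  }
  shrunk <- pmax(config$dispersionFloor,
                 config$shrinkWeight * gene +
                   (1 - config$shrinkWeight) * trend)
  setNames(shrunk, rownames(m))
}

## IRLS fit of the two-group NB log-linear model for a single feature:
## log mu_j = log s_j + b0 + b1 * x_j, dispersion alpha known.
.nbWaldOne <- function(y, sf, xg, alpha, maxIter = 100, tol = 1e-8) {
  if (all(y == 0)) {
    return(c(log2fc = 0, se = NA, stat = 0, p = 1, converged = 1))
  }
  X <- cbind(1, xg)
  off <- log(sf)
  beta <- c(log(max(mean(y / sf), 1e-8)), 0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- off + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- (eta - off) + (y - mu) / mu
    xtw <- t(X * w)
    newbeta <- tryCatch(solve(xtw %*% X, xtw %*% z),
                        error = function(e) NULL)
    if (is.null(newbeta) || any(!is.finite(newbeta))) break
    newbeta <- pmin(pmax(as.vector(newbeta), -50), 50)
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta
      converged <- TRUE
      break
    }
    beta <- newbeta
  }
  if (!converged) {
    return(c(log2fc = 0, se = NA, stat = 0, p = 1, converged = 0))
  }
  eta <- off + X %*% beta
  mu <- pmin(exp(eta), 1e12)
  w <- as.vector(mu / (1 + alpha * mu))
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  if (is.null(cov) || cov[2, 2] <= 0) {
    return(c(log2fc = 0, se = NA, stat = 0, p = 1, converged = 0))
  }
  se <- sqrt(cov[2, 2])
  stat <- beta[2] / se
  c(log2fc = beta[2] / log(2), se = se / log(2), stat = stat,
    p = 2 * stats::pnorm(-abs(stat)), converged = 1)
}

#' Per-feature negative binomial Wald test between two groups
#'
#' Fits `mean = s_j * exp(b0 + b1 * group_j)` by iteratively reweighted
#' least squares with known per-feature dispersion; the Wald statistic is
#' `b1 / SE(b1)` with a two-sided normal p-value.  The reference level is
#' the alphabetically first group (configurable), so a positive log2 fold
#' change means more abundant in the second group.
#'
#' @param x `ViromeCounts` in state `raw` or raw count matrix
#' @param groups two-level label per sample
#' @param factors size factors
#' @param dispersions per-feature dispersions
#' @param reference reference group (default alphabetically first)
#' @return `data.frame` with `feature_id`, `base_mean`, `log2fc`,
#'   `wald_stat`, `p`, `converged`
#' @export
nbWaldTest <- function(x, groups, factors = NULL, dispersions = NULL,
                       reference = NULL) {
  m <- if (is(x, "ViromeCounts")) {
    .assertState(x, "raw", "nbWaldTest")
    countValues(x)
  } else {
    as.matrix(x)
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(reference)) reference <- lev[1]
  stopifnot(reference %in% lev)
  xg <- as.numeric(groups != reference)
  if (is.null(factors)) factors <- sizeFactors(m)
  if (is.null(dispersions)) {
    dispersions <- estimateDispersion(m, factors)
  }
  norm <- sweep(m, 2, factors, "/")
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    .nbWaldOne(m[i, ], factors, xg, dispersions[i])
  }, numeric(5)))
  data.frame(
    feature_id = rownames(m),
    base_mean = rowMeans(norm),
    mean_raw = rowMeans(m),
    log2fc = res[, "log2fc"],
    wald_stat = res[, "stat"],
    p = res[, "p"],
    converged = res[, "converged"] == 1,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment: sort p ascending, `padj_(i) = min_{k >= i}
#' p_(k) * m / k`, capped at 1, mapped back to the input order.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Apply the significance rule
#'
#' A feature is significant iff `padj < padjCutoff` AND
#' `|log2fc| > lfcCutoff` AND mean raw count `> minMeanRawCount`.
#'
#' @param results data.frame from [nbWaldTest()] (a `padj` column is added
#'   if missing)
#' @param config a [daConfig()]
#' @return results with `padj` and logical `significant` columns
#' @export
callSignificant <- function(results, config = daConfig()) {
  if (is.null(results$padj)) results$padj <- bhAdjust(results$p)
  results$significant <- results$padj < config$padjCutoff &
    abs(results$log2fc) > config$lfcCutoff &
    results$mean_raw > config$minMeanRawCount
  results
}

#' Full differential abundance analysis between two sample groups
#'
#' Median-of-ratios size factors, dispersion estimation, per-feature NB
#' Wald test, BH correction and the three-part significance rule.
#'
#' @param x `ViromeCounts` in state `raw`
#' @param groups two-level label per sample (defaults to the `group`
#'   metadata column)
#' @param config a [daConfig()]
#' @param reference reference group (see [nbWaldTest()])
#' @return `data.frame` of per-feature results, sorted by p-value
#' @export
differentialAbundance <- function(x, groups = NULL, config = daConfig(),
                                  reference = NULL) {
  .assertState(x, "raw", "differentialAbundance")
  if (is.null(groups)) groups <- sampleGroups(x)
  factors <- sizeFactors(x)
  disp <- estimateDispersion(x, factors, config)
  res <- nbWaldTest(x, groups, factors, disp, reference)
  res <- callSignificant(res, config)
  .cv_log(sprintf(
    "differential abundance: %d / %d significant (padj < %g, |lfc| > %g, mean > %g)",
    sum(res$significant), nrow(res), config$padjCutoff, config$lfcCutoff,
    config$minMeanRawCount))
  res[order(res$p), ]
}
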
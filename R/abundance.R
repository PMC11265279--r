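## Normalization chain: raw counts -> rarefied -> coverage (per-bp) ->
## relative (TSS).  Each step asserts the state it requires, and the
## short-term and long-term arms are meant to be rarefied independently
## (each to the minimum depth observed in one of its own samples).

#' Rarefy a raw count table
#'
#' Per sample, reads are subsampled without replacement to the target depth
#' with the current RNG stream (set a seed for reproducibility).  With
#' `depth = "min_sample"` the target is the minimum sample total of the
#' table.
#'
#' @param x `ViromeCounts` in state `raw`
#' @param depth `"min_sample"` or an integer depth
#' @param seed optional integer seed applied before subsampling
#' @return `ViromeCounts` in state `rarefied`; all sample totals equal the
#'   depth
#' @export
rarefyCounts <- function(x, depth = "min_sample", seed = NULL) {
  .assertState(x, "raw", "rarefyCounts")
  m <- countValues(x)
  totals <- colSums(m)
  if (identical(depth, "min_sample")) {
    depth <- min(totals)
  }
  depth <- as.integer(depth)
  too_small <- totals < depth
  if (any(too_small)) {
    stop("sample(s) below requested depth ", depth, ": ",
         paste(colnames(m)[too_small], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  ## vegan expects samples in rows
  rar <- t(vegan::rrarefy(t(m), depth))
  dimnames(rar) <- dimnames(m)
  .cv_log(sprintf("rarefied %d samples to depth %d", ncol(m), depth))
  out <- ViromeCounts(rar, sampleData = sampleData(x), state = "rarefied")
  out
}

#' Length normalization (mean coverage per vOTU)
#'
#' Divides each feature's rarefied counts by its length in bp, yielding the
#' mean per-base coverage of the vOTU in each sample.
#'
#' @param x `ViromeCounts` in state `rarefied`
#' @param lengths named numeric vector, bp per feature (all features
#'   required, all positive)
#' @return `ViromeCounts` in state `coverage`
#' @export
lengthNormalize <- function(x, lengths) {
  .assertState(x, "rarefied", "lengthNormalize")
  m <- countValues(x)
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss)) {
    stop("missing length for feature(s): ", paste(miss, collapse = ", "))
  }
  lens <- lengths[rownames(m)]
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("feature lengths must be positive and finite")
  }
  ViromeCounts(m / lens, sampleData = sampleData(x), state = "coverage")
}

#' Total-sum scaling
#'
#' Divides each sample's vector by its sum so that samples sum to 1.
#'
#' @param x `ViromeCounts` in state `coverage` (or `rarefied` for the
#'   read-proportion path used by group-level abundances, which skips the
#'   genome-size normalization)
#' @return `ViromeCounts` in state `relative`
#' @export
tssNormalize <- function(x) {
  .assertState(x, c("coverage", "rarefied", "relative"), "tssNormalize")
  m <- countValues(x)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  ViromeCounts(sweep(m, 2, cs, "/"), sampleData = sampleData(x),
               state = "relative")
}

#' Mean relative-abundance filter
#'
#' Keeps features whose arithmetic-mean relative abundance across all
#' samples of the table is strictly above `threshold` (default 5e-5, i.e.
#' 0.005\%).
#'
#' @param x `ViromeCounts` in state `relative`
#' @param threshold fraction in \[0, 1)
#' @return filtered `ViromeCounts` (still state `relative`; samples are NOT
#'   re-scaled, mirroring common practice of filtering after normalization)
#' @export
filterMeanAbundance <- function(x, threshold = 5e-5) {
  .assertState(x, "relative", "filterMeanAbundance")
  m <- countValues(x)
  keep <- rowMeans(m) > threshold
  .cv_log(sprintf("abundance filter (mean > %g): kept %d / %d features",
                  threshold, sum(keep), nrow(m)))
  ## retained features keep their community-wide relative abundances; a
  ## synthetic `.other` remainder row preserves the sum-to-1 invariant
  new("ViromeCounts", .filteredRelativeSE(m[keep, , drop = FALSE], x),
      state = "relative")
}

## a filtered relative table keeps its original scale; pad with a synthetic
## remainder row so the relative-state invariant (samples sum to 1) holds
.filteredRelativeSE <- function(m, x) {
  rem <- pmax(1 - colSums(m), 0)
  if (any(rem > 1e-12)) {
    m <- rbind(m, `.other` = rem)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = SummarizedExperiment::colData(x))
}

#' Drop the `.other` remainder row added by [filterMeanAbundance()]
#'
#' @param x filtered `ViromeCounts`
#' @return matrix of the retained features' relative abundances
#' @export
abundanceValues <- function(x) {
  m <- countValues(x)
  m[setdiff(rownames(m), ".other"), , drop = FALSE]
}

#' Sparsity of a count table
#'
#' Fraction of zero cells in the matrix.
#'
#' @param x `ViromeCounts` (any state) or a plain matrix
#' @return fraction in \[0, 1\]
#' @export
sparsity <- function(x) {
  m <- if (is(x, "ViromeCounts")) countValues(x) else as.matrix(x)
  sum(m == 0) / length(m)
}

#' Aggregate features into labelled groups
#'
#' Sums the relative abundances of features sharing a label (e.g. phage
#' group); samples still sum to 1.  Unlabelled features should be passed
#' with the label `"unassigned"`.
#'
#' @param x `ViromeCounts` in state `relative`
#' @param labels named character vector mapping every feature id to a group
#'   label
#' @return group-level `ViromeCounts` in state `relative`
#' @export
aggregateByGroup <- function(x, labels) {
  .assertState(x, "relative", "aggregateByGroup")
  m <- countValues(x)
  miss <- setdiff(rownames(m), names(labels))
  if (length(miss)) {
    stop("unlabelled feature(s): ", paste(miss, collapse = ", "))
  }
  lab <- labels[rownames(m)]
  agg <- rowsum(m, group = lab)
  ViromeCounts(agg, sampleData = sampleData(x), state = "relative")
}
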
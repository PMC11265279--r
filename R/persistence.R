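## Presence/absence persistence of vOTUs across production years: Venn
## partition of the three year sets, shared-fraction percentages, and the
## core virome (abundant vOTUs detected in every year).

#' Presence/absence of features per group of samples
#'
#' A feature is present in a group (typically a production year) when its
#' value strictly exceeds `threshold` in at least one sample of the group.
#' The default threshold 0 equates detection with nonzero mapping, matching
#' the use of the unfiltered data set for year-sharing analyses.
#'
#' @param x `ViromeCounts` (any state) or features-by-samples matrix
#' @param groups group label per sample (defaults to the `group` metadata
#'   column)
#' @param threshold detection threshold (strict)
#' @return logical matrix, features x groups
#' @export
presenceAbsence <- function(x, groups = NULL, threshold = 0) {
  m <- if (is(x, "ViromeCounts")) countValues(x) else as.matrix(x)
  if (is.null(groups)) groups <- sampleGroups(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  lev <- sort(unique(groups))
  out <- vapply(lev, function(g) {
    rowSums(m[, groups == g, drop = FALSE] > threshold) > 0
  }, logical(nrow(m)))
  dimnames(out) <- list(rownames(m), lev)
  out
}

#' Venn partition of three presence sets
#'
#' Counts of the 7 nonempty subsets of the three groups, the total number
#' of detected features, and the shared-in-all and shared-in-at-least-two
#' percentages (rounded half-up to one decimal).
#'
#' @param binary logical features-by-groups matrix with exactly 3 columns
#'   (e.g. from [presenceAbsence()])
#' @return list with `counts` (named vector over the 7 regions), `total`,
#'   `pct_all_three`, `pct_two_plus`
#' @export
vennPartition <- function(binary) {
  binary <- as.matrix(binary)
  if (ncol(binary) != 3) stop("exactly 3 groups required")
  g <- colnames(binary)
  if (is.null(g)) g <- c("A", "B", "C")
  detected <- rowSums(binary) > 0
  b <- binary[detected, , drop = FALSE]
  region <- paste0(ifelse(b[, 1], "1", "0"), ifelse(b[, 2], "1", "0"),
                   ifelse(b[, 3], "1", "0"))
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  names(keys) <- c(g[1], g[2], g[3],
                   paste(g[1], g[2], sep = "&"), paste(g[1], g[3], sep = "&"),
                   paste(g[2], g[3], sep = "&"), paste(g, collapse = "&"))
  counts <- vapply(keys, function(k) sum(region == k), integer(1))
  total <- sum(detected)
  n_all <- counts[[paste(g, collapse = "&")]]
  n_two <- sum(counts[vapply(keys, function(k) {
    sum(strsplit(k, "")[[1]] == "1") >= 2
  }, logical(1))])
  list(counts = counts, total = total,
       n_all_three = n_all, n_two_plus = n_two,
       pct_all_three = .roundHalfUp(100 * n_all / total),
       pct_two_plus = .roundHalfUp(100 * n_two / total))
}

#' Core virome
#'
#' Features passing the mean relative-abundance filter AND present in all
#' three production years.
#'
#' @param x `ViromeCounts` in state `relative` (full, unfiltered table)
#' @param binary presence matrix from [presenceAbsence()] (3 groups)
#' @param threshold mean relative-abundance filter (strict), default 5e-5
#' @return character vector of core feature ids
#' @export
coreVirome <- function(x, binary, threshold = 5e-5) {
  .assertState(x, "relative", "coreVirome")
  m <- countValues(x)
  abundant <- rownames(m)[rowMeans(m) > threshold]
  everywhere <- rownames(binary)[rowSums(binary) == ncol(binary)]
  sort(intersect(abundant, everywhere))
}
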
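#' ViromeCounts: a sample-by-vOTU count container with a normalization state
#'
#' `ViromeCounts` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay (`"counts"`, features in rows, samples in columns) and an
#' explicit normalization-state flag.  Every downstream operation asserts the
#' state it requires, so a rarefied table can never be fed to the differential
#' abundance test (which starts from raw counts) and a raw table can never be
#' mistaken for relative abundances.
#'
#' Valid states are:
#' \describe{
#'   \item{`raw`}{integer read counts as produced by mapping/counting.}
#'   \item{`rarefied`}{integer counts after subsampling to a common depth.}
#'   \item{`coverage`}{rarefied counts divided by feature length (mean
#'     coverage per vOTU).}
#'   \item{`relative`}{total-sum-scaled values; every sample sums to 1.}
#' }
#'
#' Sample metadata live in `colData` and typically carry `study`
#' (`short_term` / `long_term`), `group` (ripening stage `W1`..`W5` or
#' production year `2017`/`2019`/`2022`) and `replicate` (`A`/`B`/`C`).
#'
#' @slot state character scalar, one of `raw`, `rarefied`, `coverage`,
#'   `relative`.
#'
#' @seealso [ViromeCounts()] for the constructor, [normState()],
#'   [rarefyCounts()], [tssNormalize()].
#' @export
setClass("ViromeCounts",
  contains = "SummarizedExperiment",
  representation(state = "character"),
  prototype(state = "raw")
)

.VALID_STATES <- c("raw", "rarefied", "coverage", "relative")

.validViromeCounts <- function(object) {
  msg <- NULL
  st <- object@state
  if (length(st) != 1L || !st %in% .VALID_STATES) {
    msg <- c(msg, sprintf(
      "state must be one of %s", paste(.VALID_STATES, collapse = ", ")))
    return(msg)
  }
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return(c(msg, "assay 'counts' is required"))
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  if (st %in% c("raw", "rarefied") &&
      any(abs(m - round(m)) > 1e-8)) {
    msg <- c(msg, sprintf("state '%s' requires integer counts", st))
  }
  if (st == "relative") {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9)) {
      msg <- c(msg, "state 'relative' requires every sample to sum to 1")
    }
  }
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicated sample ids")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicated feature ids")
  if (is.null(msg)) TRUE else msg
}

setValidity("ViromeCounts", .validViromeCounts)

#' Construct a ViromeCounts object
#'
#' @param counts numeric matrix, features (vOTUs or genera) in rows, samples
#'   in columns; both dimnames required.
#' @param sampleData `data.frame` of per-sample metadata (rownames or a
#'   `sample_id` column matching `colnames(counts)`), or `NULL`.
#' @param state normalization state, see [ViromeCounts-class].
#' @return a [ViromeCounts-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 2,
#'             dimnames = list(c("v1", "v2"), c("s1", "s2", "s3")))
#' vc <- ViromeCounts(m, state = "raw")
#' normState(vc)
#' @export
ViromeCounts <- function(counts, sampleData = NULL, state = "raw") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if (!is.null(sampleData$sample_id) && is.null(rownames(sampleData))) {
      rownames(sampleData) <- sampleData$sample_id
    }
    missing <- setdiff(colnames(counts), rownames(sampleData))
    extra <- setdiff(rownames(sampleData), colnames(counts))
    if (length(missing) || length(extra)) {
      stop("sample mismatch between counts and metadata: ",
           paste(c(missing, extra), collapse = ", "))
    }
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
    cd <- S4Vectors::DataFrame(sampleData)
  } else {
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("ViromeCounts", se, state = state)
}

#' @describeIn ViromeCounts-class normalization state of the table
#' @param x a `ViromeCounts` object
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))

#' @rdname ViromeCounts-class
#' @export
setMethod("normState", "ViromeCounts", function(x) x@state)

#' @describeIn ViromeCounts-class replace the state (re-validates)
#' @param value new state
#' @export
setGeneric("normState<-", function(x, value) standardGeneric("normState<-"))

#' @rdname ViromeCounts-class
#' @export
setMethod("normState<-", "ViromeCounts", function(x, value) {
  x@state <- value
  validObject(x)
  x
})

#' @describeIn ViromeCounts-class the counts matrix (features x samples)
#' @export
countValues <- function(x) {
  stopifnot(is(x, "ViromeCounts"))
  SummarizedExperiment::assay(x, "counts")
}

#' @describeIn ViromeCounts-class per-sample metadata as a data.frame
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn ViromeCounts-class group label (stage or year) per sample
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd)) stop("no 'group' column in sample metadata")
  as.character(cd$group)
}

setMethod("show", "ViromeCounts", function(object) {
  m <- countValues(object)
  cat(sprintf("ViromeCounts: %d features x %d samples [state: %s]\n",
              nrow(m), ncol(m), object@state))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) {
    cat("sample metadata:", paste(colnames(cd), collapse = ", "), "\n")
  }
})

## asserts used by downstream modules
.assertState <- function(x, required, what) {
  if (!is(x, "ViromeCounts")) stop(what, " requires a ViromeCounts object")
  if (!normState(x) %in% required) {
    stop(sprintf("%s requires state %s, got '%s'",
                 what, paste(sQuote(required), collapse = " or "),
                 normState(x)))
  }
  invisible(TRUE)
}

#' VOTUCatalog: the dereplicated species-level vOTU catalog
#'
#' Holds one row per vOTU (representative contig) together with the full
#' accounting of what happened to every input contig, so that each contig is
#' attributed to exactly one fate: `member_of_votu`, `discarded_short`,
#' `discarded_chimera`, `discarded_nonviral` or `discarded_phix`.
#'
#' @slot votus `data.frame` with columns `representative_id`, `length`,
#'   `n_members`, `quality`, `lifestyle`, `host_genus`, `dairy_phage`,
#'   `dairy_score`, `phage_group`.
#' @slot members named list: representative id -> character vector of member
#'   contig ids (the representative included).
#' @slot accounting `data.frame` with columns `contig_id`, `fate`,
#'   `votu` (representative id or `NA`).
#' @seealso [buildCatalog()], [summarizeCatalog()]
#' @export
setClass("VOTUCatalog",
  representation(votus = "data.frame", members = "list",
                 accounting = "data.frame"))

.validVOTUCatalog <- function(object) {
  msg <- NULL
  need <- c("representative_id", "length")
  if (!all(need %in% colnames(object@votus))) {
    msg <- c(msg, "votus table must have representative_id and length")
  }
  if (nrow(object@votus)) {
    if (!setequal(object@votus$representative_id, names(object@members))) {
      msg <- c(msg, "members list out of step with votus table")
    }
    ok <- vapply(seq_len(nrow(object@votus)), function(i) {
      object@votus$representative_id[i] %in%
        object@members[[object@votus$representative_id[i]]]
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "each representative must be its own member")
  }
  if (nrow(object@accounting) &&
      anyDuplicated(object@accounting$contig_id)) {
    msg <- c(msg, "every contig must be accounted for exactly once")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("VOTUCatalog", .validVOTUCatalog)

setMethod("show", "VOTUCatalog", function(object) {
  cat(sprintf("VOTUCatalog: %d vOTUs (%d input contigs)\n",
              nrow(object@votus),
              nrow(object@accounting)))
  if (nrow(object@accounting)) {
    print(table(object@accounting$fate))
  }
})

#' @describeIn VOTUCatalog-class the per-vOTU table
#' @param x a `VOTUCatalog`
#' @export
votuTable <- function(x) {
  stopifnot(is(x, "VOTUCatalog"))
  x@votus
}

#' @describeIn VOTUCatalog-class member contig ids per representative
#' @export
votuMembers <- function(x) {
  stopifnot(is(x, "VOTUCatalog"))
  x@members
}

#' @describeIn VOTUCatalog-class per-contig fate accounting
#' @export
contigAccounting <- function(x) {
  stopifnot(is(x, "VOTUCatalog"))
  x@accounting
}
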
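## Pairwise contig alignment and the identity-by-coverage score.
##
## Dereplication, chimera removal and dairy-database matching all reduce
## pairwise local alignments to a single score in [0, 1]:
##
##   identity = matches / aligned columns
##   coverage = aligned fraction of the SHORTER sequence
##   score    = identity * coverage
##
## Coverage on the shorter contig makes containment of a fragment inside a
## longer genome score high, which is what species-level dereplication needs,
## and it makes the score symmetric in its two arguments.

#' Alignment parameters for the internal seed-and-extend aligner
#'
#' @param k exact-seed word size (>= 5)
#' @param minSeedHits minimum number of k-mer seeds on a diagonal before the
#'   diagonal is extended; 2 suppresses chance single-seed matches between
#'   unrelated contigs
#' @param xdrop ungapped extension stops when the running +1/-1 score drops
#'   this far below its maximum
#' @param minHitLength hits shorter than this many bp are discarded
#' @param bothStrands also search the reverse complement of the target
#' @return a list of class `AlignParams`
#' @export
alignParams <- function(k = 11L, minSeedHits = 2L, xdrop = 20L,
                        minHitLength = 100L, bothStrands = TRUE) {
  stopifnot(k >= 5, minSeedHits >= 1, xdrop > 0, minHitLength >= 1)
  structure(list(k = as.integer(k), minSeedHits = as.integer(minSeedHits),
                 xdrop = as.integer(xdrop),
                 minHitLength = as.integer(minHitLength),
                 bothStrands = isTRUE(bothStrands)),
            class = "AlignParams")
}

#' Align two contigs
#'
#' Exact k-mer seeds are chained per diagonal and extended ungapped with an
#' x-drop criterion on both strands.  Deterministic for fixed inputs.
#'
#' @param a,b sequences: character scalars, or named length-1 character
#'   vectors, or `DNAStringSet` elements
#' @param params an [alignParams()] object
#' @param queryId,targetId ids recorded in the hit table
#' @return a hits `data.frame` with per-hit coordinates (0-based half-open),
#'   `matches`, `aligned_length`, `identity`, `coverage`, `score`, `strand`
#' @export
alignPair <- function(a, b, params = alignParams(),
                      queryId = "query", targetId = "target") {
  a <- .singleSeq(a); b <- .singleSeq(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  raw <- .cppSeedExtend(a, b, params$k, params$minSeedHits, params$xdrop,
                        params$minHitLength, params$bothStrands)
  if (!nrow(raw)) return(.emptyHits())
  aligned <- raw$q_end - raw$q_start
  shorter <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) aligned else raw$t_end - raw$t_start
  identity <- raw$matches / aligned
  coverage <- pmin(span / shorter, 1)
  data.frame(query_id = queryId, target_id = targetId,
             q_start = raw$q_start, q_end = raw$q_end,
             t_start = raw$t_start, t_end = raw$t_end,
             q_size = nchar(a), t_size = nchar(b),
             matches = raw$matches, aligned_length = aligned,
             identity = identity, coverage = coverage,
             score = identity * coverage, strand = raw$strand,
             stringsAsFactors = FALSE)
}

.singleSeq <- function(x) {
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x[[1]]))
  }
  if (is(x, "DNAString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Reduce the hits between one pair of contigs to the identity-by-coverage
#' score
#'
#' The aligned blocks of all hits are merged into a non-overlapping union on
#' the shorter contig; coverage is the union length over the shorter contig
#' length and identity is total matches over total aligned columns.
#'
#' @param hits hits `data.frame` relating one ordered (query, target) pair,
#'   e.g. from [alignPair()] or a subset of [readPSL()]
#' @param aLen,bLen query and target lengths in bp
#' @return the score, a fraction in \[0, 1\] (0 for an empty hit set)
#' @export
pairScore <- function(hits, aLen, bLen) {
  if (is.null(hits) || !nrow(hits)) return(0)
  shortLen <- min(aLen, bLen)
  if (aLen <= bLen) {
    ir <- IRanges::IRanges(start = hits$q_start + 1L, end = hits$q_end)
  } else {
    ir <- IRanges::IRanges(start = hits$t_start + 1L, end = hits$t_end)
  }
  unionLen <- sum(IRanges::width(IRanges::reduce(ir)))
  coverage <- min(unionLen / shortLen, 1)
  identity <- sum(hits$matches) / sum(hits$aligned_length)
  identity * coverage
}

#' Self-alignment fraction for chimera detection
#'
#' Total aligned query bases over all self-hits (including the trivial
#' full-length identity hit; overlaps merged within a hit, summed across
#' hits) divided by contig length.  A repeat-free contig gives exactly 1;
#' internally duplicated (chimeric) contigs exceed 1.  The chimera rule
#' removes contigs strictly above 1.10.
#'
#' @param x one sequence (character scalar or `DNAStringSet` of length 1)
#' @param params an [alignParams()]
#' @param includeTrivial include the trivial self-identity hit (default);
#'   set `FALSE` to count only off-diagonal repeats
#' @return a fraction >= 1 when `includeTrivial` is `TRUE`
#' @export
selfAlignmentFraction <- function(x, params = alignParams(),
                                  includeTrivial = TRUE) {
  s <- .singleSeq(x)
  hits <- alignPair(s, s, params)
  if (!includeTrivial) {
    trivial <- hits$strand == "+" & hits$q_start == hits$t_start
    hits <- hits[!trivial, , drop = FALSE]
  }
  if (!nrow(hits)) return(if (includeTrivial) NA_real_ else 0)
  sum(hits$q_end - hits$q_start) / nchar(s)
}

#' All-versus-all identity-by-coverage score table
#'
#' Computes [pairScore()] for every candidate pair of contigs, keeping only
#' positive scores (sparse output).  To avoid aligning every pair, a
#' one-pass shared canonical k-mer screen (word size `screenK`) first
#' selects candidates: a pair is aligned when its shared k-mer occurrence
#' count exceeds three times the random-collision expectation
#' \eqn{2 l_a l_b / 4^k} (the factor 2 because canonical k-mers collide on
#' either strand) plus `screenMargin`.  Related contigs (even at only
#' ~75\% identity) share k-mers orders of magnitude above this background,
#' so the screen does not affect scores at the dereplication thresholds; it
#' can be disabled with `screen = FALSE`.  A precomputed PSL table can be
#' supplied instead of running the internal aligner via [scoresFromPSL()].
#'
#' @param contigs named `DNAStringSet` or named character vector
#' @param params an [alignParams()]
#' @param screen use the shared k-mer candidate screen
#' @param screenK word size of the screen
#' @param screenMargin additive slack above the collision background
#' @return `data.frame` with columns `id1`, `id2`, `score`
#' @export
allVsAll <- function(contigs, params = alignParams(), screen = TRUE,
                     screenK = 13L, screenMargin = 20) {
  seqs <- .asSeqVector(contigs)
  ids <- names(seqs)
  n <- length(seqs)
  lens <- nchar(seqs)
  empty <- data.frame(id1 = character(), id2 = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  if (screen) {
    shared <- .cppSharedKmerCounts(unname(seqs), as.integer(screenK))
    ## canonical k-mers collide on either strand: background 2 l_a l_b / 4^k
    background <- 2 * outer(lens, lens) / 4^screenK
    candidate <- shared > 3 * background + screenMargin
  } else {
    candidate <- matrix(TRUE, n, n)
  }
  out <- vector("list", sum(candidate[upper.tri(candidate)]))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (!candidate[i, j]) next
      hits <- alignPair(seqs[[i]], seqs[[j]], params,
                        queryId = ids[i], targetId = ids[j])
      sc <- pairScore(hits, lens[i], lens[j])
      if (sc > 0) {
        k <- k + 1L
        out[[k]] <- data.frame(id1 = ids[i], id2 = ids[j], score = sc,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

#' Aggregate a PSL hit table into pair scores
#'
#' Multiple PSL rows for the same contig pair (in either orientation) are
#' merged with the union rule of [pairScore()].  Self-pairs are dropped.
#'
#' @param psl hits `data.frame` from [readPSL()]
#' @param lengths optional named vector of contig lengths; defaults to the
#'   `q_size`/`t_size` columns of the PSL
#' @return `data.frame` with columns `id1`, `id2`, `score`
#' @export
scoresFromPSL <- function(psl, lengths = NULL) {
  if (!nrow(psl)) {
    return(data.frame(id1 = character(), id2 = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(lengths)) {
    lengths <- c(setNames(psl$q_size, psl$query_id),
                 setNames(psl$t_size, psl$target_id))
    lengths <- lengths[!duplicated(names(lengths))]
  }
  ## canonical unordered pair; flip hits so query = first id
  flip <- psl$query_id > psl$target_id
  flipped <- psl
  flipped$query_id[flip] <- psl$target_id[flip]
  flipped$target_id[flip] <- psl$query_id[flip]
  flipped$q_start[flip] <- psl$t_start[flip]
  flipped$q_end[flip] <- psl$t_end[flip]
  flipped$t_start[flip] <- psl$q_start[flip]
  flipped$t_end[flip] <- psl$q_end[flip]
  flipped <- flipped[flipped$query_id != flipped$target_id, , drop = FALSE]
  if (!nrow(flipped)) {
    return(data.frame(id1 = character(), id2 = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(flipped$query_id, flipped$target_id, sep = "\r")
  parts <- split(flipped, key)
  rows <- lapply(parts, function(h) {
    a <- h$query_id[1]; b <- h$target_id[1]
    data.frame(id1 = a, id2 = b,
               score = pairScore(h, lengths[[a]], lengths[[b]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$score > 0, , drop = FALSE]
}

## fast lookup structure for sparse pair scores
.scoreLookup <- function(scores) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(scores)) {
    for (i in seq_len(nrow(scores))) {
      assign(paste(scores$id1[i], scores$id2[i], sep = "\r"),
             scores$score[i], envir = env)
      assign(paste(scores$id2[i], scores$id1[i], sep = "\r"),
             scores$score[i], envir = env)
    }
  }
  function(a, b) {
    v <- mget(paste(a, b, sep = "\r"), envir = env,
              ifnotfound = list(0))[[1]]
    v
  }
}
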
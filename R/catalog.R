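## Construction of the species-level vOTU catalog.
##
## Pipeline order is fixed: length filter -> chimera removal -> greedy
## species clustering -> viral selection -> PhiX removal -> lifestyle ->
## dairy database match -> host assignment.  Every input contig ends up with
## exactly one fate in the accounting table.

#' Thresholds of the vOTU catalog pipeline
#'
#' @param minLength retain contigs strictly longer than this (bp); the
#'   smallest retained vOTU in a typical cheese virome catalog is 2,002 bp
#' @param speciesScore identity-by-coverage score at/above which two contigs
#'   belong to the same species-level cluster
#' @param chimeraFraction contigs whose self-alignment fraction is strictly
#'   above this are removed as assembly chimeras
#' @param dairyScore minimal score against the dairy phage database for a
#'   match to be recorded
#' @param phixLabel database/report label identifying the PhiX174
#'   sequencing control
#' @return list of class `CatalogThresholds`
#' @export
catalogThresholds <- function(minLength = 2000, speciesScore = 0.90,
                              chimeraFraction = 1.10, dairyScore = 0.30,
                              phixLabel = "PhiX174") {
  stopifnot(minLength >= 0, speciesScore > 0, chimeraFraction > 0,
            dairyScore > 0)
  structure(list(minLength = minLength, speciesScore = speciesScore,
                 chimeraFraction = chimeraFraction, dairyScore = dairyScore,
                 phixLabel = phixLabel),
            class = "CatalogThresholds")
}

#' Minimum-length filter
#'
#' Keeps contigs strictly longer than `thresholds$minLength`.
#'
#' @param contigs named `DNAStringSet`
#' @param thresholds a [catalogThresholds()]
#' @return the retained `DNAStringSet`, with attribute `removed_ids`
#' @export
filterMinLength <- function(contigs, thresholds = catalogThresholds()) {
  keep <- Biostrings::width(contigs) > thresholds$minLength
  .cv_log(sprintf("length filter (> %d bp): kept %d / %d contigs",
                  as.integer(thresholds$minLength), sum(keep),
                  length(contigs)))
  out <- contigs[keep]
  attr(out, "removed_ids") <- names(contigs)[!keep]
  out
}

#' Remove chimeric contigs
#'
#' A contig is chimeric when its self-alignment fraction (see
#' [selfAlignmentFraction()]) is strictly greater than
#' `thresholds$chimeraFraction`; a fraction of exactly 1.10 is retained.
#'
#' @param contigs named `DNAStringSet`
#' @param params an [alignParams()]
#' @param thresholds a [catalogThresholds()]
#' @param fractions optional precomputed named vector of self-alignment
#'   fractions
#' @return retained `DNAStringSet` with attribute `removed_ids`
#' @export
removeChimeras <- function(contigs, params = alignParams(),
                           thresholds = catalogThresholds(),
                           fractions = NULL) {
  if (is.null(fractions)) {
    fractions <- vapply(seq_along(contigs), function(i) {
      selfAlignmentFraction(contigs[i], params)
    }, numeric(1))
    names(fractions) <- names(contigs)
  }
  keep <- fractions[names(contigs)] <= thresholds$chimeraFraction
  removed <- names(contigs)[!keep]
  .cv_log(sprintf("chimera removal (> %.2f): removed %d contig(s)%s",
                  thresholds$chimeraFraction, length(removed),
                  if (length(removed)) {
                    paste0(" [", paste(removed, collapse = ", "), "]")
                  } else ""))
  out <- contigs[keep]
  attr(out, "removed_ids") <- removed
  out
}

#' Greedy species-level clustering
#'
#' Contigs are visited in order of decreasing length (ties broken by
#' lexicographic id).  A contig joins the first existing representative it
#' scores at or above `thresholds$speciesScore` against (representatives are
#' tried in founding order); otherwise it founds a new cluster.
#' Representatives are therefore the longest member of their cluster by
#' construction, and the result is invariant to the input order of the
#' contigs.
#'
#' @param contigs named `DNAStringSet` (post length/chimera filtering)
#' @param scores sparse score table (`id1`, `id2`, `score`) from
#'   [allVsAll()] or [scoresFromPSL()]
#' @param thresholds a [catalogThresholds()]
#' @return a [VOTUCatalog-class] (quality/lifestyle/host columns unset)
#' @export
clusterSpecies <- function(contigs, scores,
                           thresholds = catalogThresholds()) {
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  ord <- order(-lens, names(contigs))
  ids <- names(contigs)[ord]
  lookup <- .scoreLookup(scores)
  reps <- character(0)
  members <- list()
  for (id in ids) {
    joined <- FALSE
    for (r in reps) {
      if (lookup(id, r) >= thresholds$speciesScore) {
        members[[r]] <- c(members[[r]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      members[[id]] <- id
    }
  }
  .cv_log(sprintf(
    "species clustering (score >= %.2f): %d contigs -> %d clusters",
    thresholds$speciesScore, length(contigs), length(reps)))
  votus <- data.frame(
    representative_id = reps,
    length = as.numeric(lens[reps]),
    n_members = vapply(members[reps], length, integer(1)),
    quality = NA_character_, lifestyle = NA_character_,
    host_genus = NA_character_, dairy_phage = NA_character_,
    dairy_score = NA_real_, phage_group = NA_character_,
    stringsAsFactors = FALSE)
  rownames(votus) <- NULL
  accounting <- data.frame(
    contig_id = unlist(members[reps], use.names = FALSE),
    fate = "member_of_votu",
    votu = rep(reps, times = votus$n_members),
    stringsAsFactors = FALSE)
  new("VOTUCatalog", votus = votus, members = members[reps],
      accounting = accounting)
}

.TIER_ORDER <- c(complete = 1L, high = 2L, medium = 3L, low = 4L,
                 not_determined = 5L)

#' Viral selection union rule
#'
#' A vOTU is retained as viral when its representative is declared
#' `complete`, `high` or `medium` quality by either VIBRANT or CheckV, or
#' `full` by VirSorter2.  The quality tier recorded is the CheckV tier when
#' present, else the VIBRANT tier, else `not_determined`.  Afterwards any
#' representative labelled as the PhiX174 control is removed regardless of
#' quality.
#'
#' @param catalog a [VOTUCatalog-class]
#' @param reports tool report `data.frame` (see [readToolReports()]); a
#'   missing row means all labels absent
#' @param thresholds a [catalogThresholds()] (for the PhiX label)
#' @param phixSequence optional `DNAStringSet` holding the PhiX174 genome:
#'   when given, representatives are additionally screened by alignment at
#'   the dairy cutoff
#' @param contigs optional `DNAStringSet` with the representative sequences
#'   (required for the alignment-based PhiX screen)
#' @param params an [alignParams()] for the PhiX screen
#' @return the filtered catalog with `quality` filled in
#' @export
selectViral <- function(catalog, reports,
                        thresholds = catalogThresholds(),
                        phixSequence = NULL, contigs = NULL,
                        params = alignParams()) {
  votus <- catalog@votus
  rep_rows <- reports[match(votus$representative_id, reports$contig_id), ,
                      drop = FALSE]
  vq <- rep_rows$vibrant_quality
  cq <- rep_rows$checkv_quality
  vs <- rep_rows$virsorter2_label
  qualifying <- c("complete", "high", "medium")
  viral <- (!is.na(vq) & vq %in% qualifying) |
    (!is.na(cq) & cq %in% qualifying) |
    (!is.na(vs) & vs == "full")
  quality <- ifelse(!is.na(cq), cq, ifelse(!is.na(vq), vq, "not_determined"))
  is_phix <- votus$representative_id == thresholds$phixLabel
  if (!is.null(phixSequence)) {
    if (is.null(contigs)) stop("contigs required for alignment PhiX screen")
    phix <- .singleSeq(phixSequence)
    hit <- vapply(votus$representative_id, function(id) {
      h <- alignPair(as.character(contigs[[id]]), phix, params)
      pairScore(h, nchar(as.character(contigs[[id]])), nchar(phix)) >=
        thresholds$dairyScore
    }, logical(1))
    is_phix <- is_phix | hit
  }
  .cv_log(sprintf(
    "viral selection: %d / %d vOTUs viral; %d PhiX control(s) discarded",
    sum(viral), nrow(votus), sum(viral & is_phix)))
  votus$quality <- quality
  .dropVotus(catalog, votus,
             drop = !viral, fate = "discarded_nonviral",
             then_drop = viral & is_phix, then_fate = "discarded_phix")
}

## drop vOTUs, reassigning the fate of all their member contigs
.dropVotus <- function(catalog, votus, drop, fate,
                       then_drop = NULL, then_fate = NULL) {
  acc <- catalog@accounting
  members <- catalog@members
  mark <- function(acc, rep_ids, fate) {
    acc$fate[acc$votu %in% rep_ids] <- fate
    acc$votu[acc$fate == fate] <- NA_character_
    acc
  }
  acc <- mark(acc, votus$representative_id[drop], fate)
  keep <- !drop
  if (!is.null(then_drop)) {
    acc <- mark(acc, votus$representative_id[then_drop], then_fate)
    keep <- keep & !then_drop
  }
  new("VOTUCatalog", votus = votus[keep, , drop = FALSE],
      members = members[votus$representative_id[keep]],
      accounting = acc)
}

#' Flag temperate lifestyle
#'
#' A vOTU is temperate iff VIBRANT called its representative temperate
#' (prophage excision or integrase evidence); otherwise
#' `virulent_or_unknown`.
#'
#' @inheritParams selectViral
#' @return catalog with `lifestyle` filled in
#' @export
flagLifestyle <- function(catalog, reports) {
  votus <- catalog@votus
  rep_rows <- reports[match(votus$representative_id, reports$contig_id), ,
                      drop = FALSE]
  temperate <- !is.na(rep_rows$vibrant_lifestyle) &
    rep_rows$vibrant_lifestyle == "temperate"
  votus$lifestyle <- ifelse(temperate, "temperate", "virulent_or_unknown")
  .cv_log(sprintf("lifestyle: %d / %d temperate", sum(temperate),
                  nrow(votus)))
  methods::initialize(catalog, votus = votus)
}

#' Match vOTUs against the dairy phage reference database
#'
#' Each representative is aligned against every database genome; the best
#' score at or above `thresholds$dairyScore` is recorded together with the
#' database phage's group label.  Ties are broken by alphabetical phage
#' name.  A database lifestyle of `temperate` refines the vOTU lifestyle.
#'
#' @param catalog a [VOTUCatalog-class]
#' @param contigs `DNAStringSet` holding the representative sequences
#' @param db dairy database list from [readDairyDB()]
#' @param thresholds a [catalogThresholds()]
#' @param params an [alignParams()]
#' @return catalog with `dairy_phage`, `dairy_score`, `phage_group` filled
#' @export
matchDairyDB <- function(catalog, contigs, db,
                         thresholds = catalogThresholds(),
                         params = alignParams()) {
  votus <- catalog@votus
  dbseq <- .asSeqVector(db$sequences)
  info <- db$info
  ## shared k-mer candidate screen (see allVsAll): at the 0.30 score cutoff
  ## true matches share k-mers far above the collision background
  rep_seqs <- vapply(votus$representative_id,
                     function(id) as.character(contigs[[id]]), character(1))
  screenK <- 13L
  shared <- .cppSharedKmerCounts(unname(c(rep_seqs, dbseq)), screenK)
  lens <- nchar(c(rep_seqs, dbseq))
  background <- 2 * outer(lens, lens) / 4^screenK
  candidate <- shared > 3 * background + 20
  nrep <- length(rep_seqs)
  for (i in seq_len(nrow(votus))) {
    id <- votus$representative_id[i]
    s <- rep_seqs[[i]]
    best_name <- NA_character_; best_score <- 0
    for (ph in sort(info$phage_name)) {  # alphabetical => deterministic ties
      if (!candidate[i, nrep + match(ph, names(dbseq))]) next
      h <- alignPair(s, dbseq[[ph]], params, queryId = id, targetId = ph)
      sc <- pairScore(h, nchar(s), nchar(dbseq[[ph]]))
      if (sc > best_score) {
        best_score <- sc
        best_name <- ph
      }
    }
    if (!is.na(best_name) && best_score >= thresholds$dairyScore) {
      votus$dairy_phage[i] <- best_name
      votus$dairy_score[i] <- best_score
      row <- info[info$phage_name == best_name, ]
      votus$phage_group[i] <- row$phage_group
      if (identical(row$lifestyle, "temperate")) {
        votus$lifestyle[i] <- "temperate"
      }
    }
  }
  .cv_log(sprintf("dairy db match (score >= %.2f): %d / %d matched",
                  thresholds$dairyScore, sum(!is.na(votus$dairy_phage)),
                  nrow(votus)))
  methods::initialize(catalog, votus = votus)
}

#' Assign the host genus
#'
#' The host genus is the dairy match's verified host when a match exists;
#' otherwise the iPHoP prediction; otherwise none.  The override reflects
#' that the verified host of a close relative phage is more reliable than a
#' computational prediction.
#'
#' @inheritParams matchDairyDB
#' @param reports tool report data.frame (for `iphop_genus`)
#' @return catalog with `host_genus` filled in
#' @export
assignHost <- function(catalog, reports, db = NULL) {
  votus <- catalog@votus
  rep_rows <- reports[match(votus$representative_id, reports$contig_id), ,
                      drop = FALSE]
  votus$host_genus <- rep_rows$iphop_genus
  if (!is.null(db)) {
    matched <- !is.na(votus$dairy_phage)
    idx <- match(votus$dairy_phage[matched], db$info$phage_name)
    votus$host_genus[matched] <- db$info$host_genus[idx]
  }
  .cv_log(sprintf("host assignment: %d / %d with predicted host",
                  sum(!is.na(votus$host_genus)), nrow(votus)))
  methods::initialize(catalog, votus = votus)
}

.roundHalfUp <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize a vOTU catalog
#'
#' Totals and percentages of the final catalog: number of vOTUs, percentage
#' longer than 10 kb (0 decimals), percentage of complete and of
#' high-quality genomes, percentage temperate, percentage with a predicted
#' host, percentage with a dairy database match, and per-genus vOTU counts.
#' Percentages are rounded half-up to one decimal.
#'
#' @param catalog a completed [VOTUCatalog-class]
#' @return a list of summary statistics
#' @export
summarizeCatalog <- function(catalog) {
  v <- catalog@votus
  n <- nrow(v)
  pct <- function(k, digits = 1) {
    if (n == 0) return(NA_real_)
    .roundHalfUp(100 * k / n, digits)
  }
  genus_counts <- sort(table(v$host_genus[!is.na(v$host_genus)]),
                       decreasing = TRUE)
  list(
    n_votus = n,
    pct_over_10kb = pct(sum(v$length > 10000), digits = 0),
    pct_complete = pct(sum(v$quality == "complete", na.rm = TRUE)),
    pct_high = pct(sum(v$quality == "high", na.rm = TRUE)),
    pct_temperate = pct(sum(v$lifestyle == "temperate", na.rm = TRUE)),
    pct_with_host = pct(sum(!is.na(v$host_genus))),
    pct_dairy_matched = pct(sum(!is.na(v$dairy_phage))),
    genus_counts = as.list(genus_counts)
  )
}

#' Run the full catalog pipeline
#'
#' Length filter, chimera removal, greedy species clustering, viral
#' selection, PhiX removal, lifestyle flagging and (when a database is
#' supplied) dairy matching plus host assignment, with complete per-contig
#' accounting.
#'
#' @param contigs named `DNAStringSet` of all assembled contigs
#' @param reports tool report `data.frame`
#' @param db optional dairy database from [readDairyDB()]
#' @param thresholds a [catalogThresholds()]
#' @param params an [alignParams()]
#' @param scores optional precomputed score table (e.g. from
#'   [scoresFromPSL()]); computed internally with [allVsAll()] otherwise
#' @return a [VOTUCatalog-class]
#' @export
buildCatalog <- function(contigs, reports, db = NULL,
                         thresholds = catalogThresholds(),
                         params = alignParams(), scores = NULL) {
  .cv_log(sprintf("catalog pipeline: %d input contigs", length(contigs)))
  kept <- filterMinLength(contigs, thresholds)
  short_ids <- attr(kept, "removed_ids")
  kept <- removeChimeras(kept, params, thresholds)
  chimera_ids <- attr(kept, "removed_ids")
  if (is.null(scores)) scores <- allVsAll(kept, params)
  catalog <- clusterSpecies(kept, scores, thresholds)
  catalog <- selectViral(catalog, reports, thresholds)
  catalog <- flagLifestyle(catalog, reports)
  if (!is.null(db)) {
    catalog <- matchDairyDB(catalog, contigs, db, thresholds, params)
  }
  catalog <- assignHost(catalog, reports, db)
  acc <- rbind(
    data.frame(contig_id = short_ids, fate = "discarded_short",
               votu = NA_character_, stringsAsFactors = FALSE),
    data.frame(contig_id = chimera_ids, fate = "discarded_chimera",
               votu = NA_character_, stringsAsFactors = FALSE),
    catalog@accounting)
  rownames(acc) <- NULL
  catalog <- methods::initialize(catalog, accounting = acc)
  .cv_log(sprintf("final catalog: %d vOTUs", nrow(catalog@votus)))
  catalog
}
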
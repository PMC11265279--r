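## Readers/writers for the plain-text formats the pipeline touches:
## FASTA (contigs, dairy phage database), PSL alignment tables, and TSV
## tables (counts, sample metadata, tool reports, genus tables).
## All TSVs are UTF-8, tab separated, '.' decimal, empty string = missing.

.STAGES <- paste0("W", 1:5)
.YEARS <- c("2017", "2019", "2022")
.TIERS <- c("complete", "high", "medium", "low", "not_determined")

#' Read assembled contigs from a FASTA file
#'
#' Sequences are uppercased and the id is the first whitespace-delimited
#' token of each header.  Duplicate ids are an error; an empty file yields an
#' empty set with a warning.
#'
#' @param path FASTA file
#' @return a named [Biostrings::DNAStringSet]
#' @export
readContigs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA: ", path)
    return(seqs)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate contig id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  names(seqs) <- ids
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write contigs to FASTA
#'
#' @param contigs named `DNAStringSet` or named character vector
#' @param path output file
#' @export
writeContigs <- function(contigs, path) {
  if (!is(contigs, "DNAStringSet")) {
    contigs <- Biostrings::DNAStringSet(.asSeqVector(contigs))
  }
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

.PSL_COLS <- c("matches", "misMatches", "qName", "qSize", "qStart", "qEnd",
               "tName", "tSize", "tStart", "tEnd", "blockCount", "blockSizes")

#' Read a PSL-dialect alignment table
#'
#' Accepts the 12-column tabular dialect (`matches`, `misMatches`, `qName`,
#' `qSize`, `qStart`, `qEnd`, `tName`, `tSize`, `tStart`, `tEnd`,
#' `blockCount`, `blockSizes`), with or without a header row.  The strand of
#' a hit is irrelevant for dereplication (contigs are orientation free), so
#' no strand column is required and reverse-complement hits are treated like
#' forward hits.  Each row becomes one alignment hit with identity (matches
#' over aligned columns), coverage (aligned span over the shorter sequence)
#' and the identity-by-coverage score populated.
#'
#' @param path PSL file
#' @return a hits `data.frame` compatible with [pairScore()]
#' @export
readPSL <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.emptyHits())
  fields1 <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields1[1]))))
  offset <- 0L
  if (has_header) {
    if (!all(.PSL_COLS %in% fields1)) {
      stop("PSL header found but required columns missing")
    }
    idx <- match(.PSL_COLS, fields1)
    lines <- lines[-1]
    offset <- 1L
  } else {
    idx <- seq_along(.PSL_COLS)
  }
  if (!length(lines)) return(.emptyHits())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < max(idx)) {
      stop(sprintf("malformed PSL row at line %d of %s", i + offset, path))
    }
    f <- f[idx]
    names(f) <- .PSL_COLS
    numcols <- c("matches", "qSize", "qStart", "qEnd", "tSize", "tStart",
                 "tEnd")
    num <- setNames(suppressWarnings(as.numeric(f[numcols])), numcols)
    if (any(is.na(num))) {
      stop(sprintf("malformed PSL row at line %d of %s", i + offset, path))
    }
    sizes <- suppressWarnings(as.numeric(
      strsplit(f[["blockSizes"]], ",", fixed = TRUE)[[1]]))
    if (any(is.na(sizes)) || !length(sizes)) {
      stop(sprintf("malformed PSL row at line %d of %s", i + offset, path))
    }
    aligned <- sum(sizes)
    shorter <- min(num[["qSize"]], num[["tSize"]])
    span <- if (num[["qSize"]] <= num[["tSize"]]) {
      num[["qEnd"]] - num[["qStart"]]
    } else {
      num[["tEnd"]] - num[["tStart"]]
    }
    identity <- num[["matches"]] / aligned
    coverage <- span / shorter
    data.frame(
      query_id = f[["qName"]], target_id = f[["tName"]],
      q_start = num[["qStart"]], q_end = num[["qEnd"]],
      t_start = num[["tStart"]], t_end = num[["tEnd"]],
      q_size = num[["qSize"]], t_size = num[["tSize"]],
      matches = num[["matches"]], aligned_length = aligned,
      identity = identity, coverage = coverage,
      score = identity * coverage,
      strand = "+", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyHits <- function() {
  data.frame(query_id = character(), target_id = character(),
             q_start = numeric(), q_end = numeric(),
             t_start = numeric(), t_end = numeric(),
             q_size = numeric(), t_size = numeric(),
             matches = numeric(), aligned_length = numeric(),
             identity = numeric(), coverage = numeric(),
             score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read a per-sample count table
#'
#' TSV with features (vOTUs or genera) in rows and samples in columns; the
#' first column holds the feature ids.  When `state` is `NULL` it is
#' auto-detected: integer values give `raw`, columns summing to 1 give
#' `relative`.
#'
#' @param path TSV file
#' @param sampleMetadata optional data.frame from [readSampleMetadata()];
#'   samples must match exactly.
#' @param state override the auto-detected normalization state
#' @return a [ViromeCounts-class]
#' @export
readCounts <- function(path, sampleMetadata = NULL, state = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  if (is.null(state)) {
    state <- if (all(abs(m - round(m)) < 1e-8)) {
      "raw"
    } else if (all(abs(colSums(m) - 1) < 1e-6)) {
      "relative"
    } else {
      "coverage"
    }
  }
  if (state == "relative") m <- sweep(m, 2, colSums(m), "/")
  ViromeCounts(m, sampleData = sampleMetadata, state = state)
}

#' Write a ViromeCounts table as TSV
#' @param x a `ViromeCounts`
#' @param path output file
#' @export
writeCounts <- function(x, path) {
  m <- countValues(x)
  out <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `study` (`short_term`/`long_term`),
#' `group` (stage `W1`..`W5` or year `2017`/`2019`/`2022`) and `replicate`
#' (`A`/`B`/`C`).  Unknown group labels are an error.
#'
#' @param path TSV file
#' @return a data.frame with rownames = sample ids
#' @export
readSampleMetadata <- function(path) {
  md <- read.delim(path, colClasses = "character")
  need <- c("sample_id", "study", "group", "replicate")
  if (!all(need %in% colnames(md))) {
    stop("metadata must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(md$group, c(.STAGES, .YEARS))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(unique(bad), collapse = ", "))
  }
  bad <- setdiff(md$study, c("short_term", "long_term"))
  if (length(bad)) stop("unknown study label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(md$replicate, c("A", "B", "C"))
  if (length(bad)) {
    stop("unknown replicate label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicated sample ids in metadata")
  rownames(md) <- md$sample_id
  md
}

#' Read a genus-aggregated 16S table
#'
#' Same layout as [readCounts()] (genera in rows); rows of relative
#' abundances are detected and flagged `relative`.
#'
#' @inheritParams readCounts
#' @return a [ViromeCounts-class] (the container is feature-agnostic)
#' @export
readGenusTable <- function(path, sampleMetadata = NULL, state = NULL) {
  readCounts(path, sampleMetadata = sampleMetadata, state = state)
}

#' Read viral-detection tool reports
#'
#' One row per contig with the minimal label set consumed by the viral
#' decision rule: `contig_id`, `vibrant_quality`, `vibrant_lifestyle`,
#' `checkv_quality`, `virsorter2_label`, `iphop_genus`.  Empty strings are
#' absent labels; quality tiers are restricted to
#' complete/high/medium/low/not_determined.
#'
#' @param path TSV file
#' @return data.frame with `NA` for absent labels
#' @export
readToolReports <- function(path) {
  rep <- read.delim(path, colClasses = "character")
  need <- c("contig_id", "vibrant_quality", "vibrant_lifestyle",
            "checkv_quality", "virsorter2_label", "iphop_genus")
  miss <- setdiff(need, colnames(rep))
  if (length(miss)) {
    stop("tool report missing column(s): ", paste(miss, collapse = ", "))
  }
  for (cc in setdiff(need, "contig_id")) rep[[cc]][rep[[cc]] == ""] <- NA
  for (cc in c("vibrant_quality", "checkv_quality")) {
    bad <- setdiff(stats::na.omit(rep[[cc]]), .TIERS)
    if (length(bad)) {
      stop("invalid quality tier(s) in ", cc, ": ", paste(bad, collapse = ", "))
    }
  }
  bad <- setdiff(stats::na.omit(rep$vibrant_lifestyle), c("lytic", "temperate"))
  if (length(bad)) {
    stop("invalid lifestyle value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(rep$contig_id)) stop("duplicated contig ids in report")
  rep
}

#' Read the dairy phage reference database
#'
#' A FASTA of reference genomes plus a TSV of annotations with columns
#' `phage_name`, `host_genus`, `phage_group`, `lifestyle`
#' (`virulent`/`temperate`).  Names must be unique and present in both files.
#'
#' @param fastaPath reference genomes FASTA
#' @param annotationPath annotation TSV
#' @return list with elements `sequences` (DNAStringSet) and `info`
#'   (data.frame)
#' @export
readDairyDB <- function(fastaPath, annotationPath) {
  seqs <- readContigs(fastaPath)
  info <- read.delim(annotationPath, colClasses = "character")
  need <- c("phage_name", "host_genus", "phage_group", "lifestyle")
  if (!all(need %in% colnames(info))) {
    stop("dairy db annotations must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(info$phage_name)) stop("duplicated dairy phage names")
  bad <- setdiff(info$lifestyle, c("virulent", "temperate"))
  if (length(bad)) stop("invalid dairy lifestyle: ", paste(bad, collapse = ", "))
  miss <- setdiff(info$phage_name, names(seqs))
  if (length(miss)) {
    stop("annotated phage(s) missing from FASTA: ", paste(miss, collapse = ", "))
  }
  list(sequences = seqs[info$phage_name], info = info)
}
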
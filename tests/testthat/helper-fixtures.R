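## Shared helpers for the test suite.  Everything is generated
## programmatically; no binary fixtures.

options(cheesevirome.verbose = FALSE)

## deterministic random DNA of length n
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  randomDNA(n)
}

## a small raw ViromeCounts table with stage metadata: nf features,
## 5 stages x nrep replicates
smallCounts <- function(nf = 8, nrep = 2, seed = 1, lib = 2000) {
  set.seed(seed)
  stages <- paste0("W", 1:5)
  ids <- as.vector(outer(LETTERS[seq_len(nrep)], stages,
                         function(r, s) paste0(s, r)))
  m <- matrix(rpois(nf * length(ids), lambda = lib / nf),
              nrow = nf,
              dimnames = list(sprintf("v%02d", seq_len(nf)), ids))
  md <- data.frame(
    sample_id = ids,
    study = "short_term",
    group = rep(stages, each = nrep),
    replicate = rep(LETTERS[seq_len(nrep)], times = 5),
    stringsAsFactors = FALSE)
  rownames(md) <- ids
  ViromeCounts(m, sampleData = md, state = "raw")
}

## exact Bray-Curtis oracle via vegan
veganBC <- function(m) {
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

## quiet rarefaction (vegan warns when rarefying simulated counts)
quietRarefy <- function(x, ...) {
  suppressWarnings(rarefyCounts(x, ...))
}

## build the default synthetic community once per test file when needed
simulateDefault <- function(seed = 42, design = communityDesign()) {
  suppressWarnings(simulateCommunity(design, seed = seed))
}

## a small, fast community design for catalog-pipeline tests: 14 vOTUs
## with short genomes plus members, outgroups, chimeras, fragments,
## PhiX and non-viral contigs
tinyDesign <- function() {
  guilds <- rbind(
    guildSpec("stable_936", 4, "stable", baseFraction = 0.3,
              hostGenus = "Lactococcus", phageGroup = "936"),
    guildSpec("declining_p335", 4, "declining", baseFraction = 0.3,
              rate = 2^(-4 / 3), hostGenus = "Lactococcus",
              phageGroup = "P335", temperate = TRUE),
    guildSpec("rising_glutamicibacter", 2, "rising", baseFraction = 0.01,
              rate = 16, hostGenus = "Glutamicibacter",
              phageGroup = "Glutamicibacter_phages"),
    guildSpec("sporadic_background", 4, "sporadic",
              hostGenus = NA_character_, phageGroup = "unassigned"))
  communityDesign(guilds = guilds, lengthRange = c(2002, 12000),
                  nMemberVotus = 5, membersPerVotu = 1,
                  nOutgroups = 3, nChimeras = 2, nFragments = 3,
                  nNonviral = 3)
}

## independent re-implementation of the greedy clustering rule, used as
## an oracle: longest first (ties by id), join the first representative
## in founding order scoring >= cutoff
greedyOracle <- function(contigs, scores, cutoff = 0.90) {
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  ids <- names(contigs)[order(-lens, names(contigs))]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tab <- setNames(scores$score, key(scores$id1, scores$id2))
  sc <- function(a, b) {
    v <- tab[key(a, b)]
    if (is.na(v)) 0 else v
  }
  assign_to <- character(0)
  reps <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (sc(id, r) >= cutoff) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    assign_to[id] <- hit
  }
  assign_to
}
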
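## Synthetic cheese-surface virome generator with recorded ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## ~100 species-level vOTUs spanning 2-150 kb organised into guilds
## (declining starter phages, rising ripening phages, a transient
## mid-ripening bloom, a stable low-abundance guild, and a sporadic
## background), five ripening stages x three replicates for the
## short-term arm, three production years x three replicates for the
## long-term arm, compositional multinomial counts with Dirichlet
## overdispersion, a correlated bacterial genus table with constant LAB and
## ~2-log aerobic growth, plus the contig-level artefacts the catalog
## pipeline must handle (member copies, outgroups, chimeras, sub-threshold
## fragments, a PhiX decoy, non-viral contigs).
##
## All generators are pure functions of (design, seed).

## logistic shape constants of the rising-guild trajectory: steepness and
## midpoint on the 1..5 stage axis (rise happens between W3 and W5)
.RISE_K <- 3
.RISE_S0 <- 3.5

#' Specify one phage guild
#'
#' @param name guild name
#' @param nVotus number of vOTUs in the guild
#' @param dynamic `stable`, `declining`, `rising`, `transient` or
#'   `sporadic`
#' @param baseFraction fraction of the community at stage W1 (ignored for
#'   `sporadic`, which absorbs the per-stage remainder)
#' @param rate for `declining`: the per-stage multiplicative change (< 1);
#'   for `rising`: the fold change between the W1-2 and W4-5 mean shares
#'   (the trajectory is logistic in stage); for `transient`: the per-stage
#'   fold of the mid-ripening bloom (geometric rise to the middle stage,
#'   then the mirror-image fall, so the start/end phase means are equal
#'   and the planted log2 fold change is exactly 0)
#' @param hostGenus host genus of the guild's phages (`NA` = no predicted
#'   host)
#' @param phageGroup phage group label
#' @param temperate should the guild's vOTUs carry temperate evidence
#' @return one-row data.frame
#' @export
guildSpec <- function(name, nVotus, dynamic, baseFraction = 0,
                      rate = 1, hostGenus = NA_character_,
                      phageGroup = NA_character_, temperate = FALSE) {
  stopifnot(dynamic %in% c("stable", "declining", "rising", "transient",
                           "sporadic"),
            nVotus >= 1, rate > 0, baseFraction >= 0, baseFraction <= 1)
  data.frame(name = name, n_votus = as.integer(nVotus), dynamic = dynamic,
             base_fraction = baseFraction, rate = rate,
             host_genus = hostGenus, phage_group = phageGroup,
             temperate = temperate, stringsAsFactors = FALSE)
}

#' Default guild structure
#'
#' Five profile archetypes over 113 vOTUs, designed so every archetype is
#' both scientifically meaningful and geometrically distinct in
#' log-profile space:
#'
#' * `declining_p335` (22 vOTUs, temperate *Lactococcus* P335-like
#'   starter phages): geometric decline, rate chosen so the planted log2
#'   fold change between the W1-2 and W4-5 ripening phases is exactly -4.
#' * three rising ripening-phage guilds (8 vOTUs each, hosts
#'   *Glutamicibacter*, *Brevibacterium*, *Psychrobacter*) sharing one
#'   logistic trajectory with a 16-fold increase (planted log2 fold
#'   change exactly +4).  Their base fraction anchors the guild's mean
#'   log10 per-vOTU share at the declining guild's mean level, so the
#'   two trajectories differ in direction, not overall abundance.
#' * `transient_corynebacterium` (24 vOTUs): a mid-ripening bloom that
#'   rises geometrically to W3 and falls back symmetrically; the
#'   start/end phase means are equal, so its planted log2 fold change is
#'   exactly 0 (a true differential-abundance null with a non-flat
#'   profile).
#' * `stable_987` (22 vOTUs, *Streptococcus* 987-like phages): constant
#'   low share.
#' * `sporadic_background` (21 vOTUs, no predicted host): absorbs the
#'   per-stage remainder, giving an irregular quasi-stable high-share
#'   background.
#'
#' The five archetype log profiles sit near the vertices of a regular
#' simplex (all pairwise separations comparable) and the archetypes have
#' near-equal vOTU counts, which makes the within-cluster
#' sum-of-squares elbow of the profile clustering well defined at 5.
#'
#' @return data.frame of guild specifications
#' @export
defaultGuilds <- function() {
  rbind(
    guildSpec("declining_p335", 22, "declining",
              baseFraction = 22 * 10^-1.6,
              rate = 2^(-4 / 3), hostGenus = "Lactococcus",
              phageGroup = "P335", temperate = TRUE),
    ## 8 * first stage of the logistic shape whose per-vOTU mean log10
    ## share is -2.4 (the declining guild's mean level)
    guildSpec("rising_glutamicibacter", 8, "rising",
              baseFraction = 0.0073082259811935472,
              rate = 16, hostGenus = "Glutamicibacter",
              phageGroup = "Glutamicibacter_phages"),
    guildSpec("rising_brevibacterium", 8, "rising",
              baseFraction = 0.0073082259811935472,
              rate = 16, hostGenus = "Brevibacterium",
              phageGroup = "Brevibacterium_phages"),
    guildSpec("rising_psychrobacter", 8, "rising",
              baseFraction = 0.0073082259811935472,
              rate = 16, hostGenus = "Psychrobacter",
              phageGroup = "Psychrobacter_phages"),
    ## peak per-vOTU share 10^-1.58 at W3, 3.47-fold per stage
    guildSpec("transient_corynebacterium", 24, "transient",
              baseFraction = 24 * 10^(-1.58 - 2 * 0.54),
              rate = 10^0.54, hostGenus = "Corynebacterium",
              phageGroup = "Corynebacterium_phages"),
    guildSpec("stable_987", 22, "stable", baseFraction = 22 * 10^-2.7,
              hostGenus = "Streptococcus", phageGroup = "987"),
    guildSpec("sporadic_background", 21, "sporadic",
              hostGenus = NA_character_, phageGroup = "unassigned"))
}

#' Compact benchmark design for differential-abundance power
#'
#' A small design tuned for differential-abundance benchmarking rather
#' than profile clustering: a handful of high-abundance planted movers
#' (declining at exactly -4 log2, rising at exactly +4 log2) whose raw
#' counts stay deep in the well-powered regime, two stable guilds, and a
#' large sporadic background supplying null features.  Use with
#' [communityDesign()] wherever planted fold-change recovery is the
#' question; [defaultGuilds()] remains the general-purpose succession
#' design.
#'
#' @return data.frame of guild specifications
#' @export
daBenchmarkGuilds <- function() {
  rbind(
    guildSpec("stable_936", 6, "stable", baseFraction = 0.17,
              hostGenus = "Lactococcus", phageGroup = "936"),
    guildSpec("stable_949", 6, "stable", baseFraction = 0.012,
              hostGenus = "Lactococcus", phageGroup = "949"),
    guildSpec("declining_p335", 5, "declining", baseFraction = 0.30,
              rate = 2^(-4 / 3), hostGenus = "Lactococcus",
              phageGroup = "P335", temperate = TRUE),
    guildSpec("rising_glutamicibacter", 1, "rising", baseFraction = 0.0065,
              rate = 16, hostGenus = "Glutamicibacter",
              phageGroup = "Glutamicibacter_phages"),
    guildSpec("rising_brevibacterium", 1, "rising", baseFraction = 0.0065,
              rate = 16, hostGenus = "Brevibacterium",
              phageGroup = "Brevibacterium_phages"),
    guildSpec("rising_psychrobacter", 1, "rising", baseFraction = 0.0065,
              rate = 16, hostGenus = "Psychrobacter",
              phageGroup = "Psychrobacter_phages"),
    guildSpec("sporadic_background", 80, "sporadic",
              hostGenus = NA_character_, phageGroup = "unassigned"))
}

#' Community design: everything the generators need
#'
#' Defaults mirror a desk-scale reduction (~3x) of a typical cheese-surface
#' virome study: 113 vOTUs, 5 ripening stages x 3 replicates (short term),
#' 3 production years x 3 replicates (long term), library sizes around
#' 1e5 reads.  `theta` is the Dirichlet concentration controlling replicate
#' overdispersion (larger = less noise).
#'
#' @param guilds data.frame of [guildSpec()] rows
#' @param nStages,nReplicates,nYears study dimensions
#' @param librarySizeLog10Mean,librarySizeLog10SD log10 library size
#'   distribution
#' @param theta Dirichlet concentration (> 0).  Replicate noise of a vOTU
#'   at expected relative abundance p scales as 1/sqrt(theta * p); the
#'   planted guild structure is only statistically identifiable when
#'   `theta * p` stays around 1 or above for every planted vOTU at every
#'   stage, which with the default design (rarest planted share ~6e-4 at
#'   the declining guild's final stage) requires theta around 2000.
#'   Smaller values are valid and simply bury the rarest guilds in noise.
#' @param lengthRange genome length range in bp (log-uniform sampling)
#' @param nMemberVotus how many vOTUs receive mutated member copies
#' @param membersPerVotu member copies per such vOTU
#' @param memberRate per-base substitution rate of member copies (0.03 puts
#'   them at ~97% identity, same species at the 0.90 score threshold)
#' @param nOutgroups number of outgroup copies (distinct species)
#' @param outgroupRate substitution rate of outgroup copies
#' @param nChimeras chimeric contigs (genome plus duplicate of its first
#'   half)
#' @param nFragments sub-2-kb genome fragments
#' @param nNonviral non-viral contigs (never qualify in tool reports)
#' @param iphopErrorRate probability that the emulated host prediction
#'   reports a wrong genus
#' @param yearDropFraction fraction of sporadic vOTUs absent in any given
#'   production year
#' @param yearTheta Dirichlet concentration of the year-level composition
#'   shift
#' @param bacteriomeNoiseSd lognormal noise (log10 scale) of the bacterial
#'   absolute abundances and plate counts
#' @return list of class `CommunityDesign`
#' @export
communityDesign <- function(guilds = defaultGuilds(), nStages = 5,
                            nReplicates = 3, nYears = 3,
                            librarySizeLog10Mean = 5,
                            librarySizeLog10SD = 0.05,
                            theta = 2000,
                            lengthRange = c(2002, 150000),
                            nMemberVotus = 25, membersPerVotu = 1,
                            memberRate = 0.03,
                            nOutgroups = 10, outgroupRate = 0.25,
                            nChimeras = 3, nFragments = 5, nNonviral = 10,
                            iphopErrorRate = 0.1,
                            yearDropFraction = 0.4, yearTheta = 2000,
                            bacteriomeNoiseSd = 0.1) {
  if (!nrow(guilds)) stop("degenerate design: no guilds")
  base_sum <- sum(guilds$base_fraction[guilds$dynamic != "sporadic"])
  if (base_sum > 1 + 1e-9) {
    stop("guild base fractions sum above 1 (", round(base_sum, 3), ")")
  }
  if (theta <= 0 || !is.finite(theta)) stop("theta must be finite and > 0")
  structure(list(
    guilds = guilds, nStages = as.integer(nStages),
    nReplicates = as.integer(nReplicates), nYears = as.integer(nYears),
    librarySizeLog10Mean = librarySizeLog10Mean,
    librarySizeLog10SD = librarySizeLog10SD,
    theta = theta, lengthRange = lengthRange,
    nMemberVotus = as.integer(nMemberVotus),
    membersPerVotu = as.integer(membersPerVotu),
    memberRate = memberRate, nOutgroups = as.integer(nOutgroups),
    outgroupRate = outgroupRate, nChimeras = as.integer(nChimeras),
    nFragments = as.integer(nFragments), nNonviral = as.integer(nNonviral),
    iphopErrorRate = iphopErrorRate,
    yearDropFraction = yearDropFraction, yearTheta = yearTheta,
    bacteriomeNoiseSd = bacteriomeNoiseSd),
    class = "CommunityDesign")
}

.votuIds <- function(design) {
  n <- sum(design$guilds$n_votus)
  sprintf("votu%03d", seq_len(n))
}

.votuGuilds <- function(design) {
  rep(design$guilds$name, times = design$guilds$n_votus)
}

#' Generate synthetic genomes and the contig-level ground truth
#'
#' One reference genome per planned vOTU (length log-uniform over the
#' design range), mutated member copies (same species), outgroup copies
#' (distinct species), chimeras (genome plus a duplicate of its first
#' half), sub-threshold fragments, one PhiX174 decoy and non-viral contigs.
#'
#' @param design a [communityDesign()]
#' @param seed integer seed
#' @return list with `contigs` (named `DNAStringSet`) and `truth`
#'   (per-contig data.frame: `contig_id`, `role`, `cluster`, `guild`,
#'   `host_genus`, `phage_group`, `viral`, `temperate`, `chimera`,
#'   `sub_threshold`)
#' @export
generateGenomes <- function(design = communityDesign(), seed = 1) {
  set.seed(seed)
  g <- design$guilds
  ids <- .votuIds(design)
  guild_of <- .votuGuilds(design)
  lo <- log(design$lengthRange[1]); hi <- log(design$lengthRange[2])
  lens <- round(exp(runif(length(ids), lo, hi)))
  seqs <- vapply(lens, randomDNA, character(1))
  names(seqs) <- ids
  truth_row <- function(id, role, cluster, guild, viral = TRUE,
                        temperate = FALSE, chimera = FALSE,
                        sub_threshold = FALSE) {
    gi <- match(guild, g$name)
    data.frame(contig_id = id, role = role, cluster = cluster,
               guild = guild,
               host_genus = if (is.na(gi)) NA_character_ else g$host_genus[gi],
               phage_group = if (is.na(gi)) NA_character_ else g$phage_group[gi],
               viral = viral, temperate = temperate, chimera = chimera,
               sub_threshold = sub_threshold, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(seq_along(ids), function(i) {
    truth_row(ids[i], "genome", ids[i], guild_of[i],
              temperate = g$temperate[match(guild_of[i], g$name)])
  }))
  add <- function(seqs, truth, s, row) {
    seqs[[row$contig_id]] <- s
    list(seqs = seqs, truth = rbind(truth, row))
  }
  ## member copies: same species as their source genome
  member_src <- ids[seq_len(min(design$nMemberVotus, length(ids)))]
  for (src in member_src) {
    for (m in seq_len(design$membersPerVotu)) {
      id <- sprintf("%s_m%d", src, m)
      r <- truth_row(id, "member", src, guild_of[match(src, ids)],
                     temperate = truth$temperate[truth$contig_id == src])
      out <- add(seqs, truth, mutateSequence(seqs[[src]], design$memberRate),
                 r)
      seqs <- out$seqs; truth <- out$truth
    }
  }
  ## outgroup copies: far enough to found their own species
  og_src <- ids[seq_len(min(design$nOutgroups, length(ids)))]
  for (k in seq_along(og_src)) {
    id <- sprintf("%s_og", og_src[k])
    out <- add(seqs, truth,
               mutateSequence(seqs[[og_src[k]]], design$outgroupRate),
               truth_row(id, "outgroup", id, NA_character_))
    seqs <- out$seqs; truth <- out$truth
  }
  ## chimeras: genome plus duplicate of its first half
  for (k in seq_len(design$nChimeras)) {
    src <- seqs[[ids[k]]]
    half <- substr(src, 1, nchar(src) %/% 2)
    out <- add(seqs, truth, paste0(src, half),
               truth_row(sprintf("chimera%d", k), "chimera", NA_character_,
                         NA_character_, chimera = TRUE))
    seqs <- out$seqs; truth <- out$truth
  }
  ## sub-threshold fragments of real genomes
  for (k in seq_len(design$nFragments)) {
    src <- seqs[[ids[(k %% length(ids)) + 1]]]
    flen <- sample(300:1990, 1)
    start <- sample(seq_len(max(1, nchar(src) - flen)), 1)
    out <- add(seqs, truth, substr(src, start, start + flen - 1),
               truth_row(sprintf("frag%d", k), "fragment", NA_character_,
                         NA_character_, sub_threshold = TRUE))
    seqs <- out$seqs; truth <- out$truth
  }
  ## PhiX sequencing-control decoy
  out <- add(seqs, truth, randomDNA(5386),
             truth_row("PhiX174", "phix", "PhiX174", NA_character_))
  seqs <- out$seqs; truth <- out$truth
  ## non-viral contigs (host DNA): never qualify as viral
  for (k in seq_len(design$nNonviral)) {
    id <- sprintf("host%02d", k)
    out <- add(seqs, truth, randomDNA(round(exp(runif(1, lo, hi)))),
               truth_row(id, "nonviral", id, NA_character_, viral = FALSE))
    seqs <- out$seqs; truth <- out$truth
  }
  rownames(truth) <- NULL
  list(contigs = Biostrings::DNAStringSet(unlist(seqs)), truth = truth)
}

## per-guild share trajectory over stages 1..nStages (no renormalization)
.guildShares <- function(guild, nStages) {
  s <- seq_len(nStages)
  switch(guild$dynamic,
    stable = rep(guild$base_fraction, nStages),
    declining = guild$base_fraction * guild$rate^(s - 1),
    transient = guild$base_fraction * guild$rate^pmin(s - 1, nStages - s),
    rising = {
      sig <- stats::plogis(.RISE_K * (s - .RISE_S0))
      lowIdx <- 1:2
      highIdx <- (nStages - 1):nStages
      R <- guild$rate
      cc <- (mean(sig[highIdx]) - R * mean(sig[lowIdx])) / (R - 1)
      if (cc < 0) {
        stop(sprintf(
          "rising guild '%s': fold change %g unreachable with the logistic shape",
          guild$name, R))
      }
      delta <- guild$base_fraction / (cc + sig[1])
      cc * delta + delta * sig
    },
    sporadic = rep(0, nStages))
}

#' Expected relative-abundance dynamics (stage x vOTU)
#'
#' Builds each guild's share trajectory (stable: constant; declining:
#' geometric in stage; rising: logistic in stage calibrated to the guild's
#' fold change between the W1-2 and W4-5 means; transient: geometric rise
#' to the middle stage then the mirror-image fall), splits guild shares
#' equally among the guild's vOTUs, lets any sporadic guild absorb the
#' per-stage remainder, and renormalizes each stage to sum to 1.  The
#' expected log2 fold change of every vOTU between the W1-2 and W4-5 phase
#' means is recorded.
#'
#' @param design a [communityDesign()]
#' @return matrix (stages x vOTUs) with attributes `log2fc` (named vector)
#'   and `raw` (per-guild unnormalized share matrix)
#' @export
generateDynamics <- function(design = communityDesign()) {
  g <- design$guilds
  nS <- design$nStages
  shares <- vapply(seq_len(nrow(g)), function(i) {
    .guildShares(g[i, ], nS)
  }, numeric(nS))
  colnames(shares) <- g$name
  spor <- g$dynamic == "sporadic"
  if (any(spor)) {
    remainder <- 1 - rowSums(shares[, !spor, drop = FALSE])
    if (any(remainder < 0)) stop("guild shares exceed 1 at some stage")
    shares[, spor] <- remainder / sum(spor)
  }
  ## expand to vOTUs: equal split within each guild, so guild membership is
  ## the only source of profile differences
  tensor <- do.call(cbind, lapply(seq_len(nrow(g)), function(i) {
    m <- matrix(rep(shares[, i] / g$n_votus[i], g$n_votus[i]), nrow = nS)
    m
  }))
  colnames(tensor) <- .votuIds(design)
  rownames(tensor) <- paste0("W", seq_len(nS))
  tensor <- tensor / rowSums(tensor)
  lowIdx <- 1:2
  highIdx <- (nS - 1):nS
  l2fc <- log2(colMeans(tensor[highIdx, , drop = FALSE]) /
                 colMeans(tensor[lowIdx, , drop = FALSE]))
  attr(tensor, "log2fc") <- l2fc
  attr(tensor, "raw") <- shares
  tensor
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Sample a raw count table from expected compositions
#'
#' Per sample: composition ~ Dirichlet(theta x expected vector), library
#' size ~ round(10^Normal(mean, sd)), counts ~ Multinomial(library,
#' composition).
#'
#' @param expected stage-by-vOTU matrix (rows sum to 1), e.g. from
#'   [generateDynamics()]
#' @param design a [communityDesign()]
#' @param seed integer seed
#' @param study study label recorded in the metadata
#' @return `ViromeCounts` in state `raw` with stage/replicate metadata
#' @export
sampleCounts <- function(expected, design = communityDesign(), seed = 1,
                         study = "short_term") {
  if (design$theta <= 0) stop("theta must be > 0")
  set.seed(seed)
  reps <- LETTERS[seq_len(design$nReplicates)]
  stage_names <- rownames(expected)
  samples <- as.vector(outer(stage_names, reps, paste0))
  m <- matrix(0L, ncol(expected), length(samples),
              dimnames = list(colnames(expected), samples))
  md <- data.frame(sample_id = samples, study = study,
                   group = rep(stage_names, times = length(reps)),
                   replicate = rep(reps, each = length(stage_names)),
                   stringsAsFactors = FALSE)
  rownames(md) <- samples
  for (j in seq_along(samples)) {
    p <- expected[md$group[j], ]
    w <- .rdirichlet(design$theta * p)
    lib <- round(10^rnorm(1, design$librarySizeLog10Mean,
                          design$librarySizeLog10SD))
    m[, j] <- as.integer(rmultinom(1, size = lib, prob = w))
  }
  ViromeCounts(m, sampleData = md, state = "raw")
}

#' Generate the correlated bacterial community
#'
#' Absolute genus abundances: the LAB genus (*Lactococcus*) is constant at
#' 1e8 CFU/g; aerobic ripening genera (the hosts of the rising phage
#' guilds) grow log-linearly from a combined 1e8 to 1e10 CFU/g across the
#' ripening stages, split equally.  Per-sample lognormal noise
#' (`bacteriomeNoiseSd`, log10 scale) is applied to the absolutes; the
#' relative table is the per-sample total-sum scaling of the noisy
#' absolutes and the plate counts are log10 totals plus Gaussian noise of
#' the same sd.
#'
#' @param design a [communityDesign()]
#' @param seed integer seed
#' @return list with `genusRelative` (`ViromeCounts`, state `relative`),
#'   `plateCounts` (data.frame: `sample_id`, `lab_log10`, `aerobic_log10`)
#'   and `genusAbsolute` (matrix)
#' @export
generateBacteriome <- function(design = communityDesign(), seed = 1) {
  set.seed(seed)
  g <- design$guilds
  aerobes <- unique(stats::na.omit(g$host_genus[g$dynamic == "rising"]))
  if (!length(aerobes)) aerobes <- "Glutamicibacter"
  lab <- "Lactococcus"
  genera <- c(lab, aerobes)
  nS <- design$nStages
  reps <- LETTERS[seq_len(design$nReplicates)]
  stage_names <- paste0("W", seq_len(nS))
  samples <- as.vector(outer(stage_names, reps, paste0))
  stage_of <- rep(seq_len(nS), times = length(reps))
  total_aerobic <- 10^(8 + 2 * (seq_len(nS) - 1) / (nS - 1))
  abs_design <- rbind(
    rep(1e8, nS),
    matrix(rep(total_aerobic / length(aerobes), each = length(aerobes)),
           nrow = length(aerobes)))
  dimnames(abs_design) <- list(genera, stage_names)
  noise <- design$bacteriomeNoiseSd
  absm <- vapply(seq_along(samples), function(j) {
    abs_design[, stage_of[j]] *
      10^rnorm(length(genera), 0, noise)
  }, numeric(length(genera)))
  dimnames(absm) <- list(genera, samples)
  rel <- sweep(absm, 2, colSums(absm), "/")
  md <- data.frame(sample_id = samples, study = "short_term",
                   group = stage_names[stage_of],
                   replicate = rep(reps, each = nS),
                   stringsAsFactors = FALSE)
  rownames(md) <- samples
  plate <- data.frame(
    sample_id = samples,
    lab_log10 = log10(absm[lab, ]) + rnorm(length(samples), 0, noise) * 0,
    aerobic_log10 = log10(colSums(absm[aerobes, , drop = FALSE])) +
      rnorm(length(samples), 0, noise) * 0,
    stringsAsFactors = FALSE)
  ## plate-count noise: measurement error on the log10 scale
  plate$lab_log10 <- plate$lab_log10 + rnorm(length(samples), 0, noise)
  plate$aerobic_log10 <- plate$aerobic_log10 + rnorm(length(samples), 0, noise)
  list(genusRelative = ViromeCounts(rel, sampleData = md,
                                    state = "relative"),
       plateCounts = plate, genusAbsolute = absm)
}

#' Emulated viral-detection tool reports
#'
#' Viral contigs receive at least one qualifying label (complete, high or
#' medium from VIBRANT or CheckV, or "full" from VirSorter2); which tool
#' fires is drawn from `toolProbs`.  Non-viral contigs only receive
#' non-qualifying labels.  Temperate contigs get
#' `vibrant_lifestyle = temperate`; host predictions copy the truth genus
#' with error rate `design$iphopErrorRate`.
#'
#' @param truth truth data.frame from [generateGenomes()]
#' @param design a [communityDesign()]
#' @param seed integer seed
#' @param toolProbs probabilities that (CheckV, VIBRANT, VirSorter2)
#'   provides the qualifying label (one is always chosen; the others may
#'   add non-qualifying or absent labels)
#' @return tool report data.frame (see [readToolReports()])
#' @export
generateToolReports <- function(truth, design = communityDesign(), seed = 1,
                                toolProbs = c(checkv = 0.5, vibrant = 0.3,
                                              virsorter2 = 0.2)) {
  set.seed(seed)
  n <- nrow(truth)
  tiers_q <- c("complete", "high", "medium")
  genera <- unique(stats::na.omit(truth$host_genus))
  rep <- data.frame(contig_id = truth$contig_id,
                    vibrant_quality = NA_character_,
                    vibrant_lifestyle = NA_character_,
                    checkv_quality = NA_character_,
                    virsorter2_label = NA_character_,
                    iphop_genus = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (truth$viral[i]) {
      tool <- sample(names(toolProbs), 1, prob = toolProbs)
      tier <- sample(tiers_q, 1, prob = c(0.2, 0.3, 0.5))
      if (tool == "checkv") rep$checkv_quality[i] <- tier
      if (tool == "vibrant") rep$vibrant_quality[i] <- tier
      if (tool == "virsorter2") rep$virsorter2_label[i] <- "full"
      ## the other tools may add weak evidence
      if (tool != "checkv" && runif(1) < 0.3) {
        rep$checkv_quality[i] <- "low"
      }
      if (truth$temperate[i]) {
        rep$vibrant_lifestyle[i] <- "temperate"
        if (is.na(rep$vibrant_quality[i])) {
          rep$vibrant_quality[i] <- "low"
        }
      }
      if (!is.na(truth$host_genus[i])) {
        wrong <- runif(1) < design$iphopErrorRate
        rep$iphop_genus[i] <- if (wrong && length(genera) > 1) {
          sample(setdiff(genera, truth$host_genus[i]), 1)
        } else {
          truth$host_genus[i]
        }
      }
    } else {
      if (runif(1) < 0.5) rep$checkv_quality[i] <- "low"
    }
  }
  rep
}

#' Synthetic dairy phage reference database
#'
#' One database entry per non-sporadic guild: a mutated copy (default 8%
#' substitutions, i.e. well above the 30% identity-by-coverage match
#' cutoff) of the guild's first genome, annotated with the guild's host
#' genus and group, plus one unrelated decoy entry that matches nothing.
#'
#' @param genomes list from [generateGenomes()]
#' @param design a [communityDesign()]
#' @param seed integer seed
#' @param dbRate substitution rate of the database copies
#' @return list (`sequences`, `info`) as from [readDairyDB()], plus
#'   `source_votu` in `info`
#' @export
generateDairyDB <- function(genomes, design = communityDesign(), seed = 1,
                            dbRate = 0.08) {
  set.seed(seed)
  g <- design$guilds[design$guilds$dynamic != "sporadic", , drop = FALSE]
  ids <- .votuIds(design)
  guild_of <- .votuGuilds(design)
  seqs <- character(0); info <- NULL
  for (i in seq_len(nrow(g))) {
    src <- ids[match(g$name[i], guild_of)]
    nm <- paste0("ref_", g$name[i])
    seqs[[nm]] <- mutateSequence(
      as.character(genomes$contigs[[src]]), dbRate)
    info <- rbind(info, data.frame(
      phage_name = nm, host_genus = g$host_genus[i],
      phage_group = g$phage_group[i],
      lifestyle = if (g$temperate[i]) "temperate" else "virulent",
      source_votu = src, stringsAsFactors = FALSE))
  }
  seqs[["ref_unrelated"]] <- randomDNA(30000)
  info <- rbind(info, data.frame(
    phage_name = "ref_unrelated", host_genus = "Halomonas",
    phage_group = "environmental", lifestyle = "virulent",
    source_votu = NA_character_, stringsAsFactors = FALSE))
  list(sequences = Biostrings::DNAStringSet(seqs), info = info)
}

#' Simulate the full study
#'
#' Generates genomes and truth, tool reports, the dairy database, the
#' short-term stage-by-replicate count table, the long-term
#' year-by-replicate count table (one genome pool reused across years,
#' year-specific sporadic membership and Dirichlet-resampled year
#' compositions around the post-ripening profile) and the bacterial
#' community, all deterministically from one seed.
#'
#' @param design a [communityDesign()]
#' @param seed integer master seed
#' @return list with `contigs`, `truth`, `reports`, `dairyDB`, `dynamics`,
#'   `guildOfVotu`, `shortTerm`, `longTerm`, `bacteriome`, `votuLengths`
#' @export
simulateCommunity <- function(design = communityDesign(), seed = 1) {
  genomes <- generateGenomes(design, seed = seed)
  dyn <- generateDynamics(design)
  reports <- generateToolReports(genomes$truth, design, seed = seed + 1)
  db <- generateDairyDB(genomes, design, seed = seed + 2)
  short <- sampleCounts(dyn, design, seed = seed + 3, study = "short_term")
  ## long-term arm: year compositions derived from the final ripening stage
  set.seed(seed + 4)
  years <- c("2017", "2019", "2022")[seq_len(design$nYears)]
  base <- dyn[design$nStages, ]
  guild_of <- .votuGuilds(design)
  spor <- guild_of %in%
    design$guilds$name[design$guilds$dynamic == "sporadic"]
  year_expected <- t(vapply(years, function(y) {
    p <- .rdirichlet(design$yearTheta * base)
    drop <- spor & runif(length(p)) < design$yearDropFraction
    p[drop] <- 0
    p / sum(p)
  }, numeric(length(base))))
  rownames(year_expected) <- years
  colnames(year_expected) <- colnames(dyn)
  long_design <- design
  long <- sampleCounts(year_expected, design, seed = seed + 5,
                       study = "long_term")
  bact <- generateBacteriome(design, seed = seed + 6)
  ids <- .votuIds(design)
  lens <- setNames(Biostrings::width(genomes$contigs[ids]), ids)
  list(contigs = genomes$contigs, truth = genomes$truth,
       reports = reports, dairyDB = db, dynamics = dyn,
       guildOfVotu = setNames(guild_of, ids),
       yearExpected = year_expected,
       shortTerm = short, longTerm = long, bacteriome = bact,
       votuLengths = lens, design = design, seed = seed)
}
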
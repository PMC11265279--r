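test_that("catalogThresholds validates its inputs", {
  th <- catalogThresholds()
  expect_equal(th$minLength, 2000)
  expect_equal(th$speciesScore, 0.90)
  expect_equal(th$chimeraFraction, 1.10)
  expect_equal(th$dairyScore, 0.30)
  expect_error(catalogThresholds(speciesScore = 0))
})

test_that("filterMinLength keeps strictly longer contigs only", {
  contigs <- Biostrings::DNAStringSet(c(
    short = rdna(1999, seed = 1), exact = rdna(2000),
    kept = rdna(2001)))
  out <- filterMinLength(contigs)
  expect_identical(names(out), "kept")
  expect_setequal(attr(out, "removed_ids"), c("short", "exact"))
})

test_that("removeChimeras is strict at the 1.10 boundary", {
  contigs <- Biostrings::DNAStringSet(c(
    a = rdna(2500, seed = 2), b = rdna(2500), c = rdna(2500)))
  fr <- c(a = 1.10, b = 1.1000001, c = 0.99)
  out <- removeChimeras(contigs, fractions = fr)
  expect_setequal(names(out), c("a", "c"))
  expect_identical(attr(out, "removed_ids"), "b")
})

test_that("greedy clustering recovers the planted species partition", {
  sim <- simulateDefault(seed = 11, design = tinyDesign())
  th <- catalogThresholds()
  kept <- filterMinLength(sim$contigs, th)
  kept <- removeChimeras(kept, thresholds = th)
  scores <- allVsAll(kept)
  cat <- clusterSpecies(kept, scores, th)
  acc <- contigAccounting(cat)
  truth <- sim$truth
  votu_of <- setNames(acc$votu, acc$contig_id)
  ## members at 3% divergence join their source genome's cluster
  members <- truth$contig_id[truth$role == "member"]
  for (m in members) {
    expect_identical(votu_of[[m]], votu_of[[truth$cluster[truth$contig_id == m]]])
  }
  ## outgroups at 25% divergence found their own clusters
  outgroups <- truth$contig_id[truth$role == "outgroup"]
  for (og in outgroups) {
    expect_identical(votu_of[[og]], og)
  }
  ## distinct genomes never merge
  genomes <- intersect(truth$contig_id[truth$role == "genome"], names(kept))
  expect_equal(anyDuplicated(votu_of[genomes]), 0)
  ## representatives are the longest member of their cluster
  v <- votuTable(cat)
  lens <- setNames(Biostrings::width(kept), names(kept))
  for (i in seq_len(nrow(v))) {
    expect_equal(v$length[i],
                 max(lens[votuMembers(cat)[[v$representative_id[i]]]]))
  }
})

test_that("greedy result equals the brute-force oracle", {
  sim <- simulateDefault(seed = 12, design = tinyDesign())
  th <- catalogThresholds()
  kept <- removeChimeras(filterMinLength(sim$contigs, th), thresholds = th)
  expect_lte(length(kept), 50)
  scores <- allVsAll(kept)
  cat <- clusterSpecies(kept, scores, th)
  acc <- contigAccounting(cat)
  oracle <- greedyOracle(kept, scores, th$speciesScore)
  expect_identical(setNames(acc$votu, acc$contig_id)[names(oracle)], oracle)
  ## input order invariance
  perm <- kept[rev(seq_along(kept))]
  cat2 <- clusterSpecies(perm, scores, th)
  expect_setequal(votuTable(cat2)$representative_id,
                  votuTable(cat)$representative_id)
})

test_that("selectViral applies the union rule and removes PhiX", {
  seqs <- Biostrings::DNAStringSet(c(
    v1 = rdna(2500, seed = 13), v2 = rdna(2500), v3 = rdna(2500),
    PhiX174 = rdna(2500)))
  scores <- allVsAll(seqs)
  cat <- clusterSpecies(seqs, scores)
  reports <- data.frame(
    contig_id = c("v1", "v2", "v3", "PhiX174"),
    vibrant_quality = c(NA, "low", "high", NA),
    vibrant_lifestyle = NA_character_,
    checkv_quality = c("medium", NA, "low", "complete"),
    virsorter2_label = c(NA, NA, NA, NA),
    iphop_genus = NA_character_, stringsAsFactors = FALSE)
  out <- selectViral(cat, reports)
  v <- votuTable(out)
  ## v1 qualifies via CheckV, v3 via VIBRANT (union), v2 does not;
  ## PhiX qualifies but is discarded as the control
  expect_setequal(v$representative_id, c("v1", "v3"))
  ## recorded tier prefers CheckV when present
  expect_equal(v$quality[v$representative_id == "v3"], "low")
  expect_equal(v$quality[v$representative_id == "v1"], "medium")
  acc <- contigAccounting(out)
  expect_equal(acc$fate[acc$contig_id == "v2"], "discarded_nonviral")
  expect_equal(acc$fate[acc$contig_id == "PhiX174"], "discarded_phix")
  ## virsorter2 "full" alone also qualifies
  reports$virsorter2_label[2] <- "full"
  out2 <- selectViral(cat, reports)
  expect_true("v2" %in% votuTable(out2)$representative_id)
  ## with no CheckV tier, the recorded tier falls back to VIBRANT's
  expect_equal(votuTable(out2)$quality[
    votuTable(out2)$representative_id == "v2"], "low")
})

test_that("flagLifestyle marks only VIBRANT-temperate representatives", {
  seqs <- Biostrings::DNAStringSet(c(a = rdna(2500, seed = 14),
                                     b = rdna(2500)))
  cat <- clusterSpecies(seqs, allVsAll(seqs))
  reports <- data.frame(
    contig_id = c("a", "b"), vibrant_quality = c("high", "high"),
    vibrant_lifestyle = c("temperate", NA),
    checkv_quality = NA_character_, virsorter2_label = NA_character_,
    iphop_genus = NA_character_, stringsAsFactors = FALSE)
  out <- flagLifestyle(selectViral(cat, reports), reports)
  v <- votuTable(out)
  expect_equal(v$lifestyle[v$representative_id == "a"], "temperate")
  expect_equal(v$lifestyle[v$representative_id == "b"],
               "virulent_or_unknown")
})

test_that("matchDairyDB and assignHost fill matches and override hosts", {
  sim <- simulateDefault(seed = 15, design = tinyDesign())
  cat <- buildCatalog(sim$contigs, sim$reports, db = sim$dairyDB)
  v <- votuTable(cat)
  truth <- sim$truth
  info <- sim$dairyDB$info
  ## database entries are 8% mutations of each non-sporadic guild's first
  ## genome: that source vOTU must match its reference with the right group
  for (i in which(!is.na(info$source_votu))) {
    src <- info$source_votu[i]
    row <- v[v$representative_id == src, ]
    expect_equal(row$dairy_phage, info$phage_name[i])
    expect_gte(row$dairy_score, 0.30)
    expect_equal(row$phage_group, info$phage_group[i])
    ## verified host overrides any iPHoP prediction
    expect_equal(row$host_genus, info$host_genus[i])
  }
  ## the unrelated decoy matches nothing
  expect_false("ref_unrelated" %in% v$dairy_phage)
  ## dairy-matched temperate references refine the lifestyle
  temperate_refs <- info$phage_name[info$lifestyle == "temperate"]
  matched_temp <- v$representative_id[v$dairy_phage %in% temperate_refs]
  expect_true(all(v$lifestyle[v$representative_id %in% matched_temp] ==
                    "temperate"))
  ## unmatched vOTUs fall back to the iPHoP genus
  unmatched <- v[is.na(v$dairy_phage), ]
  rep_rows <- sim$reports[match(unmatched$representative_id,
                                sim$reports$contig_id), ]
  expect_identical(unmatched$host_genus, rep_rows$iphop_genus)
})

test_that("buildCatalog accounts for every contig exactly once", {
  sim <- simulateDefault(seed = 16, design = tinyDesign())
  cat <- buildCatalog(sim$contigs, sim$reports, db = sim$dairyDB)
  acc <- contigAccounting(cat)
  expect_setequal(acc$contig_id, names(sim$contigs))
  expect_equal(anyDuplicated(acc$contig_id), 0)
  truth <- sim$truth
  fate_of <- setNames(acc$fate, acc$contig_id)
  ## planted fates map to the right bins
  expect_true(all(fate_of[truth$contig_id[truth$sub_threshold]] ==
                    "discarded_short"))
  expect_true(all(fate_of[truth$contig_id[truth$chimera]] ==
                    "discarded_chimera"))
  expect_true(all(fate_of[truth$contig_id[truth$role == "nonviral"]] ==
                    "discarded_nonviral"))
  expect_equal(unname(fate_of["PhiX174"]), "discarded_phix")
  expect_true(all(fate_of[truth$contig_id[truth$role %in%
                                            c("genome", "member")]] ==
                    "member_of_votu"))
  ## retained vOTUs are exactly the planted genomes plus the outgroups
  ## (outgroups are viral contigs founding their own species)
  expect_setequal(votuTable(cat)$representative_id,
                  truth$contig_id[truth$role %in% c("genome", "outgroup")])
})

test_that("summarizeCatalog reproduces worked percentages half-up", {
  n <- 331
  ids <- sprintf("c%03d", seq_len(n))
  votus <- data.frame(
    representative_id = ids,
    length = c(rep(15000, 79), rep(5000, n - 79)),
    n_members = 1L,
    quality = c(rep("complete", 25), rep("medium", n - 25)),
    lifestyle = c(rep("temperate", 27), rep("virulent_or_unknown", n - 27)),
    host_genus = c(rep("Lactococcus", 272), rep(NA_character_, n - 272)),
    dairy_phage = c(rep("ref_x", 134), rep(NA_character_, n - 134)),
    dairy_score = NA_real_, phage_group = NA_character_,
    stringsAsFactors = FALSE)
  cat <- methods::new("VOTUCatalog", votus = votus,
                      members = setNames(as.list(ids), ids),
                      accounting = data.frame(
                        contig_id = ids, fate = "member_of_votu",
                        votu = ids, stringsAsFactors = FALSE))
  s <- summarizeCatalog(cat)
  expect_equal(s$n_votus, 331)
  expect_equal(s$pct_over_10kb, 24)       # 79/331  = 23.867 -> 24 (0 dp)
  expect_equal(s$pct_complete, 7.6)       # 25/331  = 7.5529 -> 7.6
  expect_equal(s$pct_temperate, 8.2)      # 27/331  = 8.1571 -> 8.2
  expect_equal(s$pct_with_host, 82.2)     # 272/331 = 82.175 -> 82.2
  expect_equal(s$pct_dairy_matched, 40.5) # 134/331 = 40.483 -> 40.5
  expect_equal(s$genus_counts$Lactococcus, 272)
})

test_that("percentage rounding is half-up, not banker's", {
  expect_equal(cheesevirome:::.roundHalfUp(0.25, 1), 0.3)
  expect_equal(cheesevirome:::.roundHalfUp(0.35, 1), 0.4)
  expect_equal(cheesevirome:::.roundHalfUp(82.15, 1), 82.2)
})
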
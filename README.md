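# cheesevirome

Tools for studying the viral side of cheese ripening: building
species-level viral operational taxonomic unit (vOTU) catalogs from
assembled metavirome contigs, and analysing how the phage community of a
smear-ripened cheese surface turns over during ripening and persists
across production years.

## Background

The surface of a smear-ripened cheese is a dense, rapidly changing
microbial ecosystem. Ripening starts dominated by the inoculated lactic
acid bacteria (chiefly *Lactococcus*) and their phages; over a few weeks
the washed rind is colonized by aerobic, salt-tolerant ripening genera
(*Glutamicibacter*, *Brevibacterium*, *Psychrobacter*, and relatives),
and the virome tracks this succession: starter phages decline while
phages infecting the ripening bacteria rise. Because phage genomes carry
no universal marker gene, the community is studied through assembled
contigs that must first be dereplicated into species-level vOTUs
(clusters at an identity-by-coverage score of at least 0.90, represented
by their longest member) before any ecology can be done.

The package implements that pipeline end to end:

* **Catalog construction** — minimum-length filtering, chimera removal
  by self-alignment, greedy dereplication on an identity-by-coverage
  score computed by a seed-and-extend pairwise aligner (C++), a union
  rule over viral-detection tool reports (VIBRANT / CheckV /
  VirSorter2), PhiX control removal, temperate-lifestyle flagging, dairy
  phage reference matching at a 0.30 score cutoff with verified-host
  override, and per-contig fate accounting.
* **Abundance profiles** — rarefaction without replacement, length
  normalization, total-sum scaling and mean-abundance filtering, tracked
  by an explicit normalization state machine on a
  `SummarizedExperiment`-derived container (`ViromeCounts`).
* **Ecology** — Shannon diversity, Bray–Curtis dissimilarity, principal
  coordinate analysis, PERMANOVA, Mantel and Kruskal–Wallis tests with
  permutation p-values, Spearman correlation screens against the
  bacterial community.
* **Succession clustering** — complete-linkage clustering of per-stage
  mean log relative-abundance profiles with the cluster count selected
  by the within-cluster sum-of-squares (WSS) elbow.
* **Differential abundance** — a negative-binomial Wald test with
  median-of-ratios size factors and a three-part significance rule
  (adjusted p < 0.01, |log2 fold change| > 3, mean raw count > 1500).
* **Persistence** — presence/absence across production years, exact
  three-set Venn partitions, and the core virome.
* **Synthetic communities** — a fully seeded generator
  (`simulateCommunity()`) that plants guild structure, fold changes,
  genome-level artefacts (members, outgroups, chimeras, fragments,
  PhiX, host DNA) and a correlated bacterial community, with complete
  ground truth for validating every stage.

## Worked example

```r
library(cheesevirome)

## a synthetic ripening study with recorded ground truth
sim <- simulateCommunity(communityDesign(), seed = 42)

## build the vOTU catalog from the contigs and tool reports
catalog <- buildCatalog(sim$contigs, sim$reports, db = sim$dairyDB)
summarizeCatalog(catalog)

## normalize the short-term count table
counts <- rarefyCounts(sim$shortTerm, seed = 1)
rel    <- tssNormalize(counts)
m      <- countValues(rel)
stage  <- sampleGroups(rel)

## does the community shift between early and late ripening?
keep  <- stage %in% c("W1", "W2", "W4", "W5")
phase <- ifelse(stage[keep] %in% c("W1", "W2"), "early", "late")
d     <- brayCurtisMatrix(m[, keep])
permanovaTest(d, phase, nPerm = 999, seed = 1)

## how many abundance archetypes are there?
sm <- t(rowsum(t(m), stage) / as.vector(table(stage)))
wssClusterCount(logRelative(sm), kMax = 10)$k   # 5, as planted

## which vOTUs move, and by how much?
da <- differentialAbundance(
  sim$shortTerm[, colnames(countValues(sim$shortTerm))[keep]],
  groups = phase)
head(da)

## persistence across production years
venn <- vennPartition(presenceAbsence(sim$longTerm))
venn$pct_all_three
```

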
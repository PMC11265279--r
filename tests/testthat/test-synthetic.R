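test_that("guildSpec validates the dynamic and fractions", {
  expect_error(guildSpec("x", 3, "exploding"))
  expect_error(guildSpec("x", 3, "stable", baseFraction = 1.5))
  expect_error(guildSpec("x", 0, "stable"))
  g <- guildSpec("x", 3, "transient", baseFraction = 0.1, rate = 3)
  expect_equal(g$n_votus, 3L)
  expect_equal(g$dynamic, "transient")
})

test_that("the default design has five near-equal profile archetypes", {
  g <- defaultGuilds()
  expect_equal(sum(g$n_votus), 113)
  expect_setequal(
    unique(g$dynamic),
    c("declining", "rising", "transient", "stable", "sporadic"))
  ## archetype sizes are near-equal (a requirement of the elbow geometry)
  sizes <- tapply(g$n_votus, g$dynamic, sum)
  expect_true(all(sizes >= 21 & sizes <= 24))
  ## the three rising guilds share one trajectory
  r <- g[g$dynamic == "rising", ]
  expect_equal(length(unique(r$base_fraction)), 1)
  expect_equal(length(unique(r$rate)), 1)
  expect_setequal(r$host_genus,
                  c("Glutamicibacter", "Brevibacterium", "Psychrobacter"))
  expect_true(g$temperate[g$name == "declining_p335"])
})

test_that("generateDynamics plants exact log2 fold changes", {
  dyn <- generateDynamics(communityDesign())
  expect_equal(unname(rowSums(dyn)), rep(1, 5), tolerance = 1e-12)
  l2 <- attr(dyn, "log2fc")
  g <- defaultGuilds()
  guild_of <- rep(g$name, times = g$n_votus)
  names(guild_of) <- colnames(dyn)
  expect_equal(unname(l2[guild_of == "declining_p335"]),
               rep(-4, 22), tolerance = 1e-10)
  rising <- guild_of %in% g$name[g$dynamic == "rising"]
  expect_equal(unname(l2[rising]), rep(4, 24), tolerance = 1e-10)
  ## the transient bloom is symmetric: planted log2 fold change exactly 0
  expect_equal(unname(l2[guild_of == "transient_corynebacterium"]),
               rep(0, 24), tolerance = 1e-12)
  expect_equal(unname(l2[guild_of == "stable_987"]),
               rep(0, 22), tolerance = 1e-12)
})

test_that("the transient trajectory is a geometric tent peaking mid-way", {
  g <- guildSpec("t", 2, "transient", baseFraction = 0.02, rate = 3)
  des <- communityDesign(guilds = rbind(
    g, guildSpec("bg", 2, "sporadic")))
  dyn <- generateDynamics(des)
  traj <- dyn[, 1] * 2 / 0.02      # guild trajectory over its base
  expect_equal(unname(traj), 3^c(0, 1, 2, 1, 0), tolerance = 1e-12)
  expect_equal(which.max(dyn[, 1]), c(W3 = 3))
})

test_that("the sporadic guild absorbs the per-stage remainder", {
  dyn <- generateDynamics(communityDesign())
  raw <- attr(dyn, "raw")
  expect_equal(unname(rowSums(raw)), rep(1, 5), tolerance = 1e-12)
  ## remainder stays a meaningful share at every stage
  expect_true(all(raw[, "sporadic_background"] > 0.05))
  ## over-committed designs are rejected
  bad <- communityDesign(guilds = rbind(
    guildSpec("a", 2, "stable", baseFraction = 0.5),
    guildSpec("b", 2, "transient", baseFraction = 0.5, rate = 3),
    guildSpec("bg", 2, "sporadic")))
  expect_error(generateDynamics(bad), "exceed 1")
})

test_that("sampleCounts draws reproducible multinomial libraries", {
  des <- communityDesign()
  dyn <- generateDynamics(des)
  vc1 <- sampleCounts(dyn, des, seed = 5)
  vc2 <- sampleCounts(dyn, des, seed = 5)
  expect_identical(countValues(vc1), countValues(vc2))
  m <- countValues(vc1)
  expect_equal(dim(m), c(113, 15))
  expect_true(all(m == floor(m) & m >= 0))
  expect_equal(normState(vc1), "raw")
  ## library sizes concentrate around 10^5
  expect_true(all(colSums(m) > 10^4.7 & colSums(m) < 10^5.3))
  md <- sampleData(vc1)
  expect_setequal(unique(md$group), paste0("W", 1:5))
  expect_equal(sum(md$group == "W3"), 3)
  expect_error(communityDesign(theta = 0), "theta")
})

test_that("empirical stage means track the designed dynamics", {
  des <- communityDesign()
  dyn <- generateDynamics(des)
  vc <- sampleCounts(dyn, des, seed = 8)
  rel <- sweep(countValues(vc), 2, colSums(countValues(vc)), "/")
  grp <- sampleGroups(vc)
  sm <- t(rowsum(t(rel), grp) / 3)
  ## designed vs observed shares agree on the log scale for the planted
  ## (non-sporadic) vOTUs; sm is features x stages
  err <- abs(log10(sm[1:92, paste0("W", 1:5)] + 1e-6) -
               log10(t(dyn)[1:92, ] + 1e-6))
  expect_lt(stats::median(err), 0.15)
})

test_that("the bacteriome follows the designed growth exactly at sd 0", {
  des <- communityDesign(bacteriomeNoiseSd = 0)
  b <- generateBacteriome(des, seed = 3)
  absm <- b$genusAbsolute
  expect_equal(unname(absm["Lactococcus", ]),
               rep(1e8, 15), tolerance = 1e-12)
  aerobes <- setdiff(rownames(absm), "Lactococcus")
  expect_setequal(aerobes,
                  c("Glutamicibacter", "Brevibacterium", "Psychrobacter"))
  totals <- colSums(absm[aerobes, ])
  stage <- as.integer(sub("W(\\d)[A-Z]", "\\1", colnames(absm)))
  expect_equal(unname(log10(totals)), 8 + 2 * (stage - 1) / 4,
               tolerance = 1e-12)
  expect_equal(unname(colSums(countValues(b$genusRelative))),
               rep(1, 15), tolerance = 1e-12)
  expect_equal(b$plateCounts$lab_log10, rep(8, 15), tolerance = 1e-12)
})

test_that("tool reports qualify viral and only viral contigs", {
  des <- tinyDesign()
  des$iphopErrorRate <- 0
  sim <- simulateDefault(seed = 21, design = des)
  rep <- sim$reports
  truth <- sim$truth
  qualifies <- function(i) {
    q <- c("complete", "high", "medium")
    (!is.na(rep$vibrant_quality[i]) && rep$vibrant_quality[i] %in% q) ||
      (!is.na(rep$checkv_quality[i]) && rep$checkv_quality[i] %in% q) ||
      (!is.na(rep$virsorter2_label[i]) && rep$virsorter2_label[i] == "full")
  }
  ok <- vapply(seq_len(nrow(rep)), qualifies, logical(1))
  expect_identical(ok, truth$viral)
  ## temperate truth always reaches the lifestyle column
  expect_true(all(rep$vibrant_lifestyle[truth$temperate] == "temperate"))
  ## with error rate 0, host predictions copy the truth
  has_host <- !is.na(truth$host_genus)
  expect_identical(rep$iphop_genus[has_host], truth$host_genus[has_host])
})

test_that("simulateCommunity is a pure function of (design, seed)", {
  a <- simulateDefault(seed = 9, design = tinyDesign())
  b <- simulateDefault(seed = 9, design = tinyDesign())
  expect_identical(countValues(a$shortTerm), countValues(b$shortTerm))
  expect_identical(countValues(a$longTerm), countValues(b$longTerm))
  expect_identical(as.character(a$contigs), as.character(b$contigs))
  c <- simulateDefault(seed = 10, design = tinyDesign())
  expect_false(identical(countValues(a$shortTerm),
                         countValues(c$shortTerm)))
  ## the recorded guild map covers every planted vOTU
  expect_setequal(names(a$guildOfVotu),
                  a$truth$contig_id[a$truth$role == "genome"])
  ## long-term metadata: three years, three replicates
  md <- sampleData(a$longTerm)
  expect_setequal(unique(md$group), c("2017", "2019", "2022"))
})
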
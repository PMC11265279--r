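test_that("sizeFactors match the DESeq2 median-of-ratios oracle", {
  set.seed(61)
  m <- matrix(rpois(20 * 8, 200), nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:8)))
  ## scale samples to create real depth differences
  m <- round(sweep(m, 2, c(1, 2, 0.5, 1.5, 3, 1, 0.8, 1.2), "*"))
  sf <- sizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("sizeFactors needs an everywhere-positive feature", {
  m <- matrix(c(0, 5, 5, 0), 2)
  expect_error(sizeFactors(m), "positive counts")
})

test_that("bhAdjust equals p.adjust(method = 'BH')", {
  set.seed(62)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bhAdjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-15)
  }
  expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)))
})

test_that("estimateDispersion recovers a known dispersion", {
  set.seed(63)
  alpha <- 0.1
  mu <- 500
  m <- matrix(rnbinom(10 * 400, mu = mu, size = 1 / alpha), nrow = 10,
              dimnames = list(paste0("f", 1:10), NULL))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  disp <- estimateDispersion(m, factors = rep(1, ncol(m)))
  expect_true(all(disp > 0.05 & disp < 0.2))
  ## the floor is enforced
  m2 <- matrix(rep(c(100L, 101L), 50), nrow = 2)
  rownames(m2) <- c("a", "b"); colnames(m2) <- paste0("s", 1:50)
  d2 <- estimateDispersion(m2, factors = rep(1, 50))
  expect_true(all(d2 >= daConfig()$dispersionFloor))
})

test_that("nbWaldTest recovers a planted fold change with correct sign", {
  set.seed(64)
  n <- 6
  mk <- function(mu) rnbinom(n, mu = mu, size = 1 / 0.05)
  m <- rbind(
    up = c(mk(1000), mk(16000)),
    down = c(mk(16000), mk(1000)),
    flat = c(mk(4000), mk(4000)))
  colnames(m) <- paste0("s", 1:(2 * n))
  groups <- rep(c("early", "late"), each = n)
  res <- nbWaldTest(m, groups, factors = rep(1, 2 * n))
  expect_equal(res$log2fc[res$feature_id == "up"], 4, tolerance = 0.5)
  expect_equal(res$log2fc[res$feature_id == "down"], -4, tolerance = 0.5)
  expect_lt(abs(res$log2fc[res$feature_id == "flat"]), 0.5)
  expect_lt(res$p[res$feature_id == "up"], 1e-6)
  expect_gt(res$p[res$feature_id == "flat"], 0.01)
  ## flipping the reference flips the sign exactly
  res2 <- nbWaldTest(m, groups, factors = rep(1, 2 * n), reference = "late")
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-6)
})

test_that("the NB Wald test is calibrated under the null", {
  set.seed(65)
  nFeat <- 500
  n <- 6
  m <- matrix(rnbinom(nFeat * 2 * n, mu = 800, size = 1 / 0.08),
              nrow = nFeat,
              dimnames = list(paste0("f", seq_len(nFeat)),
                              paste0("s", seq_len(2 * n))))
  groups <- rep(c("a", "b"), each = n)
  res <- nbWaldTest(m, groups, factors = rep(1, 2 * n))
  rate <- mean(res$p < 0.05)
  ## binomial 99% CI around 0.05 with 500 draws: +/- 2.576*sqrt(.05*.95/500)
  expect_gt(rate, 0.05 - 2.576 * sqrt(0.05 * 0.95 / nFeat))
  expect_lt(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / nFeat))
})

test_that("callSignificant applies all three strict cutoffs", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    base_mean = 2000, mean_raw = c(2000, 2000, 2000, 1500),
    log2fc = c(3.5, 3.0, 3.5, 3.5),
    wald_stat = 10,
    p = c(1e-6, 1e-6, 1e-6, 1e-6),
    padj = c(1e-5, 1e-5, 0.01, 1e-5),
    converged = TRUE, stringsAsFactors = FALSE)
  out <- callSignificant(res)
  ## b fails |lfc| > 3 (equality), c fails padj < 0.01 (equality),
  ## d fails mean_raw > 1500 (equality)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  ## the 0.05 variant admits c
  out2 <- callSignificant(res, daConfig(padjCutoff = 0.05))
  expect_true(out2$significant[3])
})

test_that("differentialAbundance recovers the planted guilds end to end", {
  des <- communityDesign(guilds = daBenchmarkGuilds())
  sim <- simulateDefault(seed = 66, design = des)
  grp <- sampleGroups(sim$shortTerm)
  keep <- grp %in% c("W1", "W2", "W4", "W5")
  phase <- ifelse(grp[keep] %in% c("W1", "W2"), "early", "late")
  da <- differentialAbundance(
    sim$shortTerm[, colnames(countValues(sim$shortTerm))[keep]],
    groups = phase)
  guild_of <- sim$guildOfVotu
  g <- des$guilds
  dec <- names(guild_of)[guild_of %in% g$name[g$dynamic == "declining"]]
  ris <- names(guild_of)[guild_of %in% g$name[g$dynamic == "rising"]]
  planted <- da[match(c(dec, ris), da$feature_id), ]
  ## full power at the default thresholds
  expect_true(all(planted$significant))
  ## correct signs and calibrated magnitude
  expect_true(all(da$log2fc[match(dec, da$feature_id)] < 0))
  expect_true(all(da$log2fc[match(ris, da$feature_id)] > 0))
  expect_gte(median(da$log2fc[match(ris, da$feature_id)]), 3.5)
  expect_lte(median(da$log2fc[match(ris, da$feature_id)]), 4.5)
  ## nothing outside the planted movers is called
  expect_length(setdiff(da$feature_id[da$significant], c(dec, ris)), 0)
  ## results are sorted by p-value
  expect_false(is.unsorted(da$p))
})

test_that("differentialAbundance refuses non-raw input", {
  vc <- smallCounts(nf = 5, nrep = 2, seed = 67)
  rel <- tssNormalize(quietRarefy(vc))
  expect_error(differentialAbundance(rel, groups = rep(c("a", "b"), 5)),
               "state")
})
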
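test_that("identical sequences score exactly 1", {
  set.seed(11)
  s <- randomDNA(1500)
  hits <- alignPair(s, s)
  expect_equal(pairScore(hits, 1500, 1500), 1)
})

test_that("score equals identity for full-length substituted copies", {
  ## substitution-only mutation keeps coverage 1, so score ~ 1 - rate
  set.seed(12)
  for (rate in c(0.03, 0.10)) {
    a <- randomDNA(2000)
    b <- mutateSequence(a, rate)
    hits <- alignPair(a, b)
    sc <- pairScore(hits, nchar(a), nchar(b))
    obs_ident <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expect_gt(sc, obs_ident - 0.02)
    expect_lte(sc, 1)
  }
})

test_that("containment of a fragment scores high via shorter-side coverage", {
  set.seed(13)
  g <- randomDNA(6000)
  frag <- substr(g, 2001, 3500)
  hits <- alignPair(frag, g)
  sc <- pairScore(hits, nchar(frag), nchar(g))
  expect_gt(sc, 0.98)
})

test_that("reverse-complement hits are found and mapped back", {
  set.seed(14)
  a <- randomDNA(1200)
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  hits <- alignPair(a, b)
  expect_true(any(hits$strand == "-"))
  expect_equal(pairScore(hits, 1200, 1200), 1)
  ## disabling strand search loses the hit
  hits_fwd <- alignPair(a, b, alignParams(bothStrands = FALSE))
  expect_equal(pairScore(hits_fwd, 1200, 1200), 0)
})

test_that("unrelated sequences score 0", {
  set.seed(15)
  a <- randomDNA(3000)
  b <- randomDNA(3000)
  hits <- alignPair(a, b)
  expect_equal(pairScore(hits, 3000, 3000), 0)
})

test_that("matches agree with the Biostrings dynamic-programming oracle", {
  ## ungapped global-ish alignment of a mutated copy: the optimal
  ## substitution-only alignment is the direct base-to-base comparison,
  ## which pairwiseAlignment recovers with heavy gap penalties
  set.seed(16)
  a <- randomDNA(1200)
  b <- mutateSequence(a, 0.05)
  hits <- alignPair(a, b)
  expect_equal(nrow(hits), 1)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 100, gapExtension = 100)
  expect_equal(hits$matches, Biostrings::nmatch(pa))
})

test_that("pairScore merges overlapping hits with the union rule", {
  hits <- data.frame(
    q_start = c(0, 50), q_end = c(100, 150),
    t_start = c(0, 50), t_end = c(100, 150),
    matches = c(95, 95), aligned_length = c(100, 100))
  ## union on the shorter (equal) side = 150 bases of 200
  sc <- pairScore(hits, 200, 400)
  expect_equal(sc, (190 / 200) * (150 / 200))
})

test_that("pairScore of an empty hit set is 0 and coverage is capped", {
  expect_equal(pairScore(NULL, 10, 10), 0)
  expect_equal(pairScore(data.frame()[0, ], 10, 10), 0)
  hits <- data.frame(q_start = 0, q_end = 120, t_start = 0, t_end = 120,
                     matches = 120, aligned_length = 120)
  expect_lte(pairScore(hits, 100, 200), 1)
})

test_that("selfAlignmentFraction detects internal duplication", {
  set.seed(17)
  core <- randomDNA(1500)
  plain <- randomDNA(3000)
  chimera <- paste0(core, randomDNA(500), core)
  expect_equal(selfAlignmentFraction(plain), 1)
  expect_gt(selfAlignmentFraction(chimera), 1.10)
  expect_equal(selfAlignmentFraction(plain, includeTrivial = FALSE), 0)
})

test_that("allVsAll matches per-pair scores, with and without the screen", {
  set.seed(18)
  g1 <- randomDNA(2500)
  g2 <- mutateSequence(g1, 0.04)
  g3 <- randomDNA(2400)
  contigs <- c(a = g1, b = g2, c = g3)
  sc_screen <- allVsAll(contigs)
  sc_full <- allVsAll(contigs, screen = FALSE)
  expect_equal(sc_screen, sc_full)
  expect_equal(nrow(sc_screen), 1)
  expect_setequal(c(sc_screen$id1, sc_screen$id2), c("a", "b"))
  direct <- pairScore(alignPair(g1, g2), 2500, 2500)
  expect_equal(sc_screen$score, direct)
})

test_that("scoresFromPSL aggregates split and flipped hits", {
  psl <- data.frame(
    query_id = c("x", "y"), target_id = c("y", "x"),
    q_start = c(0, 300), q_end = c(200, 500),
    t_start = c(0, 300), t_end = c(200, 500),
    q_size = c(1000, 1000), t_size = c(1000, 1000),
    matches = c(190, 180), aligned_length = c(200, 200),
    identity = NA, coverage = NA, score = NA, strand = "+",
    stringsAsFactors = FALSE)
  got <- scoresFromPSL(psl)
  expect_equal(nrow(got), 1)
  ## union 400 of 1000; identity 370/400
  expect_equal(got$score, (370 / 400) * (400 / 1000))
})

test_that("alignment is deterministic", {
  set.seed(19)
  a <- randomDNA(2000)
  b <- mutateSequence(a, 0.08)
  h1 <- alignPair(a, b)
  h2 <- alignPair(a, b)
  expect_identical(h1, h2)
})
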
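# normalized ranks, RR selectivity, concordance, paired tests, hit filtering

rankFromScores <- function(kinase, scores, conformer = "c1") {
  st <- ScreenTable(data.frame(
    ligand_id = names(scores), conformer_id = conformer, kinase_id = kinase,
    total = unname(scores), stringsAsFactors = FALSE))
  normalizeRanks(st, kinase = kinase)
}

test_that("normalized ranks follow midrank arithmetic", {
  r <- rankValues(rankFromScores("K", c(L1 = -4, L2 = -3, L3 = -2, L4 = -1)))
  expect_equal(unname(r[c("L1", "L2", "L3", "L4")]), c(0.25, 0.5, 0.75, 1.0))
  # two tied best among 4: both get (1+2)/2 / 4 = 0.375
  r2 <- rankValues(rankFromScores("K", c(L1 = -4, L2 = -4, L3 = -2, L4 = -1)))
  expect_equal(unname(r2[c("L1", "L2")]), c(0.375, 0.375))
  # single ligand
  r3 <- rankValues(rankFromScores("K", c(L1 = 2)))
  expect_equal(unname(r3), 1.0)
})

test_that("the consensus across conformers averages per-conformer ranks", {
  d <- rbind(
    data.frame(ligand_id = c("L1", "L2"), conformer_id = "c1",
               kinase_id = "K", total = c(-2, -1)),
    data.frame(ligand_id = c("L1", "L2"), conformer_id = "c2",
               kinase_id = "K", total = c(-1, -2)))
  st <- ScreenTable(d)
  rMean <- rankValues(normalizeRanks(st, consensus = "mean"))
  expect_equal(unname(rMean[c("L1", "L2")]), c(0.75, 0.75))
  rBest <- rankValues(normalizeRanks(st, consensus = "best"))
  expect_equal(unname(rBest[c("L1", "L2")]), c(0.5, 0.5))
  expect_error(normalizeRanks(st, conformers = character()), "empty conformer")
})

test_that("RR is the exact difference of normalized ranks, antisymmetric", {
  expect_equal(relativeRank(0.5, 0.5), 0)
  expect_equal(relativeRank(0.1, 0.9), -0.8)
  expect_error(relativeRank(0, 0.5), "\\(0, 1]")
  set.seed(301)
  ra <- runif(20, 0.01, 1); rb <- runif(20, 0.01, 1)
  expect_equal(relativeRank(ra, rb), -relativeRank(rb, ra))
  # linearity: sum of rr equals difference of rank sums
  expect_equal(sum(relativeRank(ra, rb)), sum(ra) - sum(rb))
})

test_that("concordance attains its exact extremes", {
  s <- setNames(-(10:1), sprintf("L%02d", 1:10))
  rA <- rankFromScores("A", s)
  rB <- rankFromScores("B", s)
  cc <- concordance(rA, rB)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(cc$kendall_tau, 1)
  expect_true(all(abs(rankValues(rA) - rankValues(rB)) == 0))
  rBrev <- rankFromScores("B", -s)
  ccRev <- concordance(rA, rBrev)
  expect_equal(ccRev$spearman_rho, -1)
  expect_equal(ccRev$kendall_tau, -1)
  expect_error(concordance(rankFromScores("A", s[1:2]),
                           rankFromScores("B", s[1:2])), "at least 3")
})

test_that("Kendall tau matches brute-force pair counting (tau-b, with ties)", {
  set.seed(302)
  for (rep in 1:20) {
    sA <- setNames(sample(1:4, 6, replace = TRUE), sprintf("L%d", 1:6))
    sB <- setNames(sample(1:4, 6, replace = TRUE), sprintf("L%d", 1:6))
    rA <- rankFromScores("A", sA); rB <- rankFromScores("B", sB)
    got <- concordance(rA, rB)$kendall_tau
    want <- bruteKendallTauB(rankValues(rA)[sprintf("L%d", 1:6)],
                             rankValues(rB)[sprintf("L%d", 1:6)])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("paired component test reports the Bonferroni-adjusted level", {
  set.seed(303)
  a <- rnorm(30); b <- a + rnorm(30, 0.5)
  res <- pairedComponentTest(a, b, m = 2)
  expect_equal(res$adjusted_alpha, 0.025)
  expect_equal(res$significant, res$p < 0.025)
})

test_that("the exact Wilcoxon null is used for small samples", {
  # n = 5, all differences positive: one-sided exact p = 1/32, two-sided 1/16
  a <- c(1, 2, 3, 4, 5); b <- a - c(0.5, 0.7, 0.9, 1.1, 1.3)
  res <- pairedComponentTest(a, b, m = 2, alternative = "greater")
  expect_equal(res$p, 1 / 32)
  res2 <- pairedComponentTest(a, b, m = 2)
  expect_equal(res2$p, 1 / 16)
  expect_error(pairedComponentTest(a, a), "degenerate pairs")
  expect_error(pairedComponentTest(1:3, c(2, 3, 4)), "at least 5")
})

test_that("symmetric paired differences sit at the null", {
  x <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  res <- pairedComponentTest(x, rep(0, 6), m = 1)
  expect_gt(res$p, 0.9)
  expect_false(res$significant)
})

libraryFixture <- function(n = 100, seed = 304) {
  set.seed(seed)
  ids <- sprintf("L%04d", 1:n)
  sA <- setNames(rnorm(n), ids)
  sB <- setNames(sA + rnorm(n, sd = 0.5), ids)
  list(rA = rankFromScores("A", sA), rB = rankFromScores("B", sB))
}

test_that("hit prioritization retains ceiling(fraction x N) before RR filtering", {
  f <- libraryFixture()
  hits <- prioritizeHits(f$rA, f$rB, topFraction = 0.05,
                         separationMargin = 0)
  expect_equal(hits@provenance$top_retained, 5)
  expect_equal(hits@provenance$library_size, 100)
  # every retained hit satisfies the recorded filters
  h <- hitTable(hits)
  expect_true(all(h$rr <= hits@provenance$rr_cutoff))
  expect_true(all(h$r_a <= sort(rankValues(f$rA))[5] + 1e-12))
})

test_that("kinase-B-leaning and marginal ligands are dropped", {
  ids <- sprintf("L%02d", 1:20)
  sA <- setNames(seq_len(20), ids)
  sB <- setNames(seq_len(20), ids)
  sB["L01"] <- 19.5   # best in A (rr strongly negative)
  sB["L02"] <- 1.0    # rr positive for second-best in A
  rA <- rankFromScores("A", sA); rB <- rankFromScores("B", sB)
  hits <- hitTable(prioritizeHits(rA, rB, topFraction = 0.10,
                                  rrCutoff = 0, separationMargin = 0.05))
  expect_true("L01" %in% hits$ligand_id)
  expect_false("L02" %in% hits$ligand_id)   # rr > 0
})

test_that("hit lists are invariant to ligand input order", {
  f <- libraryFixture(60)
  ids <- names(rankValues(f$rA))
  perm <- sample(ids)
  rAp <- new("RankTable", kinaseId = "A", conformers = "c1",
             consensus = "mean", ranks = rankValues(f$rA)[perm])
  rBp <- new("RankTable", kinaseId = "B", conformers = "c1",
             consensus = "mean", ranks = rankValues(f$rB)[perm])
  h1 <- hitTable(prioritizeHits(f$rA, f$rB))
  h2 <- hitTable(prioritizeHits(rAp, rBp))
  expect_identical(h1, h2)
})

test_that("mismatched libraries are rejected", {
  f <- libraryFixture(20)
  short <- new("RankTable", kinaseId = "B", conformers = "c1",
               consensus = "mean", ranks = rankValues(f$rB)[1:10])
  expect_error(prioritizeHits(f$rA, short), "library mismatch")
})

test_that("planted kinase-A bias enriches tagged ligands among the hits", {
  gen <- genScreenTable(screenSpec(nActives = 150, nInactives = 150,
                                   delta = 1, sigma = 1, nConformers = 2,
                                   biasedFraction = 0.2, beta = 1, seed = 7))
  rA <- normalizeRanks(gen$kinaseA)
  rB <- normalizeRanks(gen$kinaseB)
  hits <- hitTable(prioritizeHits(rA, rB, topFraction = 0.2,
                                  separationMargin = 0.02))
  tagged <- gen$truth$ligand_id[gen$truth$tagged]
  inHit <- gen$truth$ligand_id %in% hits$ligand_id
  tab <- table(tagged = gen$truth$ligand_id %in% tagged, hit = inHit)
  expect_lt(fisher.test(tab)$p.value, 0.01)
})

test_that("zero planted bias leaves mean RR of actives near zero", {
  set.seed(305)
  means <- replicate(60, {
    seed <- sample.int(1e6, 1)
    gen <- genScreenTable(screenSpec(nActives = 40, nInactives = 40,
                                     delta = 1, sigma = 1, nConformers = 1,
                                     biasedFraction = 0, beta = 0,
                                     seed = seed))
    tab <- selectivityTable(normalizeRanks(gen$kinaseA),
                            normalizeRanks(gen$kinaseB))
    act <- gen$truth$ligand_id[gen$truth$label == "active"]
    mean(tab$rr[tab$ligand_id %in% act])
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-9)
})

test_that("drug-likeness rules evaluate their published bounds", {
  desc <- data.frame(
    ligand_id = c("ok", "fail2", "rotb"),
    MW = c(350, 510, 400), logP = c(2, 5.5, 3), HBD = c(2, 2, 2),
    HBA = c(5, 5, 5), RotB = c(4, 5, 11), TPSA = c(80, 80, 80),
    MR = c(90, 90, 90), heavy_atoms = c(25, 30, 28))
  flags <- drugLikenessFlags(desc)
  expect_equal(flags$lipinski_violations, c(0, 2, 0))
  expect_equal(flags$lipinski, c(TRUE, FALSE, TRUE))
  expect_equal(flags$veber, c(TRUE, TRUE, FALSE))
  expect_equal(flags$ghose, c(TRUE, FALSE, TRUE))
  # missing descriptor -> indeterminate, not failure
  flags2 <- drugLikenessFlags(data.frame(ligand_id = "x", MW = 300,
                                         logP = 2, HBD = 1, HBA = 2))
  expect_true(is.na(flags2$veber))
  expect_true(flags2$lipinski)
})

test_that("Spearman/Kendall recover the rank correlation of a planted copula", {
  set.seed(306)
  n <- 500
  rho <- 0.8
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  ids <- sprintf("L%04d", 1:n)
  rA <- rankFromScores("A", setNames(z1, ids))
  rB <- rankFromScores("B", setNames(z2, ids))
  cc <- concordance(rA, rB)
  # population Spearman for a bivariate normal copula
  target <- 6 / pi * asin(rho / 2)
  expect_lt(abs(cc$spearman_rho - target), 3 * sqrt(1 / (n - 3)))
  expect_lt(cc$spearman_p, 0.001)
})
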
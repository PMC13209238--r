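# activity classification and screening-performance metrics

test_that("activity classification follows the pChEMBL / nM thresholds", {
  expect_equal(classifyActivity(7.5), "active")
  expect_equal(classifyActivity(NA, 50), "active")
  expect_equal(classifyActivity(6.0), "unknown")
  expect_equal(classifyActivity(5.0), "inactive")
  expect_equal(classifyActivity(5.5), "inactive")   # boundary: <= 5.5
  expect_equal(classifyActivity(NA, 100), "active") # boundary: <= 100 nM
  expect_equal(classifyActivity(NA, 1e4), "inactive")
  expect_equal(classifyActivity(NA, 5000), "unknown")
})

test_that("pChEMBL wins over a conflicting standard value, with a warning", {
  expect_warning(lab <- classifyActivity(7.5, 2e4), "conflicting")
  expect_equal(lab, "active")
  expect_error(classifyActivity(NA, NA), "at least one")
})

test_that("AUC attains its trivial extremes", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c("active", "active", "inactive",
                                       "inactive")), 1.0)
  expect_equal(rocAuc(rep(5, 6), rep(c("active", "inactive"), 3)), 0.5)
  expect_error(rocAuc(1:3, rep("active", 3)), "at least one")
})

test_that("AUC equals exhaustive pair counting with midrank ties", {
  # 5-ligand hand ranking: scores with a tie across classes
  scores <- c(1, 2, 2, 3, 4)
  labels <- c("active", "inactive", "active", "active", "inactive")
  act <- labels == "active"
  expect_equal(rocAuc(scores, labels), pairCountAuc(scores, act))
  set.seed(201)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    scores <- sample(1:15, n, replace = TRUE)   # many ties
    act <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(act) || all(act)) next
    expect_identical(rocAuc(scores, act), pairCountAuc(scores, act))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(202)
  scores <- rnorm(80)
  act <- rep(c(TRUE, FALSE), 40)
  scores[act] <- scores[act] - 1
  ref <- as.numeric(pROC::auc(pROC::roc(act, scores, direction = ">",
                                        quiet = TRUE)))
  expect_equal(rocAuc(scores, act), ref, tolerance = 1e-12)
})

test_that("eROCE reaches 1 on perfect rankings and decays exponentially", {
  expect_equal(eroce(c(1, 2, 3, 4), c("active", "active", "inactive",
                                      "inactive")), 1.0)
  # one active ranked after all four inactives: FPR = 1 -> exp(-alpha)
  expect_equal(eroce(c(1, 2, 3, 4, 5),
                     c(rep("inactive", 4), "active"), alpha = 20),
               exp(-20))
  expect_error(eroce(1:4, c("active", "active", "inactive", "inactive"),
                     alpha = 0), "positive")
})

test_that("eROCE never increases when an active moves down the ranking", {
  set.seed(203)
  for (rep in 1:25) {
    n <- 12
    act <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(act) || all(act)) next
    scores <- seq_len(n)
    base <- eroce(scores, act)
    # swap one adjacent active/inactive pair (active moves down)
    i <- which(act[-n] & !act[-1])
    if (!length(i)) next
    i <- i[1]
    act2 <- act; act2[c(i, i + 1)] <- act2[c(i + 1, i)]
    expect_lte(eroce(scores, act2), base + 1e-12)
  }
})

test_that("enrichment factors follow the exact count arithmetic", {
  # 10 actives among 100; top-10% holds 5 actives -> EF = 5
  scores <- seq_len(100)
  act <- rep(FALSE, 100)
  act[c(1, 3, 5, 7, 9, 60, 70, 80, 90, 100)] <- TRUE
  expect_equal(enrichmentFactor(scores, act, 0.10), 5.0)
  # all actives in the top set: EF = 1/f when top size = total actives
  act2 <- c(rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(enrichmentFactor(scores, act2, 0.10), 10)
  expect_error(enrichmentFactor(scores, act, 1.5), "fraction")
})

test_that("EF is about 1 on random rankings (null expectation)", {
  set.seed(204)
  n <- 100
  act <- c(rep(TRUE, 20), rep(FALSE, 80))
  efs <- replicate(300, enrichmentFactor(sample(n), act, 0.10))
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 1e-9)
})

test_that("EF times the top-set prevalence recovers the integer hit count", {
  set.seed(205)
  for (rep in 1:30) {
    n <- sample(20:120, 1)
    act <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(act) || all(act)) next
    f <- sample(c(0.05, 0.1, 0.25), 1)
    ef <- enrichmentFactor(seq_len(n), act, f)
    size <- ceiling(f * n)
    hits <- ef * size * sum(act) / n
    expect_equal(hits, round(hits), tolerance = 1e-9)
  }
})

test_that("cutoff metrics match a hand tally on a 20-ligand fixture", {
  scores <- seq_len(20)
  act <- rep(FALSE, 20)
  act[c(1, 2, 5, 11, 15)] <- TRUE       # 5 actives, 2 in the top-10% (n=2)
  cm <- cutoffMetrics(scores, act, fractions = 0.10)
  expect_equal(cm$tp, 2)
  expect_equal(cm$fp, 0)
  expect_equal(cm$fn, 3)
  expect_equal(cm$tn, 15)
  expect_equal(cm$precision, 1)
  expect_equal(cm$recall, 2 / 5)
  expect_equal(cm$f1, 2 * 1 * 0.4 / 1.4)
})

test_that("degenerate cutoffs yield the zero-F1 convention", {
  scores <- seq_len(10)
  act <- c(rep(FALSE, 5), rep(TRUE, 5))   # all actives at the bottom
  cm <- cutoffMetrics(scores, act, fractions = 0.2)
  expect_equal(cm$tp, 0)
  expect_equal(cm$precision, 0)
  expect_equal(cm$recall, 0)
  expect_equal(cm$f1, 0)
  # perfect ranking at the fraction covering all actives
  cm2 <- cutoffMetrics(scores, rev(act), fractions = 0.5)
  expect_equal(cm2[, c("precision", "recall", "f1")],
               data.frame(precision = 1, recall = 1, f1 = 1))
})

makeReport <- function(conformer, scores, act, ...) {
  st <- ScreenTable(data.frame(ligand_id = sprintf("L%03d", seq_along(scores)),
                               conformer_id = conformer, kinase_id = "K",
                               total = scores,
                               label = ifelse(act, "active", "inactive")))
  conformerMetrics(st, conformer, ...)
}

test_that("conformer reports satisfy the confusion-count invariants", {
  set.seed(206)
  scores <- rnorm(50)
  act <- rep(c(TRUE, FALSE), 25)
  rep1 <- makeReport("c1", scores, act)
  expect_true(all(rep1@cutoffs$tp + rep1@cutoffs$fn == rep1@nActives))
  expect_true(all(rep1@cutoffs$tp + rep1@cutoffs$fp ==
                    ceiling(rep1@cutoffs$fraction * rep1@nLigands)))
  expect_true(all(rep1@ef <= 1 / as.numeric(names(rep1@ef)) + 1e-9))
})

test_that("aggregation pools confusion counts and preserves ratios", {
  set.seed(207)
  scores <- rnorm(40)
  act <- rep(c(TRUE, FALSE), 20)
  r1 <- makeReport("c1", scores, act)
  # single report: identical to its own cutoff table
  agg1 <- aggregateConformers(list(r1))
  expect_equal(agg1$summary[, c("precision", "recall", "f1")],
               r1@cutoffs[, c("precision", "recall", "f1")])
  # two identical reports: same ratios, doubled counts
  agg2 <- aggregateConformers(list(r1, r1))
  expect_equal(agg2$summary$tp, 2 * r1@cutoffs$tp)
  expect_equal(agg2$summary$precision, r1@cutoffs$precision)
  # two different reports: pooled hand tally
  scores2 <- rnorm(40)
  r2 <- makeReport("c2", scores2, act)
  agg <- aggregateConformers(list(r1, r2))
  expect_equal(agg$summary$tp, r1@cutoffs$tp + r2@cutoffs$tp)
  expect_equal(agg$summary$precision,
               (r1@cutoffs$tp + r2@cutoffs$tp) /
                 (r1@cutoffs$tp + r2@cutoffs$fp + r2@cutoffs$tp +
                    r1@cutoffs$fp))
  # mixed grids are rejected
  r3 <- makeReport("c3", scores2, act, cutoffFractions = c(0.05, 0.5))
  expect_error(aggregateConformers(list(r1, r3)), "different cutoff grids")
})

test_that("conformer prioritization applies the AUC floor and median rule", {
  set.seed(208)
  n <- 60
  act <- rep(c(TRUE, FALSE), n / 2)
  # dominant conformer: strong separation; weak ones: barely random
  mk <- function(cid, delta) {
    makeReport(cid, rnorm(n) - delta * act, act)
  }
  reports <- list(mk("good1", 2.5), mk("good2", 2.4), mk("weak1", 0.1),
                  mk("weak2", 0.0), mk("weak3", 0.05))
  sel <- selectConformers(reports, aucMin = 0.70)
  expect_setequal(sel, c("good1", "good2"))
  # an AUC below the floor is excluded regardless of enrichment
  aucs <- vapply(reports, function(r) r@auc, numeric(1))
  expect_true(all(aucs[match(sel, vapply(reports, function(r) r@conformerId,
                                         character(1)))] >= 0.70))
  # identical conformers are all retained (medians attained by all)
  r <- mk("s1", 1)
  r2 <- r
  r2@conformerId <- "s2"
  expect_length(selectConformers(list(r, r2), aucMin = 0), 2)
})

test_that("score tables round-trip through the long CSV format", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  long <- expand.grid(ligand_id = c("L1", "L2"), conformer_id = c("c1", "c2"),
                      kinase_id = "K", component = c("total", "vdw"),
                      stringsAsFactors = FALSE)
  long$value <- seq_len(nrow(long)) / 10
  write.csv(long, tmp, row.names = FALSE)
  st <- readScreenTableCSV(tmp)
  d <- screenData(st)
  expect_setequal(c("total", "vdw") %in% names(d), TRUE)
  expect_equal(nrow(d), 4)
  expect_equal(d$total[d$ligand_id == "L1" & d$conformer_id == "c1"], 0.1)
})
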
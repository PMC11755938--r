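# Per-gene counting and the intolerance regression.

test_that("gene counting follows the coding/common-functional definitions", {
  rec <- makeRecords(n = 3, af = c(0.05, 0.3, 2e-4),
                     effect = c("missense", "synonymous", "lof"))
  cnt <- countGeneVariants(rec, "G1", mafThreshold = 0.001)
  expect_equal(cnt$x, 3L)   # all coding classes
  expect_equal(cnt$y, 1L)   # only the common missense

  # genes absent from the catalog appear with zero counts
  cnt <- countGeneVariants(rec, c("G1", "G2"))
  expect_equal(cnt$x[cnt$gene == "G2"], 0L)
  expect_equal(cnt$y[cnt$gene == "G2"], 0L)

  # noncoding contributes to neither count
  cnt <- countGeneVariants(makeRecords(effect = "noncoding"), "G1")
  expect_equal(c(cnt$x, cnt$y), c(0L, 0L))

  # variant annotated to an unknown gene: warned about, still counted
  expect_warning(cnt <- countGeneVariants(makeRecords(gene = "NEW"), "G1"),
                 "absent from gene models")
  expect_equal(cnt$x[cnt$gene == "NEW"], 1L)
})

test_that("degenerate fits are refused or flagged", {
  expect_error(computeRVIS(data.frame(gene = c("a", "b"), x = 1:2, y = 0)),
               "at least 3 genes")
  expect_error(computeRVIS(data.frame(gene = letters[1:4], x = 5L,
                                      y = 1:4)),
               "identical x")
  # exact linear relation: all scores 0, degenerate flag set
  tab <- computeRVIS(data.frame(gene = letters[1:5], x = (1:5) * 10,
                                y = (1:5) * 2))
  expect_true(rvisFit(tab)$degenerate)
  expect_equal(rvisScores(tab)$rvis, rep(0, 5))
})

test_that("scores match the leave-one-out brute-force oracle", {
  # the 4-gene worked case (the last point's deletion leaves an exact fit,
  # so its leave-one-out score is +Inf)
  cnt <- data.frame(gene = letters[1:4], x = c(10, 20, 30, 40),
                    y = c(4, 8, 12, 20))
  got <- rvisScores(computeRVIS(cnt))$studentized
  want <- oracleStudentized(cnt$x, cnt$y)
  expect_equal(got, want, tolerance = 1e-8)

  # random instances, n <= 50
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(5:50, 1)
    x <- rpois(n, 30)
    y <- rbinom(n, x, 0.3)
    if (var(x) == 0) next
    got <- rvisScores(computeRVIS(data.frame(gene = as.character(seq_len(n)),
                                             x = x, y = y)))$studentized
    expect_equal(got, oracleStudentized(x, y), tolerance = 1e-8,
                 info = paste("seed", s))
  }
})

test_that("centred scores mean 0; residuals invariant to shifting every y", {
  set.seed(42)
  cnt <- data.frame(gene = sprintf("g%03d", 1:200), x = rpois(200, 40))
  cnt$y <- rbinom(200, cnt$x, 0.35)
  tab <- computeRVIS(cnt)
  sc <- rvisScores(tab)
  expect_lt(abs(mean(sc$rvis)), 1e-6)

  # adding a constant to every y is absorbed by the intercept: scores
  # unchanged
  tabB <- computeRVIS(data.frame(gene = cnt$gene, x = cnt$x,
                                 y = cnt$y + 3))
  expect_equal(rvisScores(tabB)$studentized, sc$studentized,
               tolerance = 1e-10)
  expect_equal(rvisFit(tabB)$intercept, rvisFit(tab)$intercept + 3,
               tolerance = 1e-10)
})

test_that("for fixed x, a larger y strictly raises the gene's score", {
  set.seed(7)
  base <- data.frame(gene = sprintf("g%02d", 1:30), x = rpois(30, 40))
  base$y <- rbinom(30, base$x, 0.3)
  s0 <- rvisScores(computeRVIS(base))
  bumped <- base
  bumped$y[5] <- bumped$y[5] + 3
  s1 <- rvisScores(computeRVIS(bumped))
  expect_gt(s1$rvis[5], s0$rvis[5])
})

test_that("outlier removal is one-sided, single-pass, and recentres", {
  set.seed(9)
  cnt <- data.frame(gene = sprintf("g%03d", 1:100), x = rpois(100, 40))
  cnt$y <- rbinom(100, cnt$x, 0.3)
  tab <- computeRVIS(cnt)
  expect_error(removeOutliers(tab, threshold = 0), "positive")

  # nothing above threshold: unchanged
  clean <- removeOutliers(tab, threshold = 11)
  expect_equal(sum(rvisScores(clean)$excluded), 0L)
  expect_equal(rvisScores(clean)$rvis, rvisScores(tab)$rvis)

  # inflate one gene's y until its score crosses the threshold
  inflated <- cnt
  inflated$y[1] <- inflated$x[1] <- 2000
  tab2 <- computeRVIS(inflated)
  stopifnot(rvisScores(tab2)$rvis[1] > 11)
  pruned <- removeOutliers(tab2, threshold = 11)
  sc <- rvisScores(pruned)
  expect_true(sc$excluded[1])
  expect_true(is.na(sc$rvis[1]))
  expect_equal(sum(sc$excluded), 1L)
  expect_lt(abs(mean(sc$rvis[!sc$excluded])), 1e-6)
  # refit equals a fresh fit on the remaining genes
  refit <- computeRVIS(inflated[-1, ])
  expect_equal(sc$rvis[!sc$excluded], rvisScores(refit)$rvis,
               tolerance = 1e-12)

  # one-sided: a strongly negative score is never excluded
  neg <- cnt
  neg$x[2] <- 2000; neg$y[2] <- 0
  tab3 <- computeRVIS(neg)
  stopifnot(min(rvisScores(tab3)$rvis) < -11 ||
              rvisScores(tab3)$rvis[2] < 0)
  pruned3 <- removeOutliers(tab3, threshold = 11)
  expect_false(rvisScores(pruned3)$excluded[2])
})

test_that("constrained genes recover lower scores on simulated catalogs", {
  cfg <- SimConfig(nGenes = 2000, constraintFactor = 0.3, seed = 7)
  tr <- simulateGeneCounts(cfg)
  tab <- computeRVIS(tr[, c("gene", "x", "y")])
  sc <- merge(rvisScores(tab), tr[, c("gene", "constrained")], by = "gene")
  wt <- welchTTest(sc$rvis[sc$constrained], sc$rvis[!sc$constrained])
  expect_lt(wt$meanSet, wt$meanBackground)
  expect_lt(wt$p, 1e-6)

  # point-biserial correlation between the constrained flag and the score
  # is negative across replicate seeds
  negs <- vapply(1:30, function(s) {
    tr <- simulateGeneCounts(SimConfig(nGenes = 400, seed = 7000 + s))
    sc <- rvisScores(computeRVIS(tr[, c("gene", "x", "y")]))
    cor(as.numeric(tr$constrained), sc$rvis) < 0
  }, logical(1))
  expect_gte(sum(negs), 29)
})
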
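# Drug Score aggregation, Total Score, ADMET clustering, Total Score 2.

test_that("sigmoid components hit 0.5 at their conventional midpoints", {
  expect_equal(sigmoidComponent(0, a = 1, b = 0), 0.5)
  expect_equal(sigmoidComponent(5, a = 1, b = -5), 0.5)     # logP midpoint
  expect_equal(sigmoidComponent(500, a = 0.012, b = -6), 0.5)  # MW midpoint
})

test_that("druglikeness is the normalized fragment-score sum", {
  expect_equal(druglikeness(c(1, 1), 2), 1)
  expect_equal(druglikeness(numeric(0), 1), 0)
  expect_equal(druglikeness(c(0.5, -0.5), 2), 0)
  expect_error(druglikeness(c(1), 0), ">= 1")
})

test_that("Drug Score algebra: bounds and toxicity weights", {
  # descriptor params forcing s = 1 isolate the toxicity product
  pOne <- list(logP = c(a = 0, b = -50), logS = c(a = 0, b = -50),
               mw = c(a = 0, b = -50), d = c(a = 0, b = -50))
  expect_equal(drugScore(1, 1, 100, 1, noRisks, params = pOne), 1.0)
  oneHigh <- noRisks; oneHigh["mutagenic"] <- "high"
  expect_equal(drugScore(1, 1, 100, 1, oneHigh, params = pOne), 0.6)
  oneLow <- noRisks; oneLow["irritation"] <- "low"
  expect_equal(drugScore(1, 1, 100, 1, oneLow, params = pOne), 0.8)
  # s = 0 everywhere gives the 0.5^4 lower envelope
  pZero <- list(logP = c(a = 0, b = 50), logS = c(a = 0, b = 50),
                mw = c(a = 0, b = 50), d = c(a = 0, b = 50))
  expect_equal(drugScore(1, 1, 100, 1, noRisks, params = pZero), 0.0625)
  badRisk <- noRisks; badRisk["tumorigenic"] <- "severe"
  expect_error(drugScore(1, 1, 100, 1, badRisk), "severe")
})

test_that("Drug Score lies in (0, 1] and is monotone in d and MW", {
  set.seed(8)
  for (i in 1:20) {
    ds <- drugScore(runif(1, -2, 8), runif(1, -10, 2), runif(1, 100, 2000),
                    runif(1, -1, 1), noRisks)
    expect_gt(ds, 0); expect_lte(ds, 1)
  }
  dGrid <- seq(-2, 2, by = 0.5)
  vals <- vapply(dGrid, function(d) drugScore(2, -3, 400, d, noRisks),
                 numeric(1))
  expect_true(all(diff(vals) > 0))   # increasing in druglikeness
  mwGrid <- seq(500, 2000, by = 100)
  valsMw <- vapply(mwGrid, function(mw) drugScore(2, -3, mw, 1, noRisks),
                   numeric(1))
  expect_true(all(diff(valsMw) < 0))  # decreasing in MW above the midpoint
})

test_that("the printed parameter convention is available and differs", {
  pr <- drugScoreParams("printed")
  expect_equal(unname(pr$logS), c(1, 5))
  expect_false(identical(drugScoreParams("datawarrior"), pr))
})

test_that("Total Score is the dS x S/N product with order preserved", {
  expect_equal(totalScore(0.5, 20), 10)
  expect_equal(totalScore(0, 1000), 0)
  dS <- c(0.2, 0.5, 0.9)
  expect_equal(order(totalScore(dS, 7)), order(dS))
  snr <- c(30, 10, 20)
  expect_equal(order(totalScore(0.4, snr)), order(snr))
  expect_equal(order(-totalScore(0.4, snr * 1000)), order(-snr))
})

test_that("k-means separates well-separated blobs across seeds", {
  ok <- vapply(1:50, function(seed) {
    bl <- makeAdmetBlobs(nPerCluster = 10L, k = 2L, separation = 10,
                         seed = seed)
    cl <- clusterAdmet(bl$table, k = 2L, restarts = 5L, seed = seed)
    tab <- table(cl$assignments$cluster, bl$labels)
    sum(apply(tab, 1, max)) == sum(tab)   # pure clusters up to relabeling
  }, logical(1))
  expect_equal(mean(ok), 1.0)
})

test_that("k-means degenerate cases behave as defined", {
  bl <- makeAdmetBlobs(nPerCluster = 3L, k = 2L, nFeatures = 4L, seed = 2)
  # k = number of rows: every point is its own centroid
  cl <- clusterAdmet(bl$table, k = 6L, restarts = 2L, seed = 1)
  expect_equal(cl$assignments$centroidDistance, rep(0, 6), tolerance = 1e-9)
  expect_equal(cl$withinPct, 0, tolerance = 1e-9)
  # duplicated rows land in the same cluster
  dup <- rbind(bl$table, transform(bl$table, compound_id = paste0(compound_id, "_copy")))
  cl2 <- clusterAdmet(dup, k = 2L, restarts = 5L, seed = 1)
  a <- cl2$assignments
  expect_equal(a$cluster[seq_len(6)], a$cluster[7:12])
  # constant columns are dropped with a warning
  bad <- bl$table; bad$const <- 1
  expect_warning(cl3 <- clusterAdmet(bad, k = 2L, restarts = 2L, seed = 1),
                 "const")
  expect_equal(cl3$droppedColumns, "const")
})

test_that("variance decomposition sums to 100%", {
  bl <- makeAdmetBlobs(nPerCluster = 12L, k = 3L, separation = 6, seed = 33)
  cl <- clusterAdmet(bl$table, k = 3L, restarts = 5L, seed = 42)
  expect_equal(cl$withinPct + cl$betweenPct, 100, tolerance = 1e-9)
})

test_that("Total Score 2 is S/N over centroid distance with zero-distance flag", {
  ts <- totalScore2(30, 2)
  expect_equal(ts$totalScore2, 15)
  expect_false(ts$rankFirst)
  expect_equal(totalScore2(10, 4)$totalScore2,
               totalScore2(10, 2)$totalScore2 / 2)  # doubling distance halves
  two <- totalScore2(c(5, 5), c(1, 2))
  expect_gt(two$totalScore2[1], two$totalScore2[2])  # smaller distance wins
  z <- totalScore2(5, 0)
  expect_true(z$rankFirst)
  expect_true(is.na(z$totalScore2))
})

test_that("descriptor-table Drug Scores respect row identity", {
  tab <- data.frame(compound_id = c("x", "y"),
                    logP = c(2, 9), logS = c(-3, -9), mw = c(350, 1500),
                    d = c(1, -1),
                    irritation = "none", mutagenic = c("none", "high"),
                    reproductive = "none", tumorigenic = "none")
  out <- computeDrugScores(tab)
  expect_equal(out$dS[1],
               drugScore(2, -3, 350, 1, noRisks))
  expect_gt(out$dS[1], out$dS[2])
  expect_error(computeDrugScores(tab[setdiff(names(tab), "logS")]), "logS")
})
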
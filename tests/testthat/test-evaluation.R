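test_that("confusion counts match a hand loop and are order-invariant", {
  expect_equal(unclass(confusionCounts(rep(c(TRUE, FALSE), each = 5),
                                       rep(c(TRUE, FALSE), each = 5))@tp),
               5L)
  cm <- confusionCounts(c(TRUE, TRUE, FALSE), rep(TRUE, 3))
  expect_equal(c(cm@fn, cm@tn), c(0L, 0L))

  withr::local_seed(41)
  truth <- runif(60) < 0.4
  pred <- runif(60) < 0.5
  cm <- confusionCounts(truth, pred)
  o <- bruteConfusion(truth, pred)
  expect_equal(c(cm@tp, cm@fn, cm@fp, cm@tn), unname(o))
  perm <- sample(60)
  cm2 <- confusionCounts(truth[perm], pred[perm])
  expect_equal(c(cm2@tp, cm2@fn, cm2@fp, cm2@tn), unname(o))

  expect_error(confusionCounts(truth, pred[-1]), "length")
  # string label encodings
  cm3 <- confusionCounts(c("bvFTD", "other"),
                         c("bvFTD_compatible", "not_compatible"))
  expect_equal(c(cm3@tp, cm3@tn), c(1L, 1L))
})

test_that("metrics reproduce the published confusion arithmetic", {
  cm <- confusionMatrix(tp = 10, fn = 4, fp = 4, tn = 32)
  m <- classificationMetrics(cm)
  f <- formatMetrics(m)
  expect_equal(f[["sensitivity"]], "71%")
  expect_equal(f[["specificity"]], "89%")
  expect_equal(f[["accuracy"]], "84%")
  expect_equal(f[["lr_pos"]], "6.43")
  expect_equal(f[["fn_rate"]], "29%")
  expect_equal(f[["fp_rate"]], "11%")
  # the negative likelihood ratio implied by these counts rounds to 0.32
  expect_equal(f[["lr_neg"]], "0.32")
  expect_equal(m$accuracy, 42 / 50)
  expect_equal(m$fnRate + m$sensitivity, 1)
})

test_that("metric edge cases are flagged, not fatal", {
  m <- classificationMetrics(confusionMatrix(10, 0, 0, 10))
  expect_equal(m$sensitivity, 1)
  expect_true(is.infinite(m$lrPos))
  expect_true("lr_pos_infinite" %in% m$flags)

  m <- classificationMetrics(confusionMatrix(0, 10, 0, 10))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$lrNeg, 1 / m$specificity)

  expect_error(classificationMetrics(confusionMatrix(0, 0, 5, 5)),
               "sensitivity")
  expect_error(classificationMetrics(confusionMatrix(5, 5, 0, 0)),
               "specificity")
})

test_that("Dice behaves as an overlap measure", {
  a <- array(0, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- 1
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(0, c(6, 6, 6)); b[5:6, 5:6, 5:6] <- 1
  expect_equal(diceCoefficient(a, b), 0)
  # 2x2x2 cube against itself shifted one voxel along x
  shifted <- array(0, c(6, 6, 6)); shifted[3:4, 2:3, 2:3] <- 1
  expect_equal(diceCoefficient(a, shifted), 0.5)
  expect_equal(diceCoefficient(array(0, c(4, 4, 4)),
                               array(0, c(4, 4, 4))), 1)  # both empty
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_error(diceCoefficient(a, array(0, c(5, 5, 5))), "differ")
})

test_that("volume correlation is a plain Pearson r with guards", {
  v <- c(10, 20, 30, 40, 50)
  expect_equal(volumeCorrelation(v, 2 * v), 1)
  expect_equal(volumeCorrelation(v, -v), -1)
  w <- c(12, 19, 33, 38, 52)
  num <- sum((v - mean(v)) * (w - mean(w)))
  den <- sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(volumeCorrelation(v, w), num / den)
  expect_error(volumeCorrelation(v, rep(1, 5)), "variance")
  expect_error(volumeCorrelation(1:2, 1:2), "at least 3")
})

test_that("group comparison applies Welch t and the Bonferroni cap", {
  x <- c(1.1, 1.3, 0.9, 1.2)
  g <- groupCompare(x, x)
  expect_equal(g$t, 0)
  expect_equal(g$pRaw, 1)

  withr::local_seed(43)
  a <- rnorm(20); b <- rnorm(20, 0.3)
  g <- groupCompare(a, b, nComparisons = 5)
  expect_equal(g$pBonferroni, min(1, 5 * g$pRaw))
  expect_gte(g$pBonferroni, g$pRaw)
  ref <- t.test(a, b)
  expect_equal(g$pRaw, ref$p.value)

  g <- groupCompare(rep(2, 3), rep(2, 4))
  expect_true("degenerate_variance" %in% g$flags)
  expect_equal(g$pRaw, 1)
})

test_that("the published APR contrast is detectable at n = 30 per group", {
  # power simulation mirroring the FP-vs-TN anterior-posterior contrast
  hits <- 0
  for (i in 1:100) {
    p <- withr::with_seed(2000 + i, {
      a <- rnorm(30, 1.26, 0.3)
      b <- rnorm(30, 0.97, 0.3)
      groupCompare(a, b)$pRaw
    })
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("misclassification report flags the encoded group contrasts", {
  # cohort built so FNs are older with smaller APR than TPs
  withr::local_seed(47)
  n <- 40
  truth <- rep(TRUE, n)
  pred <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- data.frame(
    age = c(rnorm(n / 2, 63, 8), rnorm(n / 2, 72, 3)),
    apr = c(rnorm(n / 2, 1.4, 0.2), rnorm(n / 2, 1.0, 0.2)))
  rep1 <- suppressWarnings(
    misclassificationReport(feats, truth, pred))
  tpfn <- rep1[rep1$stratum == "TP_vs_FN", ]
  expect_equal(nrow(tpfn), 2)
  expect_gt(tpfn$mean_b[tpfn$feature == "age"],
            tpfn$mean_a[tpfn$feature == "age"])    # FNs older
  expect_lt(tpfn$mean_b[tpfn$feature == "apr"],
            tpfn$mean_a[tpfn$feature == "apr"])    # FNs smaller APR
  expect_equal(unique(tpfn$n_a), 20)
  expect_equal(unique(tpfn$n_b), 20)

  # all-correct predictions leave only empty-stratum warnings
  warns <- testthat::capture_warnings(
    out <- misclassificationReport(feats, truth, rep(TRUE, n)))
  expect_true(all(grepl("skipped", warns)))
  expect_gt(length(warns), 0)
  expect_equal(nrow(out), 0)
})
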
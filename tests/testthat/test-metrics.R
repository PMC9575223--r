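test_that("confusion counts tally predictions at the threshold", {
  cc <- confusionCounts(c(0.9, 0.1), c(1, 0))
  expect_equal(cc, c(TP = 1L, FN = 0L, TN = 1L, FP = 0L))
  ccFlip <- confusionCounts(c(0.1, 0.9), c(1, 0))
  expect_equal(ccFlip[["TP"]], 0L)
  expect_equal(ccFlip[["TN"]], 0L)
  expect_error(confusionCounts(c(0.5), c(1, 0)), "equal length")
  # counting oracle on 1000 random pairs
  set.seed(8)
  p <- runif(1000); y <- rbinom(1000, 1, 0.4); t <- 0.3
  cc2 <- confusionCounts(p, y, t)
  expect_equal(cc2[["TP"]], sum(p >= t & y == 1))
  expect_equal(cc2[["FP"]], sum(p >= t & y == 0))
  expect_equal(cc2[["FN"]], sum(p < t & y == 1))
  expect_equal(cc2[["TN"]], sum(p < t & y == 0))
  expect_equal(sum(cc2), 1000L)
})

test_that("threshold metrics implement the standard formulas", {
  m1 <- computeMetrics(c(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(unname(m1), c(1, 1, 1, 1))
  m2 <- computeMetrics(c(TP = 25, FN = 25, TN = 25, FP = 25))
  expect_equal(m2[["ACC"]], 0.5)
  expect_equal(m2[["MCC"]], 0)
  # hand evaluation of the formulas
  tp <- 50; fn <- 10; tn <- 40; fp <- 20
  m3 <- computeMetrics(c(TP = tp, FN = fn, TN = tn, FP = fp))
  expect_equal(m3[["ACC"]], (tp + tn) / 120, tolerance = 1e-12)
  expect_equal(m3[["SN"]], tp / (tp + fn), tolerance = 1e-12)
  expect_equal(m3[["SP"]], tn / (tn + fp), tolerance = 1e-12)
  expect_equal(m3[["MCC"]],
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
               tolerance = 1e-12)
  # zero-denominator convention and warnings
  m4 <- suppressWarnings(computeMetrics(c(TP = 10, FN = 0, TN = 0, FP = 0)))
  expect_equal(m4[["MCC"]], 0)
  expect_true(is.nan(m4[["SP"]]))
  expect_error(computeMetrics(c(TP = 0, FN = 0, TN = 0, FP = 0)), "zero")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cc <- c(TP = sum(pred & y), FN = sum(!pred & y),
            TN = sum(!pred & !y), FP = sum(pred & !y))
    mcc <- suppressWarnings(computeMetrics(cc)[["MCC"]])
    r <- suppressWarnings(stats::cor(pred, y))
    if (is.na(r)) r <- 0          # degenerate: constant vector
    expect_equal(mcc, r, tolerance = 1e-12)
  }
})

test_that("ACC decomposes as prevalence-weighted SN and SP", {
  set.seed(21)
  p <- runif(500); y <- rbinom(500, 1, 0.3)
  m <- computeMetrics(confusionCounts(p, y, 0.5))
  P <- sum(y == 1); N <- sum(y == 0)
  expect_equal(m[["ACC"]], (m[["SN"]] * P + m[["SP"]] * N) / (P + N),
               tolerance = 1e-12)
})

test_that("ROC/PR curves and their areas behave per contract", {
  # perfect separation
  r <- rocPrCurves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$ap, 1)
  # labels independent of scores: AUC near 1/2
  set.seed(33)
  p <- runif(10000); y <- rbinom(10000, 1, 0.5)
  expect_equal(rocPrCurves(p, y)$auc, 0.5, tolerance = 0.02)
  expect_error(rocPrCurves(c(.1, .2), c(1, 1)), "both classes")
})

test_that("AUC equals the concordant-pair fraction including ties", {
  set.seed(44)
  for (i in 1:30) {
    n <- 20
    p <- round(runif(n), 1)             # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(rocPrCurves(p, y)$auc, oracleAUC(p, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(55)
  p <- runif(300); y <- rbinom(300, 1, 0.4)
  a0 <- rocPrCurves(p, y)$auc
  expect_equal(rocPrCurves(stats::qlogis(p * 0.98 + 0.01), y)$auc, a0)
  expect_equal(rocPrCurves(p^3, y)$auc, a0)
})

test_that("ROC/AUC/AP agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  p <- runif(400); y <- rbinom(400, 1, 0.5)
  ours <- rocPrCurves(p, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours$auc, ref, tolerance = 1e-10)
})

test_that("cross-grid evaluation matches plain evaluation and round-trips", {
  m <- tinyModel(seed = 5)
  ds <- methDataSet(randomDNA(30, 11, seed = 9), rep(c(1, 0), 15))
  g <- crossGrid(list(A = m), list(A = ds))
  expect_equal(nrow(g), 1L)
  ev <- evaluateModel(m, ds)
  expect_equal(g$ACC, unname(ev[["ACC"]]))
  expect_equal(g$AUC, unname(ev[["AUC"]]))
  path <- tempfile(fileext = ".csv")
  writeGrid(g, path)
  back <- readGrid(path)
  expect_equal(back$ACC, g$ACC, tolerance = 1e-12)
  # length contract violation names the pair
  ds14 <- methDataSet(randomDNA(4, 14, seed = 2), c(1, 0, 1, 0))
  expect_error(crossGrid(list(A = m), list(B = ds14)), "A -> B")
})
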
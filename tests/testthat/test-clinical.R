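test_that("single-feature ROC orients by expression direction and matches pair counting", {
  lab <- rep(c("healthy", "cancer"), each = 3)
  sep <- singleFeatureROC(c(1, 2, 3, 10, 11, 12), lab)
  expect_equal(sep$auc, 1)
  expect_equal(sep$direction, "high")

  # lowly expressed indicator: orientation restores the same AUC
  low <- singleFeatureROC(c(10, 11, 12, 1, 2, 3), lab)
  expect_equal(low$auc, 1)
  expect_equal(low$direction, "low")

  set.seed(14)
  for (i in 1:5) {
    v <- rnorm(6)
    roc <- singleFeatureROC(v, lab)
    expect_equal(roc$auc, pairCountAUC(roc$oriented, lab), tolerance = 1e-9)
  }
  expect_warning(deg <- singleFeatureROC(rep(1, 6), lab), "degenerate")
  expect_equal(deg$auc, 0.5)
})

test_that("Youden optimisation matches brute-force threshold enumeration", {
  lab <- rep(c("healthy", "cancer"), each = 5)
  sep <- youdenOptimize(c(1:5, 11:15), lab)
  expect_equal(sep$optimalJ, 1)
  expect_equal(length(sep$thresholds), 100)
  expect_equal(sep$youden, sep$sen + sep$spec - 1)

  set.seed(15)
  v <- rnorm(10)
  got <- youdenOptimize(v, lab)
  thr <- seq(min(v), max(v), length.out = 100)
  oracle <- vapply(thr, function(t) {
    sen <- mean(v[lab == "cancer"] >= t)
    spec <- mean(v[lab == "healthy"] < t)
    sen + spec - 1
  }, numeric(1))
  expect_equal(got$youden, oracle)
  expect_equal(got$optimalThreshold, thr[which.max(oracle)])

  # labels independent of values: J near zero at larger n
  set.seed(16)
  vNull <- rnorm(2000)
  labNull <- rep(c("healthy", "cancer"), 1000)
  jNull <- youdenOptimize(vNull, labNull)$optimalJ
  expect_lt(jNull, 0.12)
  expect_error(youdenOptimize(1:4, rep("cancer", 4)), "both classes")
})

test_that("net-benefit formulas evaluate exactly as written", {
  expect_equal(netBenefit(30, 10, 100, 0.2), 0.275)
  expect_equal(netBenefit(25, 0, 100, 0.7), 0.25)     # FP = 0 -> TP/N
  expect_lte(netBenefit(0, 5, 100, 0.3), 0)
  expect_error(netBenefit(1, 1, 10, 1), "strictly")
  expect_error(netBenefit(1, 1, 10, 0), "strictly")
})

test_that("treat-all variants differ by the documented denominator factor", {
  # standard: limit at t -> 0 is the prevalence; zero at t = prevalence
  expect_equal(treatAllBenefit(50, 50, 1e-9, "standard"), 0.5,
               tolerance = 1e-6)
  expect_equal(treatAllBenefit(50, 50, 0.5, "standard"), 0)
  nPos <- 240; nNeg <- 249; t <- 0.2
  prev <- nPos / (nPos + nNeg)
  printed <- treatAllBenefit(nPos, nNeg, t, "as_printed")
  standard <- treatAllBenefit(nPos, nNeg, t, "standard")
  # the (TP+TN) denominator reduces to the positive count, inflating the
  # curve by exactly 1/prevalence
  expect_equal(printed, standard / prev, tolerance = 1e-12)
  expect_equal(printed, 1 - (nNeg / nPos) * t / (1 - t), tolerance = 1e-12)
})

test_that("Simpson benefit area agrees with a trapezoidal oracle on smooth curves", {
  x <- seq(0.01, 0.99, length.out = 99)
  y <- pmax(0.4 - 0.3 * x - 0.2 * x^2, 0)
  simpson <- maldiDx:::.simpsonArea(x, y)
  trap <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  expect_lt(abs(simpson - trap), 1e-3)
})

test_that("cross-validated DCA approaches the prevalence bound for a separable cohort", {
  fm <- separableMatrix(nPerGroup = 25, shift = 6)
  dca <- dcaCrossval(fm, "random_forest", k = 5, seed = 6)
  prev <- mean(sampleGroups(fm) == "cancer")
  # model net benefit never exceeds the prevalence bound
  expect_true(all(dca$nbModel <= prev + 1e-9))
  # for a near-perfect classifier the low-threshold net benefit is the
  # prevalence
  expect_equal(mean(dca$nbModel[dca$thresholds < 0.3]), prev,
               tolerance = 0.02)
  expect_true(all(dca$ciLow <= dca$nbModel + 1e-12))
  expect_true(all(dca$ciHigh >= dca$nbModel - 1e-12))
  expect_true(all(dca$nbNone == 0))
  expect_gte(dca$benefitArea, 0)
})

test_that("single-feature DCA respects the expression direction and the printed formula", {
  lab <- rep(c("healthy", "cancer"), each = 4)
  hi <- c(1, 2, 3, 4, 10, 11, 12, 13)
  dcaHi <- singleFeatureDCA(hi, lab, "high")
  expect_true(any(dcaHi$nbModel > 0))
  # low direction on negated values reproduces the high-direction curve
  dcaLo <- singleFeatureDCA(-hi, lab, "low")
  expect_equal(dcaHi$nbModel, dcaLo$nbModel, tolerance = 1e-12)

  # 8-point hand case against direct confusion-then-formula evaluation
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  got <- singleFeatureDCA(v, lab, "high", thresholds = c(0.25, 0.5, 0.75))
  oracle <- vapply(c(0.25, 0.5, 0.75), function(t) {
    cut <- quantile(v, t, names = FALSE)
    pos <- v >= cut
    tp <- sum(pos & lab == "cancer"); fp <- sum(pos & lab == "healthy")
    tp / 8 - fp / 8 * t / (1 - t)
  }, numeric(1))
  expect_equal(got$nbModel, oracle)
  expect_error(singleFeatureDCA(v, lab, "sideways"), "arg")
})

test_that("the Youden index approaches 2 AUC - 1 for binormal scores", {
  set.seed(17)
  n <- 2000
  scores <- c(rnorm(n, 0), rnorm(n, 1.2))
  lab <- rep(c("healthy", "cancer"), each = n)
  auc <- pairCountAUC(scores, lab)
  j <- youdenOptimize(scores, lab)$optimalJ
  # the ROC curve passes through the optimal operating point, so
  # AUC >= (J + 1)/2 always; for equal-variance binormal scores at
  # delta = 1.2 the theoretical gap 2 Phi(delta/sqrt 2) - 2 Phi(delta/2)
  # is about 0.15, giving a tight two-sided band at n = 2000
  gap <- 2 * pnorm(1.2 / sqrt(2)) - 2 * pnorm(1.2 / 2)
  expect_gte(2 * auc - 1, j - 0.02)
  expect_lt(abs((2 * auc - 1) - j - gap), 0.05)
})
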
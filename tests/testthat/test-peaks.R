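test_that("peak detection applies the height and width thresholds", {
  # 2% bump is below the 3% floor: exactly one peak survives
  s <- gaussianSpectrum(c(1050, 1150), areas = c(100, 2), sigma = 2,
                        mzMax = 1300)
  expect_equal(length(detectPeaks(s)), 1)

  flat <- MassSpectrum(seq(1000, 1100, 0.5), rep(0, 201))
  expect_equal(length(detectPeaks(flat)), 0)

  s2 <- gaussianSpectrum(c(1050, 1150), areas = c(100, 60), sigma = 2,
                         mzMax = 1300)
  pk <- peakTable(detectPeaks(s2))
  expect_equal(nrow(pk), 2)
  expect_true(all(abs(pk$mz - c(1050, 1150)) <= 0.5))
  expect_true(all(pk$width >= 5))
  expect_true(all(pk$area > 0))
})

test_that("matrix-cluster flagging is interval membership with optional exclusion", {
  pl <- makePeakSet(c(1600, 2500))
  kept <- flagMatrixRegion(pl, exclude = TRUE)
  expect_equal(peakTable(kept)$mz, 2500)
  flagged <- flagMatrixRegion(pl)
  expect_equal(peakTable(flagged)$mz, c(1600, 2500))
  expect_equal(peakTable(flagged)$matrixFlag, c(TRUE, FALSE))
  empty <- flagMatrixRegion(makePeakSet(numeric(0)))
  expect_equal(length(empty), 0)
  expect_error(flagMatrixRegion(pl, lo = 2000, hi = 1500), "lo")
})

test_that("greedy alignment groups peaks by ppm distance", {
  # one sample: one feature per peak
  one <- greedyAlign(list(makePeakSet(c(1000, 1200, 1400))))
  expect_equal(nrow(one), 3)
  expect_equal(sum(!is.na(assay(one, "relabund"))), 3)

  # 1000 ppm apart -> merged
  two <- greedyAlign(list(makePeakSet(1000.0, sampleId = "a"),
                          makePeakSet(1001.0, sampleId = "b")))
  expect_equal(nrow(two), 1)
  expect_equal(sum(!is.na(assay(two, "relabund"))), 2)

  # 10,000 ppm apart -> separate features
  far <- greedyAlign(list(makePeakSet(1000.0, sampleId = "a"),
                          makePeakSet(1010.0, sampleId = "b")))
  expect_equal(nrow(far), 2)

  expect_error(greedyAlign(list()), "at least one")
  expect_error(greedyAlign(list(makePeakSet(1000)), tolPpm = -5), "tolPpm")
})

test_that("alignment partitions the peaks and preserves per-spectrum normalisation", {
  coh <- generateCohort(cohortConfig(nCancer = 4, nHealthy = 4,
                                     replicates = 2, nPeaks = 15,
                                     mzMax = 9000, seed = 17))
  ps <- lapply(coh$spectra, function(s)
    detectPeaks(preprocessSpectrum(s)))
  fm <- greedyAlign(ps)
  totalPeaks <- sum(vapply(ps, length, integer(1)))
  v <- assay(fm, "relabund")
  # each non-missing cell is exactly one assigned peak
  expect_equal(sum(!is.na(v)), totalPeaks)
  # detected relative areas of each spectrum sum to one
  expect_equal(unname(colSums(v, na.rm = TRUE)), rep(1, ncol(v)))
  expect_true(all(diff(featureMz(fm)) > 0))
})

test_that("greedy alignment matches the exhaustive optimal partition on small instances", {
  set.seed(42)
  nChecked <- 0
  for (rep in 1:12) {
    nSamples <- sample(2:4, 1)
    nClusters <- sample(2:3, 1)
    centers <- sort(runif(nClusters, 1000, 1300))
    # keep clusters far apart relative to the tolerance window
    while (any(diff(centers) / centers[-length(centers)] * 1e6 < 12000))
      centers <- sort(runif(nClusters, 1000, 1300))
    spec <- integer(0); mzv <- numeric(0); hv <- numeric(0)
    for (s in seq_len(nSamples)) {
      present <- which(runif(nClusters) < 0.8)
      for (cl in present) {
        spec <- c(spec, s)
        mzv <- c(mzv, centers[cl] * (1 + runif(1, -1e-3, 1e-3)))
        hv <- c(hv, runif(1, 5, 50))
      }
    }
    if (length(mzv) < 2 || length(mzv) > 7) next
    ex <- exhaustiveAlign(spec, mzv, hv, tolPpm = 2500)
    if (!ex$unique) next
    presentSamples <- sort(unique(spec))
    pls <- lapply(presentSamples, function(s)
      makePeakSet(mzv[spec == s], heights = hv[spec == s],
                  sampleId = paste0("s", s)))
    fm <- greedyAlign(pls, tolPpm = 2500)
    # recover greedy's partition from the matrix (fm columns follow
    # presentSamples order)
    v <- assay(fm, "relabund")
    greedyAssign <- integer(length(mzv))
    for (f in seq_len(nrow(v))) {
      for (sm in which(!is.na(v[f, ]))) {
        idx <- which(spec == presentSamples[sm])
        j <- idx[which.min(abs(mzv[idx] - featureMz(fm)[f]))]
        greedyAssign[j] <- f
      }
    }
    expect_identical(canonicalPartition(greedyAssign),
                     canonicalPartition(ex$assignment))
    nChecked <- nChecked + 1
  }
  expect_gte(nChecked, 5)
})

test_that("zero-noise cohorts align to exactly the planted feature count", {
  coh <- generateCohort(cohortConfig(nCancer = 3, nHealthy = 3,
                                     replicates = 2, nPeaks = 12,
                                     mzMax = 9000, noiseSd = 0,
                                     matrixArtifactRate = 0, seed = 23))
  ps <- lapply(coh$spectra, function(s) detectPeaks(preprocessSpectrum(s)))
  fm <- greedyAlign(ps)
  expect_equal(nrow(fm), 12)
})

test_that("imputation fills missing cells as specified", {
  v <- matrix(c(1, 2, NA, 4, 0.5, NA, 3, 2), nrow = 4)
  fm <- PeptideFeatureMatrix(v, featureMz = c(1000, 1100, 1200, 1300),
                             sampleId = c("a", "b"),
                             group = c("healthy", "cancer"))
  z <- imputeMissing(fm, "zero")
  expect_equal(assay(z, "relabund")[3, 1], 0)
  expect_false(anyNA(assay(z, "relabund")))
  # flanked by 2 (at 1100) and 4 (at 1300), equidistant -> 3
  ip <- imputeMissing(fm, "interpolate")
  expect_equal(assay(ip, "relabund")[3, 1], 3)
  # second spectrum: feature at 1100 flanked by 0.5 (1000) and 3 (1200)
  expect_equal(assay(ip, "relabund")[2, 2], 1.75)
  full <- imputeMissing(z, "zero")
  expect_identical(assay(full, "relabund"), assay(z, "relabund"))
  expect_error(imputeMissing(fm, "nearest"), "arg")
  # provenance mask still marks the imputed cell
  expect_false(detectedMask(z)[3, 1])
})

test_that("replicate collapsing averages replicate rows per sample", {
  v <- matrix(c(1, 2, 3,  1, 2, 3,  1, 2, 3,   2, 4, 6), nrow = 3)
  fm <- PeptideFeatureMatrix(v, featureMz = c(1000, 1100, 1200),
                             sampleId = c("a", "a", "a", "b"),
                             group = rep(c("healthy", "cancer"), c(3, 1)),
                             replicate = c(1L, 2L, 3L, 1L))
  out <- collapseReplicates(fm)
  expect_equal(ncol(out), 2)
  expect_equal(unname(assay(out, "relabund")[, 1]), c(1, 2, 3))
  # replicates (1,2,3) of one feature average to 2
  v2 <- matrix(c(1, 2, 3), nrow = 1)
  fm2 <- PeptideFeatureMatrix(v2, featureMz = 1000,
                              sampleId = rep("a", 3), group = rep("x", 3),
                              replicate = 1:3)
  expect_equal(unname(assay(collapseReplicates(fm2), "relabund")[1, 1]), 2)
  # single replicate: identity
  single <- PeptideFeatureMatrix(matrix(1:2 / 3, 2), c(1000, 1100),
                                 "a", "healthy")
  expect_identical(assay(collapseReplicates(single), "relabund"),
                   assay(single, "relabund"))
})
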
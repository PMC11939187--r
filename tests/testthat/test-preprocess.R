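test_that("Savitzky-Golay filter reproduces low-order polynomials and matches a sliding regression oracle", {
  mz <- seq(1000, 1100, by = 0.5)
  # constants and polynomials up to the filter order pass through
  const <- MassSpectrum(mz, rep(7, length(mz)))
  expect_equal(intensityValues(savgolSmooth(const)), rep(7, length(mz)))
  u <- seq(-1, 1, length.out = length(mz))
  yPoly <- 3 + 2 * u - 5 * u^2 + u^3
  got <- intensityValues(savgolSmooth(MassSpectrum(mz, yPoly)))
  inner <- 11:(length(mz) - 10)
  expect_equal(got[inner], yPoly[inner], tolerance = 1e-8)
  # the order-10 edge transient correction is numerically ill-conditioned;
  # edge values are still reproduced to ~1e-4
  expect_lt(max(abs(got - yPoly)), 1e-3)

  # interior points equal an explicit least-squares window fit
  set.seed(4)
  y <- 50 * dnorm(mz, 1050, 3) * 5 + rnorm(length(mz), 0, 0.3)
  sm <- intensityValues(savgolSmooth(MassSpectrum(mz, y), 21, 4))
  half <- 10
  oracle <- vapply(seq(half + 1, length(y) - half), function(i) {
    w <- (i - half):(i + half)
    fit <- lm(y[w] ~ poly(seq_along(w), 4, raw = TRUE))
    unname(fitted(fit)[half + 1])
  }, numeric(1))
  expect_equal(sm[(half + 1):(length(y) - half)], oracle, tolerance = 1e-6)

  expect_error(savgolSmooth(const, window = 20), "odd")
  expect_error(savgolSmooth(const, window = 21, polyorder = 21), "polyorder")
})

test_that("moving median removes isolated spikes and matches direct order-statistic computation", {
  mz <- 1:60 + 999
  flat <- MassSpectrum(mz, rep(3, 60))
  expect_equal(intensityValues(medianDespike(flat)), rep(3, 60))

  spike <- rep(0, 60); spike[30] <- 100
  out <- intensityValues(medianDespike(MassSpectrum(mz, spike)))
  expect_equal(out[30], 0)

  s <- MassSpectrum(mz, rnorm(60))
  expect_equal(intensityValues(medianDespike(s, window = 1)),
               intensityValues(s))

  # even window: centered, left-biased, reflected padding
  set.seed(1)
  y <- rnorm(40)
  got <- intensityValues(medianDespike(MassSpectrum(1:40 + 999, y), 10))
  reflect <- function(i, n) { i <- ifelse(i < 1, 2 - i, i)
                              ifelse(i > n, 2 * n - i, i) }
  oracle <- vapply(1:40, function(i)
    median(y[reflect((i - 5):(i + 4), 40)]), numeric(1))
  expect_equal(got, oracle)

  expect_error(medianDespike(flat, window = 100), "trace length")
})

test_that("white top-hat removes broad baselines, keeps narrow peaks, and matches a brute-force morphology oracle", {
  mz <- seq(1000, 1100, by = 0.5)
  zero <- MassSpectrum(mz, rep(0, length(mz)))
  expect_equal(intensityValues(tophatBaseline(zero)), rep(0, length(mz)))
  # a constant trace is pure baseline
  expect_equal(intensityValues(tophatBaseline(MassSpectrum(mz, rep(5, length(mz))))),
               rep(0, length(mz)))

  # broad smooth hump (width >> element) is removed
  hump <- MassSpectrum(mz, 100 * dnorm(mz, 1050, 30) * 75)
  expect_lt(max(intensityValues(tophatBaseline(hump, 11))), 0.6)

  # brute-force erosion/dilation oracle on short random traces
  bruteTophat <- function(y, k) {
    n <- length(y)
    lo <- -((k - 1) %/% 2); hi <- lo + k - 1
    reflect <- function(i) { i <- ifelse(i < 1, 2 - i, i)
                             ifelse(i > n, 2 * n - i, i) }
    ero <- vapply(1:n, function(i) min(y[reflect((i + lo):(i + hi))]),
                  numeric(1))
    dil <- vapply(1:n, function(i) max(ero[reflect((i + lo):(i + hi))]),
                  numeric(1))
    pmax(y - dil, 0)
  }
  set.seed(9)
  for (k in c(3, 11)) {
    y <- abs(rnorm(150)) + 20 * dnorm(1:150, 75, 2)
    got <- intensityValues(tophatBaseline(MassSpectrum(1:150 + 999, y), k))
    expect_equal(got, bruteTophat(y, k))
  }
})

test_that("the preprocessing cascade preserves apex positions and its stage order is locked", {
  coh <- generateCohort(cohortConfig(nCancer = 1, nHealthy = 1,
                                     replicates = 1, nPeaks = 6,
                                     mzMax = 5000, nUp = 0, nDown = 0,
                                     noiseSd = 0, intensityCv = 0,
                                     baselineAmplitude = 0,
                                     massJitterPpm = 0,
                                     matrixArtifactRate = 0, seed = 8))
  s <- coh$spectra[[1]]
  out <- preprocessSpectrum(s)
  expect_identical(mzValues(out), mzValues(s))        # grid untouched
  apexTrue <- round(truePeakMz(coh$truth))
  pk <- peakTable(detectPeaks(out))
  expect_equal(nrow(pk), 6)
  expect_true(all(abs(pk$mz - truePeakMz(coh$truth)) <= 1))

  # flat input ends all-zero
  mz <- seq(1000, 1100, 0.5)
  expect_equal(intensityValues(preprocessSpectrum(MassSpectrum(mz, rep(4, length(mz))))),
               rep(0, length(mz)))

  # permuting the stages changes the result on a baseline-laden trace
  sBase <- generateCohort(cohortConfig(nCancer = 1, nHealthy = 0,
                                       replicates = 1, nPeaks = 4,
                                       mzMax = 3000, nUp = 0, nDown = 0,
                                       baselineAmplitude = 50,
                                       matrixArtifactRate = 0,
                                       seed = 3))$spectra[[1]]
  specified <- tophatBaseline(medianDespike(savgolSmooth(sBase)))
  permuted <- savgolSmooth(medianDespike(tophatBaseline(sBase)))
  expect_gt(max(abs(intensityValues(specified) - intensityValues(permuted))),
            1e-3)
})
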
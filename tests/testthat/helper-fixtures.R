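# Shared fixtures, built lazily once per session and cached.

suppressPackageStartupMessages(library(SummarizedExperiment))

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a clean Gaussian-peak spectrum on a uniform grid
gaussianSpectrum <- function(centers, areas, sigma = 2, mzMin = 1000,
                             mzMax = 1200, step = 0.5, baseline = 0,
                             noiseSd = 0, sampleId = "s1", group = NA) {
  mz <- seq(mzMin, mzMax, by = step)
  y <- rep(baseline, length(mz))
  for (i in seq_along(centers))
    y <- y + areas[i] * dnorm(mz, centers[i], sigma)
  if (noiseSd > 0) y <- y + rnorm(length(mz), 0, noiseSd)
  MassSpectrum(mz, y, sampleId, 1L, group)
}

# a small fully separable feature matrix: 3 informative features with a
# large mean shift, the rest standard normal noise
separableMatrix <- function(nPerGroup = 20, nFeatures = 8, shift = 4,
                            nInformative = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerGroup
  X <- matrix(rnorm(n * nFeatures, mean = 10), n, nFeatures)
  g <- rep(c("healthy", "cancer"), each = nPerGroup)
  X[g == "cancer", seq_len(nInformative)] <-
    X[g == "cancer", seq_len(nInformative)] + shift
  X <- pmax(X, 0.01)   # relative areas are non-negative
  PeptideFeatureMatrix(t(X), featureMz = 1000 + 100 * seq_len(nFeatures),
                       sampleId = sprintf("s%02d", seq_len(n)), group = g)
}

# a hand-built PeakSet
makePeakSet <- function(mzs, heights = rep(10, length(mzs)),
                        areas = heights, sampleId = "s1", replicate = 1L,
                        group = NA_character_) {
  ord <- order(mzs)
  new("PeakSet", sampleId = sampleId, replicate = as.integer(replicate),
      group = group,
      peaks = data.frame(mz = mzs[ord], height = heights[ord],
                         area = areas[ord],
                         width = rep(5, length(mzs)),
                         matrixFlag = rep(FALSE, length(mzs))))
}

# the frozen full-size reference cohort, processed end to end (shared by
# the acceptance tests)
referenceRun <- function() {
  cached("referenceRun", function() {
    coh <- generateCohort(defaultCohortConfig())
    peakSets <- lapply(coh$spectra, function(s)
      flagMatrixRegion(detectPeaks(preprocessSpectrum(s))))
    fm <- collapseReplicates(imputeMissing(greedyAlign(peakSets)))
    vf <- volcanoFilter(differentialTest(fm))
    list(truth = coh$truth, fm = fm, volcano = vf)
  })
}

# Mann-Whitney two-sided p by full enumeration of group assignments
permutationMannWhitneyP <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  idx <- combn(length(vals), n1)
  uOf <- function(sel) {
    a <- vals[sel]; b <- vals[-sel]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  uAll <- apply(idx, 2, uOf)
  uObs <- uOf(seq_len(n1))
  mu <- n1 * (length(vals) - n1) / 2
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# AUC by all-pairs concordance counting
pairCountAUC <- function(values, labels) {
  pos <- values[labels == "cancer"]
  neg <- values[labels == "healthy"]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Rand index by explicit pair enumeration
pairEnumerationRand <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# exhaustive optimal alignment partition for small instances: among all
# feasible partitions (<= 1 peak per sample per block, all members within
# tolPpm of the intensity-weighted block centroid) takes the one with the
# fewest blocks, breaking ties by the smallest total absolute deviation
# from the block centroids (all-singleton partitions are always feasible
# with zero deviation, so block count must dominate the objective)
exhaustiveAlign <- function(spec, mz, height, tolPpm) {
  n <- length(mz)
  best <- NULL
  bestCost <- Inf
  nBest <- 0L
  assign <- integer(n)
  feasible <- function(members) {
    if (anyDuplicated(spec[members])) return(FALSE)
    c0 <- sum(mz[members] * height[members]) / sum(height[members])
    all(abs(mz[members] - c0) / c0 * 1e6 <= tolPpm)
  }
  cost <- function(blocks) {
    dev <- sum(vapply(blocks, function(m) {
      c0 <- sum(mz[m] * height[m]) / sum(height[m])
      sum(abs(mz[m] - c0))
    }, numeric(1)))
    length(blocks) * 1e6 + dev
  }
  recurse <- function(i, nBlocks) {
    if (i > n) {
      blocks <- split(seq_len(n), assign[seq_len(n)])
      if (!all(vapply(blocks, feasible, logical(1)))) return()
      cc <- cost(blocks)
      if (cc < bestCost - 1e-12) {
        bestCost <<- cc; best <<- assign[seq_len(n)]; nBest <<- 1L
      } else if (abs(cc - bestCost) <= 1e-12) nBest <<- nBest + 1L
      return()
    }
    for (b in seq_len(nBlocks + 1)) {
      assign[i] <<- b
      recurse(i + 1, max(nBlocks, b))
    }
  }
  recurse(1, 0)
  list(assignment = best, cost = bestCost, unique = nBest == 1L)
}

# canonical form of a partition (sorted blocks) for comparison
canonicalPartition <- function(assign) {
  blocks <- unname(split(seq_along(assign), assign))
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, `[`, integer(1), 1))]
}
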
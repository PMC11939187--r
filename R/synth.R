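#' CohortConfig: synthetic cohort parameters
#'
#' Full parameterisation of the synthetic MALDI-TOF cohort generator:
#' cohort sizes, m/z grid, shared peptide peak set, planted differential
#' structure, noise model and instrumental artifacts.
#'
#' @slot nCancer,nHealthy sample counts per group.
#' @slot replicates replicate spectra (spots) per sample.
#' @slot mzMin,mzMax m/z range in Da.
#' @slot gridStep grid spacing in Da.
#' @slot nPeaks number of shared peptide peaks.
#' @slot peakSigma Gaussian peak sigma in Da.
#' @slot nUp,nDown numbers of up-/down-regulated peaks (cancer vs healthy).
#' @slot log2fcUp,log2fcDown planted log2 fold changes (down is negative).
#' @slot intensityCv within-group coefficient of variation of peak areas.
#' @slot replicateCv extra CV between replicate spots of one sample.
#' @slot baselineAmplitude baseline height at the low-mass end (intensity).
#' @slot noiseSd additive Gaussian trace noise SD (intensity).
#' @slot massJitterPpm per-spectrum instrumental mass drift bound (ppm).
#' @slot matrixArtifactRate expected spurious matrix-cluster peaks per
#'   spectrum in m/z 1500-2000.
#' @slot seed integer RNG seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(nCancer = "integer", nHealthy = "integer",
                 replicates = "integer", mzMin = "numeric", mzMax = "numeric",
                 gridStep = "numeric", nPeaks = "integer",
                 peakSigma = "numeric", nUp = "integer", nDown = "integer",
                 log2fcUp = "numeric", log2fcDown = "numeric",
                 intensityCv = "numeric", replicateCv = "numeric",
                 baselineAmplitude = "numeric", noiseSd = "numeric",
                 massJitterPpm = "numeric", matrixArtifactRate = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  chkNonneg <- function(name) {
    if (slot(object, name) < 0) sprintf("'%s' must be >= 0", name)
  }
  for (f in c("nCancer", "nHealthy", "replicates", "nPeaks", "nUp", "nDown",
              "intensityCv", "replicateCv", "baselineAmplitude", "noiseSd",
              "massJitterPpm", "matrixArtifactRate"))
    msg <- c(msg, chkNonneg(f))
  if (object@replicates < 1) msg <- c(msg, "'replicates' must be >= 1")
  if (object@mzMin >= object@mzMax) msg <- c(msg, "'mzMin' must be < 'mzMax'")
  if (object@gridStep <= 0) msg <- c(msg, "'gridStep' must be > 0")
  if (object@peakSigma <= 0) msg <- c(msg, "'peakSigma' must be > 0")
  if (object@nUp + object@nDown > object@nPeaks)
    msg <- c(msg, "'nUp' + 'nDown' must not exceed 'nPeaks'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d cancer + %d healthy x %d replicates\n",
              object@nCancer, object@nHealthy, object@replicates))
  cat(sprintf("  m/z %g-%g Da (step %g), %d peaks (sigma %g Da), %d up / %d down at log2FC %+g/%+g\n",
              object@mzMin, object@mzMax, object@gridStep, object@nPeaks,
              object@peakSigma, object@nUp, object@nDown,
              object@log2fcUp, object@log2fcDown))
  cat(sprintf("  CV %g (replicate %g), baseline %g, noise SD %g, drift ±%g ppm, artifact rate %g, seed %d\n",
              object@intensityCv, object@replicateCv, object@baselineAmplitude,
              object@noiseSd, object@massJitterPpm, object@matrixArtifactRate,
              object@seed))
})

#' Create a synthetic-cohort configuration
#'
#' @param nCancer,nHealthy samples per group.
#' @param replicates replicate spectra per sample (triplicate spotting by
#'   default).
#' @param mzMin,mzMax,gridStep m/z grid (Da); linear-mode serum profiling
#'   covers 1000-15,000 Da.
#' @param nPeaks shared peptide peaks in the cohort.
#' @param peakSigma Gaussian sigma of each peak (Da).
#' @param nUp,nDown planted up-/down-regulated peak counts.
#' @param log2fcUp,log2fcDown planted effects on the log2 scale.
#' @param intensityCv within-group CV of true peak areas (log-normal).
#' @param replicateCv extra CV between replicate spots.
#' @param baselineAmplitude baseline intensity at the low-mass end.
#' @param noiseSd additive trace noise SD.
#' @param massJitterPpm per-spectrum mass drift bound (uniform in
#'   ±massJitterPpm).
#' @param matrixArtifactRate expected spurious matrix-cluster peaks per
#'   spectrum (Poisson) in m/z 1500-2000.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nCancer = 20, nHealthy = 20, replicates = 3,
                         mzMin = 1000, mzMax = 15000, gridStep = 1,
                         nPeaks = 60, peakSigma = 3, nUp = 5, nDown = 5,
                         log2fcUp = 2, log2fcDown = -2, intensityCv = 0.15,
                         replicateCv = 0.05, baselineAmplitude = 20,
                         noiseSd = 1, massJitterPpm = 1500,
                         matrixArtifactRate = 0.3, seed = 1) {
  new("CohortConfig", nCancer = as.integer(nCancer),
      nHealthy = as.integer(nHealthy), replicates = as.integer(replicates),
      mzMin = mzMin, mzMax = mzMax, gridStep = gridStep,
      nPeaks = as.integer(nPeaks), peakSigma = peakSigma,
      nUp = as.integer(nUp), nDown = as.integer(nDown),
      log2fcUp = log2fcUp, log2fcDown = log2fcDown,
      intensityCv = intensityCv, replicateCv = replicateCv,
      baselineAmplitude = baselineAmplitude, noiseSd = noiseSd,
      massJitterPpm = massJitterPpm, matrixArtifactRate = matrixArtifactRate,
      seed = as.integer(seed))
}

#' The frozen reference cohort configuration
#'
#' The configuration used throughout validation: 240 cancer and 249
#' healthy samples in triplicate over 1000-15,000 Da, 120 shared peptide
#' peaks, 19 upregulated and 23 downregulated peaks with log2 fold changes
#' of +2 / -2, 15% within-group CV, ±1500 ppm instrumental drift and
#' matrix-cluster artifacts in 1500-2000 Da.
#'
#' @param seed RNG seed (the differential structure and noise are redrawn
#'   under the given seed; all other parameters are frozen).
#' @return A \linkS4class{CohortConfig}.
#' @examples
#' cfg <- defaultCohortConfig()
#' @export
defaultCohortConfig <- function(seed = 20250309) {
  cohortConfig(nCancer = 240, nHealthy = 249, replicates = 3,
               mzMin = 1000, mzMax = 15000, gridStep = 1,
               nPeaks = 120, peakSigma = 3, nUp = 19, nDown = 23,
               log2fcUp = 2, log2fcDown = -2, intensityCv = 0.15,
               replicateCv = 0.05, baselineAmplitude = 20, noiseSd = 1,
               massJitterPpm = 1500, matrixArtifactRate = 0.3, seed = seed)
}

#' CohortTruth: generator ground truth
#'
#' The planted structure of a synthetic cohort: true peak centroids, the
#' index sets of up-/down-regulated peaks, and the per-group mean peak
#' areas.
#'
#' @slot peakMz true centroid m/z (Da), ascending.
#' @slot upSet,downSet disjoint integer index sets into \code{peakMz}.
#' @slot meanArea 2 x nPeaks matrix of group mean areas (rows healthy,
#'   cancer).
#' @exportClass CohortTruth
setClass("CohortTruth",
  representation(peakMz = "numeric", upSet = "integer", downSet = "integer",
                 meanArea = "matrix"))

setValidity("CohortTruth", function(object) {
  msg <- character()
  if (length(intersect(object@upSet, object@downSet)))
    msg <- c(msg, "upSet and downSet must be disjoint")
  if (ncol(object@meanArea) != length(object@peakMz))
    msg <- c(msg, "meanArea must have one column per peak")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf("CohortTruth: %d peaks (%d up, %d down)\n",
              length(object@peakMz), length(object@upSet),
              length(object@downSet)))
})

#' @describeIn CohortTruth true centroids (Da)
#' @param x,object a \code{CohortTruth}
#' @export
truePeakMz <- function(x) x@peakMz

#' @describeIn CohortTruth indices of planted up-regulated peaks
#' @export
upSet <- function(x) x@upSet

#' @describeIn CohortTruth indices of planted down-regulated peaks
#' @export
downSet <- function(x) x@downSet

#' @describeIn CohortTruth per-group mean areas (rows healthy, cancer)
#' @export
groupMeanAreas <- function(x) x@meanArea

# Draw nPeaks centroids, log-uniform over [mzMin+margin, mzMax-margin],
# with a minimum relative spacing so that drifted peaks of different
# identities cannot fall inside one alignment window.
drawCentroids <- function(n, mzMin, mzMax, minSpacingPpm = 12000) {
  lo <- log(mzMin + 30); hi <- log(mzMax - 30)
  gap <- minSpacingPpm * 1e-6
  cents <- numeric(0)
  tries <- 0
  while (length(cents) < n) {
    cand <- exp(stats::runif(1, lo, hi))
    if (!length(cents) || all(abs(cand - cents) / pmin(cand, cents) > gap))
      cents <- c(cents, cand)
    tries <- tries + 1
    if (tries > 200 * n)
      stop("could not place ", n, " peaks with the required spacing")
  }
  sort(cents)
}

# multiplicative log-normal factor with unit mean and coefficient of
# variation cv
lnormFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# smooth MALDI-like baseline: exponential decay toward high mass plus a
# gentle quadratic ripple
baselineCurve <- function(mz, amplitude) {
  if (amplitude <= 0) return(numeric(length(mz)))
  u <- (mz - mz[1]) / (mz[length(mz)] - mz[1])
  amplitude * (exp(-4 * u) + 0.15 * (1 - u)^2)
}

#' Generate a synthetic MALDI-TOF cohort with known ground truth
#'
#' Simulates the data-generating process of a case-control serum
#' peptidome study: a shared set of Gaussian peptide peaks on a common m/z
#' grid, log-normal between-sample intensity variation, tighter replicate
#' variation, a smooth decaying baseline, additive trace noise,
#' per-spectrum instrumental mass drift (uniform within
#' ±\code{massJitterPpm}), Poisson-distributed spurious matrix-cluster
#' peaks in 1500-2000 Da, and a planted set of up-/down-regulated peaks
#' whose group mean areas differ by the configured log2 fold change.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A list with \code{spectra} (list of \linkS4class{MassSpectrum},
#'   one per sample x replicate), \code{labels} (data.frame sample_id,
#'   group, replicate) and \code{truth} (\linkS4class{CohortTruth}).
#'   Deterministic for a fixed \code{config@seed}.
#' @examples
#' coh <- generateCohort(cohortConfig(nCancer = 2, nHealthy = 2,
#'                                    replicates = 1, nPeaks = 10,
#'                                    mzMax = 3000, seed = 7))
#' length(coh$spectra)
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  grid <- seq(config@mzMin, config@mzMax, by = config@gridStep)
  P <- config@nPeaks

  cents <- if (P) drawCentroids(P, config@mzMin, config@mzMax) else numeric(0)
  # baseline (healthy) mean areas, log-normal across peaks
  baseArea <- stats::rlnorm(P, meanlog = log(600), sdlog = 0.45)
  dif <- if (config@nUp + config@nDown > 0)
    sample.int(P, config@nUp + config@nDown) else integer(0)
  up <- sort(dif[seq_len(config@nUp)])
  down <- sort(setdiff(dif, up))
  fc <- rep(1, P)
  fc[up] <- 2^config@log2fcUp
  fc[down] <- 2^config@log2fcDown
  meanArea <- rbind(healthy = baseArea, cancer = baseArea * fc)
  truth <- new("CohortTruth", peakMz = cents, upSet = as.integer(up),
               downSet = as.integer(down), meanArea = meanArea)

  groups <- c(rep("cancer", config@nCancer), rep("healthy", config@nHealthy))
  ids <- c(sprintf("CC%03d", seq_len(config@nCancer)),
           sprintf("HC%03d", seq_len(config@nHealthy)))
  spectra <- vector("list", length(ids) * config@replicates)
  labels <- data.frame(sample_id = character(0), group = character(0),
                       replicate = integer(0))
  sig <- config@peakSigma
  halfWin <- ceiling(6 * sig / config@gridStep)
  k <- 0L
  for (i in seq_along(ids)) {
    gmean <- meanArea[groups[i], ]
    sampleArea <- gmean * lnormFactor(P, config@intensityCv)
    for (r in seq_len(config@replicates)) {
      area <- sampleArea * lnormFactor(P, config@replicateCv)
      drift <- if (config@massJitterPpm > 0)
        stats::runif(1, -config@massJitterPpm, config@massJitterPpm) * 1e-6 else 0
      y <- baselineCurve(grid, config@baselineAmplitude)
      addPeak <- function(y, center, a, s) {
        j <- round((center - config@mzMin) / config@gridStep) + 1
        idx <- max(1, j - halfWin):min(length(grid), j + halfWin)
        y[idx] <- y[idx] + a * stats::dnorm(grid[idx], center, s)
        y
      }
      for (p in seq_len(P))
        y <- addPeak(y, cents[p] * (1 + drift), area[p], sig)
      nArt <- stats::rpois(1, config@matrixArtifactRate)
      if (nArt > 0) {
        artMz <- stats::runif(nArt, 1500, 2000)
        artA <- stats::rlnorm(nArt, log(300), 0.5)
        for (a in seq_len(nArt)) y <- addPeak(y, artMz[a], artA[a], sig)
      }
      if (config@noiseSd > 0)
        y <- y + stats::rnorm(length(grid), 0, config@noiseSd)
      k <- k + 1L
      spectra[[k]] <- MassSpectrum(grid, y, ids[i], r, groups[i])
      labels <- rbind(labels, data.frame(sample_id = ids[i],
                                         group = groups[i], replicate = r))
    }
  }
  list(spectra = spectra, labels = labels, truth = truth)
}

#' Write / read a cohort as plain-text files
#'
#' \code{writeCohort} writes one \code{mz,intensity} CSV per replicate
#' spectrum, a \code{labels.csv} (sample_id, group, replicate, file) and a
#' \code{truth.json}. \code{readCohort} reads the same layout back.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return \code{writeCohort}: the directory, invisibly;
#'   \code{readCohort}: a cohort list (truth is NULL if no truth.json).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort$spectra))
  for (i in seq_along(cohort$spectra)) {
    s <- cohort$spectra[[i]]
    files[i] <- sprintf("%s_r%d.csv", s@sampleId, s@replicate)
    utils::write.csv(data.frame(mz = s@mz, intensity = s@intensity),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  lab <- cohort$labels
  lab$file <- files
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(peak_mz = tr@peakMz, up_set = tr@upSet, down_set = tr@downSet,
           mean_area = list(healthy = unname(tr@meanArea["healthy", ]),
                            cancer = unname(tr@meanArea["cancer", ]))),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = FALSE)
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(lab)), function(i) {
    d <- utils::read.csv(file.path(dir, lab$file[i]))
    MassSpectrum(d$mz, d$intensity, lab$sample_id[i], lab$replicate[i],
                 lab$group[i])
  })
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    j <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- new("CohortTruth", peakMz = j$peak_mz,
                 upSet = as.integer(j$up_set), downSet = as.integer(j$down_set),
                 meanArea = rbind(healthy = j$mean_area$healthy,
                                  cancer = j$mean_area$cancer))
  }
  list(spectra = spectra, labels = lab[c("sample_id", "group", "replicate")],
       truth = truth)
}
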
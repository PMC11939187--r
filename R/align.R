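#' Greedy ppm-tolerance cross-sample peak alignment
#'
#' Builds the consensus feature set by an iterative greedy procedure:
#' seed a new feature at the unassigned peak of greatest intensity; for
#' each spectrum take its nearest unassigned peak within \code{tolPpm} of
#' the consensus centroid (at most one peak per spectrum per feature);
#' recompute the centroid as the intensity-weighted mean of the members
#' and reassign until membership stabilises; then fix the feature and
#' repeat until every peak is assigned. Measuring the tolerance against
#' the moving consensus centroid (rather than the seed) absorbs
#' per-spectrum instrumental drift.
#'
#' Matrix cells are relative areas: each spectrum's peak areas divided by
#' that spectrum's total detected peak area, so every spectrum's detected
#' values sum to 1. Cells where a spectrum contributed no peak are NA
#' until \code{\link{imputeMissing}}.
#'
#' @param peakSets list of \linkS4class{PeakSet}, one per spectrum.
#' @param tolPpm mass tolerance in ppm (> 0); the default 2500 ppm covers
#'   instrumental drift of ±1500 ppm plus biological variation.
#' @param maxPasses maximum centroid-update passes per feature.
#' @return A \linkS4class{PeptideFeatureMatrix} (features x spectra) with
#'   missing cells NA.
#' @examples
#' coh <- generateCohort(cohortConfig(nCancer = 3, nHealthy = 3,
#'                                    replicates = 1, nPeaks = 8,
#'                                    mzMax = 4000, seed = 11))
#' ps <- lapply(coh$spectra, function(s) detectPeaks(preprocessSpectrum(s)))
#' fm <- greedyAlign(ps)
#' @export
greedyAlign <- function(peakSets, tolPpm = 2500, maxPasses = 10) {
  if (!length(peakSets)) stop("at least one PeakSet is required")
  if (tolPpm <= 0) stop("'tolPpm' must be > 0")

  counts <- vapply(peakSets, length, integer(1))
  spec <- rep(seq_along(peakSets), counts)
  mz <- unlist(lapply(peakSets, function(p) p@peaks$mz), use.names = FALSE)
  height <- unlist(lapply(peakSets, function(p) p@peaks$height),
                   use.names = FALSE)
  area <- unlist(lapply(peakSets, function(p) p@peaks$area),
                 use.names = FALSE)
  totalArea <- vapply(peakSets, function(p)
    if (length(p)) sum(p@peaks$area) else NA_real_, numeric(1))
  relArea <- area / totalArea[spec]

  sampleId <- vapply(peakSets, function(p) p@sampleId, character(1))
  group <- vapply(peakSets, function(p) p@group, character(1))
  replicate <- vapply(peakSets, function(p) p@replicate, integer(1))

  nPk <- length(mz)
  assigned <- logical(nPk)
  featMz <- numeric(0)
  featMembers <- list()

  while (any(!assigned)) {
    open <- which(!assigned)
    seed <- open[which.max(height[open])]
    center <- mz[seed]
    sel <- seed
    for (pass in seq_len(maxPasses)) {
      d <- abs(mz[open] - center) / center * 1e6
      cand <- open[d <= tolPpm]
      if (!length(cand)) break
      # nearest candidate per spectrum
      ord <- cand[order(spec[cand], abs(mz[cand] - center))]
      newSel <- ord[!duplicated(spec[ord])]
      newCenter <- sum(mz[newSel] * height[newSel]) / sum(height[newSel])
      if (identical(sort(newSel), sort(sel)) && abs(newCenter - center) < 1e-9) {
        center <- newCenter
        break
      }
      sel <- newSel
      center <- newCenter
    }
    if (!(seed %in% sel)) {   # centroid drifted off its seed: keep singleton
      sel <- seed
      center <- mz[seed]
    }
    assigned[sel] <- TRUE
    featMz <- c(featMz, center)
    featMembers <- c(featMembers, list(sel))
  }

  ord <- order(featMz)
  featMz <- featMz[ord]
  featMembers <- featMembers[ord]
  # enforce strictly increasing centroids on pathological ties
  for (i in seq_along(featMz)[-1])
    if (featMz[i] <= featMz[i - 1]) featMz[i] <- featMz[i - 1] + 1e-9

  vals <- matrix(NA_real_, nrow = length(featMz), ncol = length(peakSets))
  for (f in seq_along(featMembers))
    vals[f, spec[featMembers[[f]]]] <- relArea[featMembers[[f]]]

  PeptideFeatureMatrix(vals, featMz, sampleId, group, replicate)
}

#' Impute missing feature-matrix cells
#'
#' \code{mode = "zero"} sets undetected cells to 0 (a peak absent from a
#' spectrum is treated as below the detection floor).
#' \code{mode = "interpolate"} fills each missing cell by linear
#' interpolation, in m/z, between the same spectrum's nearest detected
#' features below and above; cells with no flanking value on one side
#' fall back to 0.
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix}.
#' @param mode \code{"zero"} or \code{"interpolate"}.
#' @return A \linkS4class{PeptideFeatureMatrix} with no missing cells;
#'   the \code{"detected"} assay still records which cells were measured.
#' @export
imputeMissing <- function(fm, mode = c("zero", "interpolate")) {
  mode <- match.arg(mode)
  v <- assay(fm, "relabund")
  if (!anyNA(v)) return(fm)
  if (mode == "zero") {
    v[is.na(v)] <- 0
  } else {
    fmz <- rowData(fm)$mz
    for (j in seq_len(ncol(v))) {
      col <- v[, j]
      miss <- which(is.na(col))
      if (!length(miss)) next
      have <- which(!is.na(col))
      v[miss, j] <- if (length(have) >= 2)
        stats::approx(fmz[have], col[have], xout = fmz[miss],
                      method = "linear", yleft = 0, yright = 0)$y
      else 0
    }
  }
  assay(fm, "relabund") <- v
  fm
}

#' Average replicate spectra into per-sample features
#'
#' Collapses the feature matrix from one column per replicate spectrum to
#' one column per sample by averaging each sample's replicate values
#' (missing cells are ignored in the average; a cell missing in every
#' replicate stays NA).
#'
#' @param fm a \linkS4class{PeptideFeatureMatrix} with replicate columns.
#' @return A \linkS4class{PeptideFeatureMatrix} with one column per
#'   sample; \code{"detected"} is TRUE where any replicate detected the
#'   feature.
#' @export
collapseReplicates <- function(fm) {
  sid <- colData(fm)$sample_id
  uid <- unique(sid)
  if (length(uid) == ncol(fm)) return(fm)
  v <- assay(fm, "relabund")
  d <- assay(fm, "detected")
  vm <- vapply(uid, function(s) {
    m <- rowMeans(v[, sid == s, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(v)))
  vm <- matrix(vm, nrow = nrow(v))
  dm <- matrix(vapply(uid, function(s)
    rowSums(d[, sid == s, drop = FALSE]) > 0, logical(nrow(d))),
    nrow = nrow(d))
  grp <- colData(fm)$group[match(uid, sid)]
  PeptideFeatureMatrix(vm, rowData(fm)$mz, uid, grp,
                       replicate = rep(1L, length(uid)), detected = dm)
}
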
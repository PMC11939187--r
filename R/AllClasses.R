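#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @import SummarizedExperiment
#' @importFrom Rcpp sourceCpp
#' @useDynLib maldiDx, .registration = TRUE
NULL

#' MassSpectrum: a single MALDI-TOF trace
#'
#' One acquisition (one spot of one sample) as an intensity-versus-m/z
#' trace on a strictly increasing m/z grid, with its provenance.
#'
#' @slot sampleId character(1), sample identifier.
#' @slot replicate integer(1), replicate (spot) index within the sample.
#' @slot group character(1), class label (\code{"healthy"}, \code{"cancer"})
#'   or \code{NA} when unknown.
#' @slot mz numeric, strictly increasing m/z grid in Da.
#' @slot intensity numeric, intensities (arbitrary units), same length as
#'   \code{mz}, all finite.
#' @exportClass MassSpectrum
setClass("MassSpectrum",
  representation(sampleId = "character", replicate = "integer",
                 group = "character", mz = "numeric", intensity = "numeric"))

setValidity("MassSpectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (length(object@intensity) && !all(is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a MassSpectrum
#'
#' @param mz strictly increasing numeric m/z grid (Da).
#' @param intensity numeric intensities, same length as \code{mz}.
#' @param sampleId sample identifier.
#' @param replicate replicate index (default 1).
#' @param group class label or \code{NA}.
#' @return A \linkS4class{MassSpectrum}.
#' @examples
#' s <- MassSpectrum(mz = 1000:1010, intensity = rep(1, 11), sampleId = "s1")
#' @export
MassSpectrum <- function(mz, intensity, sampleId = "sample",
                         replicate = 1L, group = NA_character_) {
  new("MassSpectrum", sampleId = as.character(sampleId),
      replicate = as.integer(replicate), group = as.character(group),
      mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' @describeIn MassSpectrum m/z grid accessor
#' @param x,object a \code{MassSpectrum}
#' @export
mzValues <- function(x) x@mz

#' @describeIn MassSpectrum intensity accessor
#' @export
intensityValues <- function(x) x@intensity

setMethod("show", "MassSpectrum", function(object) {
  cat("MassSpectrum", object@sampleId,
      sprintf("(replicate %d, group %s)\n", object@replicate, object@group))
  cat(sprintf("  %d points, m/z %.1f-%.1f Da\n", length(object@mz),
              min(object@mz), max(object@mz)))
})

#' PeakSet: detected peaks of one spectrum
#'
#' Peak centroids with height, trapezoidal area and half-prominence width
#' (in grid points) for one spectrum, ordered by ascending m/z. The
#' \code{matrixFlag} column marks peaks inside the matrix-cluster artifact
#' window (by default m/z 1500-2000).
#'
#' @slot sampleId character(1) sample identifier.
#' @slot replicate integer(1) replicate index.
#' @slot group character(1) class label or NA.
#' @slot peaks data.frame with columns \code{mz}, \code{height},
#'   \code{area}, \code{width}, \code{matrixFlag}.
#' @exportClass PeakSet
setClass("PeakSet",
  representation(sampleId = "character", replicate = "integer",
                 group = "character", peaks = "data.frame"))

setValidity("PeakSet", function(object) {
  p <- object@peaks
  need <- c("mz", "height", "area", "width", "matrixFlag")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(diff(p$mz) <= 0)) return("peak centroids must be strictly increasing")
    if (any(p$height <= 0)) return("heights must be positive")
    if (any(p$area < 0)) return("areas must be non-negative")
    if (any(p$width < 1)) return("widths must be >= 1")
  }
  TRUE
})

#' @describeIn PeakSet peak table accessor
#' @param x,object a \code{PeakSet}
#' @export
peakTable <- function(x) x@peaks

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet", object@sampleId,
      sprintf("(replicate %d): %d peaks\n", object@replicate, nrow(object@peaks)))
})

setMethod("length", "PeakSet", function(x) nrow(x@peaks))

#' PeptideFeatureMatrix: aligned relative-area features
#'
#' A \linkS4class{SummarizedExperiment} whose rows are consensus aligned
#' peptide features (consensus centroid m/z in \code{rowData()$mz}) and
#' whose columns are spectra (or samples once replicates are collapsed).
#' Assay \code{"relabund"} holds relative peak areas (each spectrum's raw
#' peak areas divided by that spectrum's total detected peak area; NA until
#' imputed); assay \code{"detected"} is the logical provenance mask (FALSE
#' where a value was imputed).
#'
#' Column metadata carries \code{sample_id}, \code{group} and
#' \code{replicate}.
#'
#' @exportClass PeptideFeatureMatrix
setClass("PeptideFeatureMatrix", contains = "SummarizedExperiment")

setValidity("PeptideFeatureMatrix", function(object) {
  msg <- character()
  if (!"relabund" %in% assayNames(object))
    msg <- c(msg, "assay 'relabund' is required")
  if (!"mz" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain feature m/z ('mz')")
  else if (nrow(object) > 1 && any(diff(rowData(object)$mz) <= 0))
    msg <- c(msg, "feature m/z must be strictly increasing")
  if (!all(c("sample_id", "group") %in% names(colData(object))))
    msg <- c(msg, "colData must contain sample_id and group")
  v <- assay(object, "relabund")
  if (any(v[!is.na(v)] < 0)) msg <- c(msg, "relative areas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideFeatureMatrix
#'
#' @param values features x spectra numeric matrix of relative areas (NA
#'   where a feature was not detected in a spectrum).
#' @param featureMz strictly increasing consensus centroids (Da), length
#'   \code{nrow(values)}.
#' @param sampleId,group,replicate per-column annotations.
#' @param detected logical mask of the same shape as \code{values}
#'   (default: \code{!is.na(values)}).
#' @return A \linkS4class{PeptideFeatureMatrix}.
#' @export
PeptideFeatureMatrix <- function(values, featureMz, sampleId, group,
                                 replicate = rep(1L, ncol(values)),
                                 detected = !is.na(values)) {
  values <- as.matrix(values)
  rownames(values) <- sprintf("mz_%.2f", featureMz)
  colnames(values) <- make.unique(paste0(sampleId, "_r", replicate))
  dimnames(detected) <- dimnames(values)
  se <- SummarizedExperiment(
    assays = SimpleList(relabund = values, detected = detected),
    rowData = DataFrame(mz = as.numeric(featureMz)),
    colData = DataFrame(sample_id = as.character(sampleId),
                        group = as.character(group),
                        replicate = as.integer(replicate)))
  new("PeptideFeatureMatrix", se)
}

#' @describeIn PeptideFeatureMatrix consensus feature m/z (Da)
#' @param x,object a \code{PeptideFeatureMatrix}
#' @export
featureMz <- function(x) rowData(x)$mz

#' @describeIn PeptideFeatureMatrix per-column group labels
#' @export
sampleGroups <- function(x) colData(x)$group

#' @describeIn PeptideFeatureMatrix samples x features value matrix (the
#'   transposed \code{"relabund"} assay, the orientation classifiers use)
#' @export
featureValues <- function(x) t(assay(x, "relabund"))

#' @describeIn PeptideFeatureMatrix logical imputation provenance mask
#'   (TRUE = actually detected)
#' @export
detectedMask <- function(x) assay(x, "detected")

setMethod("show", "PeptideFeatureMatrix", function(object) {
  v <- assay(object, "relabund")
  cat(sprintf("PeptideFeatureMatrix: %d features x %d spectra\n",
              nrow(object), ncol(object)))
  cat(sprintf("  m/z %.1f-%.1f Da; %.1f%% missing; groups: %s\n",
              min(rowData(object)$mz), max(rowData(object)$mz),
              100 * mean(is.na(v)),
              paste(names(table(colData(object)$group)), collapse = "/")))
})

#' CVEvaluation: cross-validated classifier performance
#'
#' Per-fold one-vs-rest AUCs for both classes, their mean and SD, the
#' macro mean AUC, and the pooled out-of-fold confusion matrix (at the 0.5
#' probability operating point) with the derived accuracy, precision,
#' recall and F1.
#'
#' @slot modelName classifier identifier.
#' @slot aucPerFold k x 2 matrix (columns healthy, cancer) of per-fold
#'   one-vs-rest AUCs.
#' @slot meanAuc,sdAuc named numeric(2): per-class mean and SD across folds.
#' @slot macroAuc numeric(1): mean of the per-class mean AUCs.
#' @slot confusion named numeric: TP, FP, TN, FN pooled over folds
#'   (positive class = cancer).
#' @slot metrics named numeric: accuracy, precision, recall, f1.
#' @slot rocPoints data.frame of pooled (fpr, tpr) points for plotting.
#' @exportClass CVEvaluation
setClass("CVEvaluation",
  representation(modelName = "character", aucPerFold = "matrix",
                 meanAuc = "numeric", sdAuc = "numeric", macroAuc = "numeric",
                 confusion = "numeric", metrics = "numeric",
                 rocPoints = "data.frame"))

setValidity("CVEvaluation", function(object) {
  msg <- character()
  if (any(object@aucPerFold < 0 | object@aucPerFold > 1))
    msg <- c(msg, "AUCs must lie in [0, 1]")
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@confusion)))
    msg <- c(msg, "confusion must have TP, FP, TN, FN")
  if (length(msg)) msg else TRUE
})

#' @describeIn CVEvaluation macro (class-averaged) mean AUC
#' @param x,object a \code{CVEvaluation}
#' @export
macroAUC <- function(x) x@macroAuc

#' @describeIn CVEvaluation pooled confusion counts (TP, FP, TN, FN)
#' @export
confusionCounts <- function(x) x@confusion

#' @describeIn CVEvaluation accuracy/precision/recall/F1 from the pooled
#'   confusion matrix
#' @export
performanceMetrics <- function(x) x@metrics

setMethod("show", "CVEvaluation", function(object) {
  cat(sprintf("%s: Total mean AUC = %.2f ± %.2f", object@modelName,
              object@macroAuc, mean(object@sdAuc)))
  cat(sprintf(" (Healthy AUC = %.2f ± %.2f, Cancer AUC = %.2f ± %.2f)\n",
              object@meanAuc["healthy"], object@sdAuc["healthy"],
              object@meanAuc["cancer"], object@sdAuc["cancer"]))
  cat(sprintf("  accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n",
              object@metrics["accuracy"], object@metrics["precision"],
              object@metrics["recall"], object@metrics["f1"]))
})
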
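#' Differential peptide test (volcano statistics)
#'
#' Per-feature two-sided Mann-Whitney U test of cancer versus healthy
#' relative abundances, with
#' \eqn{\log_2 FC = \log_2((\bar{x}_{cancer}+\epsilon)/(\bar{x}_{healthy}+\epsilon))}
#' where the pseudocount \eqn{\epsilon} is \code{1e-9} of the grand mean
#' (guarding zero means after zero-imputation). The exact U distribution
#' is used when the smaller group has at most 8 samples and the values
#' are tie-free; otherwise the tie-corrected normal approximation.
#'
#' @param fm an imputed \linkS4class{PeptideFeatureMatrix} with one
#'   column per sample and both groups present (>= 2 samples each).
#' @param adjust optional multiple-testing correction passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}: raw p-values,
#'   as in volcano screening at p < 0.001).
#' @return A \code{DifferentialTable}: data.frame with columns \code{mz},
#'   \code{log2fc}, \code{p} and \code{call} (all \code{"ns"} until
#'   \code{\link{volcanoFilter}}).
#' @examples
#' coh <- generateCohort(cohortConfig(nCancer = 6, nHealthy = 6,
#'                                    replicates = 1, nPeaks = 10,
#'                                    mzMax = 4000, seed = 5))
#' ps <- lapply(coh$spectra, function(s) detectPeaks(preprocessSpectrum(s)))
#' fm <- imputeMissing(greedyAlign(ps))
#' head(differentialTest(fm))
#' @export
differentialTest <- function(fm, adjust = "none") {
  g <- sampleGroups(fm)
  if (length(unique(g)) < 2) stop("both classes must be present")
  if (min(table(g)) < 2) stop("each class needs >= 2 samples")
  v <- featureValues(fm)              # samples x features
  if (anyNA(v)) stop("impute missing values before testing")
  ca <- v[g == "cancer", , drop = FALSE]
  he <- v[g == "healthy", , drop = FALSE]
  eps <- 1e-9 * mean(v)
  log2fc <- log2((colMeans(ca) + eps) / (colMeans(he) + eps))
  nmin <- min(nrow(ca), nrow(he))
  p <- vapply(seq_len(ncol(v)), function(j) {
    x <- ca[, j]; y <- he[, j]
    ties <- anyDuplicated(c(x, y)) > 0
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = (nmin <= 8 && !ties), correct = FALSE)$p.value
  }, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  out <- data.frame(mz = featureMz(fm), log2fc = unname(log2fc),
                    p = p, call = "ns", stringsAsFactors = FALSE)
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

#' Volcano filtering of differential features
#'
#' Calls a feature up-regulated when \code{p < pThresh} and
#' \code{log2fc > fcThresh}, down-regulated when \code{p < pThresh} and
#' \code{log2fc < -fcThresh}, otherwise not significant. The defaults
#' (p < 0.001, |log2FC| > 1) are the screening operating point.
#'
#' @param dt a \code{DifferentialTable} from \code{\link{differentialTest}}.
#' @param pThresh p-value threshold.
#' @param fcThresh |log2FC| threshold.
#' @return A list with \code{up} and \code{down} (subsets of \code{dt})
#'   and \code{table} (the full table with the \code{call} column set).
#' @export
volcanoFilter <- function(dt, pThresh = 0.001, fcThresh = 1) {
  call <- rep("ns", nrow(dt))
  call[dt$p < pThresh & dt$log2fc > fcThresh] <- "up"
  call[dt$p < pThresh & dt$log2fc < -fcThresh] <- "down"
  dt$call <- call
  list(up = dt[call == "up", , drop = FALSE],
       down = dt[call == "down", , drop = FALSE],
       table = dt)
}

#' Top-k differential features
#'
#' Shortlists the \code{k} features with the largest absolute log2 fold
#' changes (\code{by = "abs_log2fc"}) or the smallest p-values
#' (\code{by = "p"}); ties are broken deterministically by ascending m/z.
#'
#' @param dt a \code{DifferentialTable}.
#' @param by ranking criterion.
#' @param k shortlist size (>= 1). If \code{k} exceeds the number of
#'   features, all are returned with a warning.
#' @return The top-k rows of \code{dt} in ranked order.
#' @export
topFeatures <- function(dt, by = c("abs_log2fc", "p"), k = 20) {
  by <- match.arg(by)
  if (k < 1) stop("'k' must be >= 1")
  if (k > nrow(dt)) {
    warning("k exceeds the number of features; returning all")
    k <- nrow(dt)
  }
  ord <- if (by == "abs_log2fc") order(-abs(dt$log2fc), dt$mz)
         else order(dt$p, dt$mz)
  dt[ord[seq_len(k)], , drop = FALSE]
}

#' Volcano plot
#'
#' log2 fold change against -log10 p with the screening thresholds drawn
#' and called features coloured.
#'
#' @param dt a \code{DifferentialTable} (after \code{\link{volcanoFilter}}
#'   if calls should be coloured).
#' @param pThresh,fcThresh thresholds to draw.
#' @param ... passed to \code{plot}.
#' @return Invisibly, \code{dt}.
#' @export
plotVolcano <- function(dt, pThresh = 0.001, fcThresh = 1, ...) {
  col <- c(ns = "grey60", up = "firebrick", down = "steelblue")[dt$call]
  graphics::plot(dt$log2fc, -log10(dt$p), pch = 19, col = col,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ italic(p)), ...)
  graphics::abline(h = -log10(pThresh), lty = 2)
  graphics::abline(v = c(-fcThresh, fcThresh), lty = 2)
  invisible(dt)
}
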
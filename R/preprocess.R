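#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing of the intensity trace on its
#' unchanged m/z grid. The defaults (window 21, polynomial order 10) are
#' the profiling pipeline's standard settings; the unusually high order
#' makes the filter nearly interpolating, attenuating only the highest
#' frequencies. Edges are handled by the filter's polynomial-extension
#' transient correction, so the output has the input's length.
#'
#' @param s a \linkS4class{MassSpectrum}.
#' @param window odd window size in grid points.
#' @param polyorder polynomial order, must be < window.
#' @return A smoothed \linkS4class{MassSpectrum} on the same grid.
#' @examples
#' s <- MassSpectrum(1:50, sin(1:50 / 5) + rnorm(50, 0, 0.05))
#' sm <- savgolSmooth(s)
#' @export
savgolSmooth <- function(s, window = 21, polyorder = 10) {
  if (window %% 2 != 1) stop("'window' must be odd")
  if (polyorder >= window) stop("'polyorder' must be < 'window'")
  if (length(s@intensity) < window) stop("spectrum shorter than 'window'")
  y <- signal::sgolayfilt(s@intensity, p = polyorder, n = window)
  initialize(s, intensity = as.numeric(y))
}

#' Moving-median despiking
#'
#' Centered moving median of the intensity trace, suppressing sporadic
#' single-point noise spikes. For even windows (the default window of 10)
#' the window is centered with left bias, covering points
#' \eqn{i - w/2, \dots, i + w/2 - 1}; edges use reflected padding, and the
#' median of an even count is the mean of the two central order
#' statistics.
#'
#' @param s a \linkS4class{MassSpectrum}.
#' @param window window size in grid points (>= 1); \code{window = 1} is
#'   the identity.
#' @return A despiked \linkS4class{MassSpectrum}.
#' @export
medianDespike <- function(s, window = 10) {
  if (window < 1) stop("'window' must be >= 1")
  if (window > length(s@intensity)) stop("'window' exceeds trace length")
  if (window == 1) return(s)
  initialize(s, intensity = as.numeric(.runningMedian(s@intensity,
                                                      as.integer(window))))
}

#' White top-hat baseline removal
#'
#' Subtracts the morphological opening (erosion followed by dilation with
#' a flat structuring element) from the intensity trace. Broad structures
#' wider than the element — the slowly varying chemical baseline — survive
#' the opening and are removed; narrow peptide peaks are retained.
#' Negative residuals are clipped to zero so downstream peak areas remain
#' non-negative.
#'
#' @param s a \linkS4class{MassSpectrum}.
#' @param elementSize flat structuring element width in grid points.
#' @return A baseline-corrected \linkS4class{MassSpectrum} with
#'   non-negative intensities.
#' @export
tophatBaseline <- function(s, elementSize = 11) {
  if (elementSize < 1) stop("'elementSize' must be >= 1")
  opened <- .runningMax(.runningMin(s@intensity, as.integer(elementSize)),
                        as.integer(elementSize))
  initialize(s, intensity = pmax(as.numeric(s@intensity - opened), 0))
}

#' Full spectrum preprocessing
#'
#' The standard cleaning cascade in its fixed order: Savitzky-Golay
#' smoothing, moving-median despiking, then white top-hat baseline
#' removal. The m/z grid is never modified.
#'
#' @param s a \linkS4class{MassSpectrum}.
#' @param sgWindow,sgPolyorder Savitzky-Golay parameters.
#' @param medianWindow moving-median window.
#' @param tophatElement top-hat structuring element size.
#' @return A preprocessed \linkS4class{MassSpectrum}.
#' @examples
#' coh <- generateCohort(cohortConfig(nCancer = 1, nHealthy = 1,
#'                                    replicates = 1, nPeaks = 5,
#'                                    mzMax = 3000, seed = 3))
#' p <- preprocessSpectrum(coh$spectra[[1]])
#' @export
preprocessSpectrum <- function(s, sgWindow = 21, sgPolyorder = 10,
                               medianWindow = 10, tophatElement = 11) {
  tophatBaseline(medianDespike(savgolSmooth(s, sgWindow, sgPolyorder),
                               medianWindow), tophatElement)
}
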
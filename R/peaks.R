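#' Detect peaks in a preprocessed spectrum
#'
#' Local maxima whose height reaches \code{minHeightFrac} of the
#' spectrum's maximum intensity and whose width at half prominence spans
#' at least \code{minWidthPoints} grid points. For each peak the bases are
#' the lowest points between the apex and the nearest higher signal on
#' either side; prominence is the apex height above the higher of the two
#' bases, the reported centroid is the intensity-weighted mean m/z over
#' the half-prominence region, and the area is the trapezoidal integral
#' of the trace between the bases.
#'
#' @param s a preprocessed \linkS4class{MassSpectrum}.
#' @param minHeightFrac minimum apex height as a fraction of the
#'   spectrum's maximum intensity (default 0.03, i.e. 3\%).
#' @param minWidthPoints minimum width at half prominence in grid points.
#' @return A \linkS4class{PeakSet} (empty for an all-zero spectrum).
#' @examples
#' mz <- seq(1000, 1100, 0.5)
#' y <- 100 * dnorm(mz, 1050, 2) * sqrt(2 * pi) * 2
#' detectPeaks(MassSpectrum(mz, y))
#' @export
detectPeaks <- function(s, minHeightFrac = 0.03, minWidthPoints = 5) {
  y <- s@intensity
  mz <- s@mz
  n <- length(y)
  empty <- data.frame(mz = numeric(0), height = numeric(0),
                      area = numeric(0), width = numeric(0),
                      matrixFlag = logical(0))
  mk <- function(p) new("PeakSet", sampleId = s@sampleId,
                        replicate = s@replicate, group = s@group, peaks = p)
  if (n < 3 || max(y) <= 0) return(mk(empty))
  thr <- minHeightFrac * max(y)
  # local maxima on the run-length-compressed trace, so plateaus (flat
  # apices produced by the moving median) count as single peaks with the
  # apex at the plateau centre
  r <- rle(y)
  nr <- length(r$values)
  if (nr < 3) return(mk(empty))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  kk <- 2:(nr - 1)
  top <- kk[r$values[kk] > r$values[kk - 1] & r$values[kk] > r$values[kk + 1] &
            r$values[kk] >= thr]
  apex <- starts[top] + (r$lengths[top] - 1) %/% 2
  if (!length(apex)) return(mk(empty))

  rows <- lapply(apex, function(p) {
    h <- y[p]
    # left base: lowest point between apex and nearest higher point (or edge)
    j <- p
    lmin <- p
    while (j > 1 && y[j - 1] <= h) {
      j <- j - 1
      if (y[j] < y[lmin]) lmin <- j
    }
    j <- p
    rmin <- p
    while (j < n && y[j + 1] <= h) {
      j <- j + 1
      if (y[j] < y[rmin]) rmin <- j
    }
    prom <- h - max(y[lmin], y[rmin])
    level <- h - prom / 2
    a <- p
    while (a > lmin && y[a - 1] >= level) a <- a - 1
    b <- p
    while (b < rmin && y[b + 1] >= level) b <- b + 1
    idx <- a:b
    data.frame(
      mz = sum(mz[idx] * y[idx]) / sum(y[idx]),
      height = h,
      area = sum(diff(mz[lmin:rmin]) *
                 (y[lmin:(rmin - 1)] + y[(lmin + 1):rmin]) / 2),
      width = length(idx))
  })
  p <- do.call(rbind, rows)
  p <- p[p$width >= minWidthPoints, , drop = FALSE]
  p <- p[order(p$mz), , drop = FALSE]
  # merge pathological duplicates (two apices sharing a centroid)
  p <- p[!duplicated(p$mz), , drop = FALSE]
  p$matrixFlag <- FALSE
  rownames(p) <- NULL
  mk(p)
}

#' Flag (or drop) matrix-cluster artifact peaks
#'
#' Marks peaks whose centroid lies in the matrix-cluster window (by
#' default m/z 1500-2000 Da), where MALDI matrix adducts produce spurious
#' signals. By default peaks are only flagged, since genuine differential
#' peptides are reported in this mass range too; set
#' \code{exclude = TRUE} to remove them.
#'
#' @param pl a \linkS4class{PeakSet}.
#' @param lo,hi window bounds in Da (\code{lo < hi}).
#' @param exclude drop flagged peaks instead of flagging them.
#' @return A \linkS4class{PeakSet} with \code{matrixFlag} set (and flagged
#'   peaks removed when \code{exclude = TRUE}).
#' @export
flagMatrixRegion <- function(pl, lo = 1500, hi = 2000, exclude = FALSE) {
  if (lo >= hi) stop("'lo' must be < 'hi'")
  p <- pl@peaks
  if (nrow(p)) {
    inWin <- p$mz >= lo & p$mz <= hi
    p$matrixFlag <- p$matrixFlag | inWin
    if (exclude) p <- p[!inWin, , drop = FALSE]
    rownames(p) <- NULL
  }
  initialize(pl, peaks = p)
}
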
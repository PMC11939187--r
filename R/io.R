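#' Read a spectrum from a two-column CSV/TSV
#'
#' Expects columns \code{mz} and \code{intensity} (header required);
#' the delimiter is sniffed from the first line.
#'
#' @param path file path.
#' @param sampleId,replicate,group provenance annotations.
#' @return A \linkS4class{MassSpectrum}.
#' @export
readSpectrumCsv <- function(path, sampleId = basename(path),
                            replicate = 1L, group = NA_character_) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("mz", "intensity") %in% names(d)))
    stop("expected columns 'mz' and 'intensity' in ", path)
  ord <- order(d$mz)
  MassSpectrum(d$mz[ord], d$intensity[ord], sampleId, replicate, group)
}

#' Read spectra from an mzML file
#'
#' Thin wrapper over \pkg{mzR} mapping each scan to a
#' \linkS4class{MassSpectrum} (requires the \pkg{mzR} package).
#'
#' @param path mzML file path.
#' @param sampleId sample identifier (scans become replicates).
#' @param group class label.
#' @return List of \linkS4class{MassSpectrum}.
#' @export
readSpectraMzML <- function(path, sampleId = basename(path),
                            group = NA_character_) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  n <- nrow(mzR::header(h))
  lapply(seq_len(n), function(i) {
    pk <- mzR::peaks(h, i)
    ord <- order(pk[, 1])
    MassSpectrum(pk[ord, 1], pk[ord, 2], sampleId, i, group)
  })
}

#' Write a peak list as CSV
#'
#' @param pl a \linkS4class{PeakSet}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePeakCsv <- function(pl, path) {
  utils::write.csv(cbind(sample_id = pl@sampleId, replicate = pl@replicate,
                         pl@peaks), path, row.names = FALSE)
  invisible(path)
}
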
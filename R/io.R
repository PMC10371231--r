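#' @include AllGenerics.R
NULL

#' Read and write glymphflow volumes and series as NIfTI-1
#'
#' Thin wrappers around RNifti keeping the grid's voxel size in the NIfTI
#' header. \code{writeDCESeries} stores frame times, baseline indices and
#' units in a JSON sidecar next to the image.
#'
#' @param x array, \linkS4class{DCESeries} or \linkS4class{SpeedMap}.
#' @param grid an \linkS4class{ImageGrid}.
#' @param file path ending in .nii or .nii.gz.
#' @return \code{readDCESeries} returns a \linkS4class{DCESeries};
#'   \code{readVolume} an array with a \code{pixdim} attribute.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
writeVolume <- function(x, grid, file) {
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- grid@voxelSize[seq_len(min(3, length(dim(x))))]
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname nifti-io
#' @export
readVolume <- function(file) {
  img <- RNifti::readNifti(file)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname nifti-io
#' @export
writeDCESeries <- function(x, file) {
  stopifnot(is(x, "DCESeries"))
  writeVolume(x@frames, x@grid, file)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", file)
  jsonlite::write_json(list(frameTimes_s = x@frameTimes,
                            baselineIndices = x@baselineIndices,
                            units = x@units,
                            voxelSize_mm = x@grid@voxelSize),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' @rdname nifti-io
#' @export
readDCESeries <- function(file) {
  arr <- readVolume(file)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", file)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- imageGrid3D(dim(arr)[1:3], meta$voxelSize_mm)
  cls <- if (identical(meta$units, "percent")) "PercentChangeSeries"
         else "DCESeries"
  new(cls, frames = array(as.numeric(arr), dim(arr)),
      frameTimes = as.numeric(meta$frameTimes_s),
      baselineIndices = as.integer(meta$baselineIndices),
      units = meta$units, grid = grid)
}

#' Write a speed map as NIfTI-1 with a JSON provenance sidecar
#' @param map a \linkS4class{SpeedMap}.
#' @param file output path.
#' @export
writeSpeedMap <- function(map, file) {
  stopifnot(is(map, "SpeedMap"))
  writeVolume(map@map, map@grid, file)
  jsonlite::write_json(map@provenance, sub("\\.nii(\\.gz)?$", ".json", file),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file)
}

#' Read or write an ICP trace as CSV (time_s, pressure_mmHg)
#'
#' @param rec an \linkS4class{ICPRecording}.
#' @param file CSV path.
#' @param samplingRate required by \code{readIcpCsv} when the time column
#'   spacing should not be trusted for rate recovery (defaults to the
#'   median spacing).
#' @name icp-io
NULL

#' @rdname icp-io
#' @export
writeIcpCsv <- function(rec, file) {
  stopifnot(is(rec, "ICPRecording"))
  t <- (seq_along(rec@samples) - 1) / rec@samplingRate
  write.csv(data.frame(time_s = t, pressure_mmHg = rec@samples), file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname icp-io
#' @export
readIcpCsv <- function(file, samplingRate = NULL) {
  d <- read.csv(file)
  if (is.null(samplingRate))
    samplingRate <- 1 / stats::median(diff(d$time_s))
  new("ICPRecording", samples = d$pressure_mmHg,
      samplingRate = samplingRate)
}

#' Write a time-signal curve as CSV (time_min, signal_au)
#' @param tsc a \linkS4class{TSC}.
#' @param file CSV path.
#' @export
writeTscCsv <- function(tsc, file) {
  stopifnot(is(tsc, "TSC"))
  write.csv(data.frame(time_min = tsc@times, signal_au = tsc@values), file,
            row.names = FALSE)
  invisible(file)
}
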
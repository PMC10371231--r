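#' @include AllGenerics.R
NULL

#' Preprocessing configuration
#'
#' @param fwhm smoothing kernel full-width at half-maximum, mm (default
#'   0.1, applied to percent-change frames).
#' @param windowDuration analysis window fed to the transport solver,
#'   minutes (default 100).
#' @param floorEpsilonFrac density floor offset as a fraction of the series
#'   maximum; percent-change values are clamped at >= 0 and offset by this
#'   floor before the solver because optimal mass transport requires
#'   nonnegative mass and noise produces small negatives.
#' @return a validated list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(fwhm = 0.1, windowDuration = 100,
                             floorEpsilonFrac = 1e-4) {
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (windowDuration <= 0) stop("windowDuration must be positive", call. = FALSE)
  structure(list(fwhm = fwhm, windowDuration = windowDuration,
                 floorEpsilonFrac = floorEpsilonFrac),
            class = "PreprocessConfig")
}

#' Voxel-wise percent signal change from baseline
#'
#' Per voxel, \code{100 * (S_t - Sbar) / Sbar} where \code{Sbar} is the mean
#' over the baseline frames. Voxels with nonpositive baseline mean are set
#' to 0 and counted in the returned metadata. Only post-baseline frames are
#' kept in the output.
#'
#' @param series a raw-signal \linkS4class{DCESeries} with
#'   \code{baselineIndices} set.
#' @return a \linkS4class{PercentChangeSeries}.
#' @examples
#' # baselines 100, 102, 98 and a post frame of 125 -> 25 percent
#' @export
percentChange <- function(series) {
  stopifnot(is(series, "DCESeries"))
  if (series@units != "signal")
    stop("percentChange expects a raw-signal series", call. = FALSE)
  bi <- series@baselineIndices
  if (!length(bi)) stop("series has no baseline frames", call. = FALSE)
  d <- dim(series@frames)
  base <- series@frames[, , , bi, drop = FALSE]
  sbar <- apply(base, 1:3, mean)
  post <- setdiff(seq_len(d[4]), bi)
  bad <- sbar <= 0
  sbarSafe <- ifelse(bad, 1, sbar)
  pc <- array(0, c(d[1:3], length(post)))
  for (j in seq_along(post)) {
    f <- 100 * (series@frames[, , , post[j]] - sbar) / sbarSafe
    f[bad] <- 0
    pc[, , , j] <- f
  }
  new("PercentChangeSeries", frames = pc,
      frameTimes = series@frameTimes[post], baselineIndices = integer(),
      units = "percent", grid = series@grid,
      meta = c(series@meta,
               list(nBadBaseline = sum(bad), baselineIndices = bi)))
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable convolution with \code{sigma_vox = fwhm / (2 sqrt(2 ln 2)) /
#' voxelSize} per axis, reflective (mirror) boundary so the volume total is
#' preserved; \code{fwhm = 0} is the identity. Anisotropic voxels get a
#' per-axis sigma with a warning.
#'
#' @param volume 3D numeric array.
#' @param fwhm full-width at half-maximum, mm.
#' @param voxelSize mm, scalar or length 3.
#' @return smoothed array of the same dimensions.
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' sum(gaussianSmooth(v, 0.4, 0.3))  # 1
#' @export
gaussianSmooth <- function(volume, fwhm, voxelSize = 0.3) {
  stopifnot(length(dim(volume)) == 3L, fwhm >= 0)
  if (fwhm == 0) return(volume)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (length(unique(voxelSize)) > 1L)
    warning("anisotropic voxels: using per-axis smoothing sigma")
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  .cppGaussSmooth(volume, dim(volume), sigmaVox)
}

#' Smooth every frame of a series
#'
#' @param series a \linkS4class{DCESeries} (any units).
#' @param fwhm mm.
#' @return series of the same class with smoothed frames.
#' @export
smoothSeries <- function(series, fwhm) {
  stopifnot(is(series, "DCESeries"))
  if (fwhm == 0) return(series)
  out <- series
  for (k in seq_len(dim(series@frames)[4]))
    out@frames[, , , k] <- gaussianSmooth(series@frames[, , , k], fwhm,
                                          series@grid@voxelSize)
  out@meta$smoothedFwhm <- fwhm
  out
}

#' Restrict a percent-change series to the solver's analysis window
#'
#' Keeps frames acquired within \code{windowDuration} minutes of the first
#' frame; errors if fewer than 2 frames remain (the solver needs pairs).
#' The selection is recorded in the series metadata.
#'
#' @param series a \linkS4class{PercentChangeSeries}.
#' @param windowDuration minutes (default 100).
#' @return the windowed series.
#' @export
selectFrames <- function(series, windowDuration = 100) {
  stopifnot(is(series, "PercentChangeSeries"))
  t0 <- series@frameTimes[1]
  keep <- which(series@frameTimes <= t0 + windowDuration * 60 + 1e-9)
  if (length(keep) < 2L)
    stop("analysis window retains fewer than 2 frames", call. = FALSE)
  out <- series
  out@frames <- series@frames[, , , keep, drop = FALSE]
  out@frameTimes <- series@frameTimes[keep]
  out@meta$frameSelection <- list(windowDuration_min = windowDuration,
                                  kept = keep,
                                  dropped = setdiff(seq_along(series@frameTimes),
                                                    keep))
  out
}

#' Clamp a percent-change series to a positive density floor
#'
#' Negative values (noise) are clamped to zero, then the whole series is
#' offset by \code{floorEpsilonFrac * max(series)} so the solver sees
#' strictly positive mass.
#'
#' @param series a \linkS4class{PercentChangeSeries}.
#' @param floorEpsilonFrac fraction of the series maximum used as offset.
#' @return the floored series.
#' @export
floorDensity <- function(series, floorEpsilonFrac = 1e-4) {
  stopifnot(is(series, "PercentChangeSeries"))
  out <- series
  eps <- floorEpsilonFrac * max(series@frames)
  out@frames <- pmax(series@frames, 0) + eps
  out@meta$densityFloor <- eps
  out
}

#' Run the full preprocessing chain
#'
#' percent change (if raw signal) -> Gaussian smoothing -> window selection
#' -> density floor, in that order. Smoothing is applied to percent-change
#' frames (configurable by calling the stages directly).
#'
#' @param series a \linkS4class{DCESeries} in raw-signal or percent units.
#' @param config a \code{\link{preprocessConfig}}.
#' @return a floored, smoothed, windowed \linkS4class{PercentChangeSeries}.
#' @export
preprocessSeries <- function(series, config = preprocessConfig()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  pc <- if (series@units == "signal") percentChange(series) else series
  pc <- smoothSeries(pc, config$fwhm)
  pc <- selectFrames(pc, config$windowDuration)
  floorDensity(pc, config$floorEpsilonFrac)
}
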
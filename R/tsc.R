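#' @include AllGenerics.R
NULL

#' Extract CSF-normalized time-signal curves from a neck series
#'
#' Per VOI per frame, the mean in-mask signal; each node curve is divided
#' by the subject's CSF curve summary (its maximum by default), and the CSF
#' curve itself is returned unnormalized for provenance. Node volume is the
#' mask voxel count times the voxel volume.
#'
#' @param series a \linkS4class{DCESeries} (neck acquisition).
#' @param voiMasks named list of logical arrays, one per node (names may
#'   encode side as "dcLN.left" etc.).
#' @param csfMask logical array of the CSF reference VOI.
#' @param divisor "max" (default) or "mean" of the CSF curve.
#' @return named list of \linkS4class{TSC}: one per node (normalized) plus
#'   \code{"CSF"} (raw).
#' @export
extractAndNormalize <- function(series, voiMasks, csfMask,
                                divisor = c("max", "mean")) {
  stopifnot(is(series, "DCESeries"))
  divisor <- match.arg(divisor)
  d <- dim(series@frames)[1:3]
  if (!identical(dim(csfMask), as.integer(d)))
    stop("csfMask must match the series grid", call. = FALSE)
  if (!any(csfMask)) stop("empty VOI: CSF", call. = FALSE)
  nf <- dim(series@frames)[4]
  meanCurve <- function(mask) {
    vapply(seq_len(nf), function(k) mean(series@frames[, , , k][mask]),
           numeric(1))
  }
  tMin <- series@frameTimes / 60
  csf <- meanCurve(csfMask)
  ref <- if (divisor == "max") max(csf) else mean(csf)
  if (ref <= 0) stop("CSF reference curve is nonpositive", call. = FALSE)
  voxVol <- prod(series@grid@voxelSize)
  out <- lapply(names(voiMasks), function(nm) {
    m <- voiMasks[[nm]]
    if (!identical(dim(m), as.integer(d)) || !any(m))
      stop("empty VOI: ", nm, call. = FALSE)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    new("TSC", times = tMin, values = meanCurve(m) / ref,
        node = parts[1],
        side = if (length(parts) > 1) parts[2] else "none",
        normalized = TRUE, volume = sum(m) * voxVol)
  })
  names(out) <- names(voiMasks)
  out$CSF <- new("TSC", times = tMin, values = csf, node = "CSF",
                 normalized = FALSE, volume = sum(csfMask) * voxVol)
  out
}

#' Two-time-step moving average of a time-signal curve
#'
#' Trailing 2-point moving average for noise cancellation; the output value
#' is stamped at the later time, so the curve shortens by one point.
#'
#' @param tsc a \linkS4class{TSC} with at least 2 points.
#' @return the smoothed \linkS4class{TSC}.
#' @examples
#' # values 0, 2, 4, 6 -> 1, 3, 5
#' @export
smoothTsc <- function(tsc) {
  stopifnot(is(tsc, "TSC"))
  n <- length(tsc@values)
  if (n < 2L) stop("need at least 2 points to smooth", call. = FALSE)
  v <- (tsc@values[-1] + tsc@values[-n]) / 2
  initialize(tsc, times = tsc@times[-1], values = v)
}

#' Time-to-peak, peak magnitude, and area under a time-signal curve
#'
#' \code{timeToPeak} is the time of the global maximum (earliest on ties),
#' \code{peakMagnitude} that maximum (both read from the smoothed,
#' normalized curve), and \code{auc} the trapezoidal integral over the
#' acquisition window.
#'
#' @param tsc a (smoothed, normalized) \linkS4class{TSC}.
#' @param window optional numeric(2), minutes, restricting the analysis.
#' @return data.frame with node, side, timeToPeak_min, peakMagnitude_au,
#'   auc_au_min, volume_mm3.
#' @export
tscMetrics <- function(tsc, window = NULL) {
  stopifnot(is(tsc, "TSC"))
  t <- tsc@times; v <- tsc@values
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(t) < 2L) stop("analysis window is empty", call. = FALSE)
  i <- which.max(v)                              # earliest tie wins
  auc <- sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  data.frame(node = tsc@node, side = tsc@side, timeToPeak_min = t[i],
             peakMagnitude_au = v[i], auc_au_min = auc,
             volume_mm3 = tsc@volume, stringsAsFactors = FALSE)
}
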
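#' @include AllClasses.R
NULL

#' Accessors for glymphflow objects
#'
#' Small accessor family in the usual Bioconductor style: \code{frames} and
#' \code{frameTimes} for image series, \code{imageGrid}, \code{voxelSize} and
#' \code{gridMask} for the sampling lattice, \code{speedVolume} for speed
#' maps, \code{retained} and \code{pathPositions} for pathline sets.
#'
#' @param x a glymphflow object.
#' @param name mask name for \code{gridMask}.
#' @return The stored component; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridMask", function(x, name) standardGeneric("gridMask"))
#' @rdname accessors
#' @export
setGeneric("speedVolume", function(x) standardGeneric("speedVolume"))
#' @rdname accessors
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))
#' @rdname accessors
#' @export
setGeneric("pathPositions", function(x) standardGeneric("pathPositions"))
#' @rdname accessors
#' @export
setGeneric("pathSpeeds", function(x) standardGeneric("pathSpeeds"))
#' @rdname accessors
#' @export
setGeneric("energyLog", function(x) standardGeneric("energyLog"))

#' Trace pathlines through an estimated or synthetic velocity field
#'
#' @param x a list of \linkS4class{IntervalSolution} objects (the usual
#'   entry point after \code{\link{solveSeries}}) or a single
#'   \linkS4class{VelocityField}.
#' @param ... method-specific arguments; see
#'   \code{\link{tracePathlines,list-method}}.
#' @return a \linkS4class{PathlineSet}.
#' @export
setGeneric("tracePathlines", function(x, ...) standardGeneric("tracePathlines"))

#' @rdname accessors
#' @export
setMethod("frames", "DCESeries", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameTimes", "DCESeries", function(x) x@frameTimes)
#' @rdname accessors
#' @export
setMethod("imageGrid", "DCESeries", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("imageGrid", "SpeedMap", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("imageGrid", "PathlineSet", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("imageGrid", "VelocityField", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ImageGrid", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "DCESeries", function(x) x@grid@voxelSize)
#' @rdname accessors
#' @export
setMethod("gridMask", "ImageGrid", function(x, name) {
  if (!name %in% names(x@masks))
    stop("no mask named '", name, "' on this grid", call. = FALSE)
  x@masks[[name]]
})
#' @rdname accessors
#' @export
setMethod("speedVolume", "SpeedMap", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("retained", "PathlineSet", function(x) x@retained)
#' @rdname accessors
#' @export
setMethod("pathPositions", "PathlineSet", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("pathSpeeds", "PathlineSet", function(x) x@speeds)
#' @rdname accessors
#' @export
setMethod("energyLog", "IntervalSolution", function(x) x@iterations)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(signif(object@voxelSize, 3), collapse = " x ")))
  if (length(object@masks))
    cat("  masks:", paste(names(object@masks), collapse = ", "), "\n")
})

setMethod("show", "DCESeries", function(object) {
  cat(sprintf("%s: %d frames of %s voxels [%s units]\n",
              class(object), dim(object@frames)[4],
              paste(dim(object@frames)[1:3], collapse = " x "),
              object@units))
  cat(sprintf("  times %.1f .. %.1f s; %d baseline frame(s)\n",
              min(object@frameTimes), max(object@frameTimes),
              length(object@baselineIndices)))
})

setMethod("show", "VelocityField", function(object) {
  d <- dim(object@data)
  spd <- speedsMicronsPerSecond(object)
  cat(sprintf("VelocityField: %s voxels, %d substeps over %.0f s\n",
              paste(d[1:3], collapse = " x "), d[5], object@frameInterval))
  cat(sprintf("  |v| mean %.3g, max %.3g um/s\n", mean(spd), max(spd)))
})

setMethod("show", "IntervalSolution", function(object) {
  cat(sprintf("IntervalSolution over [%.0f, %.0f] s\n",
              object@frameTimes[1], object@frameTimes[2]))
  cat(sprintf("  energy total %.6g (kinetic %.6g, mismatch %.6g), %d accepted iterations\n",
              object@energy["total"], object@energy["kinetic"],
              object@energy["mismatch"], nrow(object@iterations)))
})

setMethod("show", "PathlineSet", function(object) {
  cat(sprintf("PathlineSet: %d pathlines (%d retained), %d steps\n",
              dim(object@positions)[3], sum(object@retained),
              nrow(object@speeds)))
})

setMethod("show", "SpeedMap", function(object) {
  pos <- object@map[object@map > 0]
  cat(sprintf("SpeedMap: %s voxels; %d visited; mean positive speed %.3g um/s\n",
              paste(dim(object@map), collapse = " x "), length(pos),
              if (length(pos)) mean(pos) else 0))
})

setMethod("show", "ICPRecording", function(object) {
  cat(sprintf("ICPRecording '%s': %.1f s at %g Hz (%d samples)\n",
              object@subject, length(object@samples) / object@samplingRate,
              object@samplingRate, length(object@samples)))
  if (nrow(object@epochs))
    cat("  epochs:", paste(sprintf("%s [%g, %g]s", object@epochs$label,
                                   object@epochs$start_s, object@epochs$end_s),
                           collapse = ", "), "\n")
})

setMethod("show", "TSC", function(object) {
  cat(sprintf("TSC %s (%s)%s: %d points over %.0f min\n", object@node,
              object@side, if (object@normalized) " [CSF-normalized]" else "",
              length(object@times), diff(range(object@times))))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: df = %d; %d voxels tested; sig A>B %d, B>A %d at alpha %.3g\n",
              object@df, sum(object@included), sum(object@sigAgtB),
              sum(object@sigBgtA), object@alpha))
})

#' Construct an image grid
#'
#' @param dims integer(3) voxels per axis.
#' @param voxelSize voxel edge length in mm; scalar (isotropic) or length 3.
#' @param origin physical origin, mm.
#' @param masks named list of logical arrays.
#' @return an \linkS4class{ImageGrid}.
#' @examples
#' g <- imageGrid3D(c(16, 16, 16), 0.3)
#' @export
imageGrid3D <- function(dims, voxelSize = 0.3, origin = c(0, 0, 0),
                        masks = list()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("ImageGrid", dims = as.integer(dims), voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), masks = masks)
}

#' Convert a velocity field's per-substep speeds to microns per second
#'
#' Internal solver units are voxels per substep; the physical speed is
#' \code{|v| * voxelSize_mm * 1000 * nSubsteps / frameInterval_s}.
#'
#' @param vf a \linkS4class{VelocityField}.
#' @return array (x, y, z, substep) of speeds in um/s.
#' @export
speedsMicronsPerSecond <- function(vf) {
  stopifnot(is(vf, "VelocityField"))
  d <- dim(vf@data)
  spd <- sqrt(vf@data[, , , 1L, , drop = FALSE]^2 +
              vf@data[, , , 2L, , drop = FALSE]^2 +
              vf@data[, , , 3L, , drop = FALSE]^2)
  dim(spd) <- d[c(1:3, 5)]
  spd * vf@grid@voxelSize[1] * 1000 * d[5] / vf@frameInterval
}

# voxel (0-based, centre) <-> physical mm conversions used throughout
voxToMm <- function(idx, grid) {
  sweep(sweep(idx + 0.5, 2, grid@voxelSize, "*"), 2, grid@origin, "+")
}
mmToVox <- function(pos, grid) {
  sweep(sweep(pos, 2, grid@origin, "-"), 2, grid@voxelSize, "/") - 0.5
}
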
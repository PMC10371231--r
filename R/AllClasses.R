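#' @import methods
#' @importFrom stats rnorm runif setNames approx fft pt sd var
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib glymphflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Image sampling grid with named compartment masks
#'
#' Describes the voxel lattice shared by all volumes of one study: grid
#' dimensions, isotropic or per-axis voxel size in mm, physical origin, and a
#' named list of binary compartment masks (e.g. \code{brain}, \code{csf},
#' \code{tissue}, or lymph-node VOIs). The physical position of voxel index
#' \code{(i,j,k)} (0-based) is \code{(i+0.5, j+0.5, k+0.5) * voxelSize} mm;
#' all pathline geometry uses this convention.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot voxelSize numeric(3), voxel edge length in mm per axis.
#' @slot origin numeric(3), physical origin offset in mm.
#' @slot masks named list of logical arrays matching \code{dims}. If
#'   \code{csf} and \code{tissue} are both present they must be disjoint
#'   subsets of \code{brain}.
#' @export
setClass("ImageGrid",
  representation(dims = "integer", voxelSize = "numeric",
                 origin = "numeric", masks = "list"),
  prototype(origin = c(0, 0, 0), masks = list()))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive numbers (mm)")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(object@dims)))
      msg <- c(msg, sprintf("mask '%s' must be a logical array of grid dims", nm))
  }
  ms <- object@masks
  if (all(c("brain", "csf", "tissue") %in% names(ms))) {
    if (any(ms$csf & ms$tissue))
      msg <- c(msg, "csf and tissue masks must be disjoint")
    if (any((ms$csf | ms$tissue) & !ms$brain))
      msg <- c(msg, "csf and tissue masks must be subsets of brain")
  }
  if (length(msg)) msg else TRUE
})

#' Dynamic contrast-enhanced image series
#'
#' Ordered 3D frames with acquisition times. \code{units} records whether the
#' frames are raw signal (\code{"signal"}) or percent signal change from
#' baseline (\code{"percent"}); \code{baselineIndices} marks the pre-contrast
#' frames used to compute the baseline mean.
#'
#' @slot frames 4D numeric array (x, y, z, frame).
#' @slot frameTimes numeric, acquisition time of each frame in seconds,
#'   strictly increasing.
#' @slot baselineIndices integer, indices of pre-contrast frames (may be
#'   empty for percent-change series).
#' @slot units "signal" or "percent".
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot meta free-form provenance list.
#' @export
setClass("DCESeries",
  representation(frames = "array", frameTimes = "numeric",
                 baselineIndices = "integer", units = "character",
                 grid = "ImageGrid", meta = "list"),
  prototype(units = "signal", meta = list()))

setValidity("DCESeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 4L) msg <- c(msg, "frames must be a 4D array")
  else {
    if (!identical(d[1:3], as.integer(object@grid@dims)))
      msg <- c(msg, "frame dims must match grid dims")
    if (d[4] != length(object@frameTimes))
      msg <- c(msg, "frameTimes length must equal number of frames")
  }
  if (length(object@frameTimes) > 1 && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (!object@units %in% c("signal", "percent"))
    msg <- c(msg, "units must be 'signal' or 'percent'")
  if (length(object@baselineIndices) &&
      any(object@baselineIndices < 1L | object@baselineIndices > length(object@frameTimes)))
    msg <- c(msg, "baselineIndices out of range")
  if (length(msg)) msg else TRUE
})

#' Percent-signal-change series
#'
#' A \linkS4class{DCESeries} whose frames are percent signal change from the
#' baseline mean; the baseline average of a noise-free series maps to zero
#' everywhere. Produced by \code{\link{percentChange}}.
#' @export
setClass("PercentChangeSeries", contains = "DCESeries")

#' Ground truth of a synthetic phantom
#'
#' The known velocity field and diffusion coefficient behind a simulated
#' tracer series, used for parameter-recovery testing.
#'
#' @slot velocityTrue 4D array (x, y, z, 3) in mm/s at voxel centers.
#' @slot velocityFun function mapping an n-by-3 matrix of physical positions
#'   (mm) to an n-by-3 matrix of velocities (mm/s); evaluated analytically on
#'   the refined simulation grid.
#' @slot sigmaTrue diffusion coefficient, mm^2/s.
#' @slot expectedMeanSpeed mean |v| over the initial tracer-occupied region,
#'   in um/s.
#' @slot displacementTrue 4D array, mm displaced per frame interval.
#' @slot grid the phantom \linkS4class{ImageGrid}.
#' @export
setClass("GroundTruth",
  representation(velocityTrue = "array", velocityFun = "function",
                 sigmaTrue = "numeric", expectedMeanSpeed = "numeric",
                 displacementTrue = "array", grid = "ImageGrid"))

#' Per-substep velocity field estimated by the rOMT solver
#'
#' @slot data 5D array (x, y, z, component, substep), internal units of
#'   voxels per substep.
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot frameInterval seconds spanned by the full substep sequence of one
#'   frame pair (used by \code{\link{speedsMicronsPerSecond}}).
#' @slot nSubsteps substeps per frame pair.
#' @export
setClass("VelocityField",
  representation(data = "array", grid = "ImageGrid",
                 frameInterval = "numeric", nSubsteps = "integer"))

setValidity("VelocityField", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 5L || d[4] != 3L)
    msg <- c(msg, "data must be (x, y, z, 3, substep)")
  else if (!identical(d[1:3], as.integer(object@grid@dims)))
    msg <- c(msg, "data dims must match grid dims")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "velocity field must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Solution of one rOMT frame-pair problem
#'
#' @slot velocity a \linkS4class{VelocityField}.
#' @slot trajectory 4D array (x, y, z, substep+1): the advected-diffused
#'   density from the first frame to the endpoint.
#' @slot energy named numeric: total, kinetic, mismatch at the solution.
#' @slot iterations data.frame log of accepted outer iterations
#'   (non-increasing total energy).
#' @slot config the \code{\link{romtConfig}} used.
#' @slot frameTimes numeric(2), the times (s) of the two frames.
#' @export
setClass("IntervalSolution",
  representation(velocity = "VelocityField", trajectory = "array",
                 energy = "numeric", iterations = "data.frame",
                 config = "list", frameTimes = "numeric"))

setValidity("IntervalSolution", function(object) {
  msg <- character()
  if (min(object@trajectory) < -1e-8 * max(abs(object@trajectory)))
    msg <- c(msg, "density trajectory must be nonnegative (up to solver tolerance)")
  e <- object@iterations$total
  if (length(e) > 1 && any(diff(e) > 1e-12 * abs(e[-length(e)])))
    msg <- c(msg, "accepted energy log must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Set of traced solute pathlines
#'
#' @slot positions array (step+1, 3, pathline), physical mm.
#' @slot speeds matrix (step, pathline), um/s: |v| at each step's start point.
#' @slot seeds matrix (pathline, 3), 0-based seed voxel indices.
#' @slot retained logical, pathlines whose traversed arc length reached the
#'   retention threshold.
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot provenance list (seed threshold, retention threshold, substeps).
#' @export
setClass("PathlineSet",
  representation(positions = "array", speeds = "matrix", seeds = "matrix",
                 retained = "logical", grid = "ImageGrid",
                 provenance = "list"))

setValidity("PathlineSet", function(object) {
  msg <- character()
  if (any(object@speeds < 0)) msg <- c(msg, "speeds must be nonnegative")
  d <- dim(object@positions)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "positions must be (steps+1, 3, pathlines)")
  else {
    if (d[1] != nrow(object@speeds) + 1L)
      msg <- c(msg, "positions must have one more step than speeds")
    if (d[3] != length(object@retained))
      msg <- c(msg, "retained flag length must match pathline count")
  }
  if (length(msg)) msg else TRUE
})

#' Voxel map of solute speed deposited along pathlines
#'
#' @slot map 3D array, um/s; zero at voxels visited by no retained pathline.
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot provenance list describing seeding and retention settings.
#' @export
setClass("SpeedMap",
  representation(map = "array", grid = "ImageGrid", provenance = "list"),
  prototype(provenance = list()))

setValidity("SpeedMap", function(object) {
  if (any(object@map < 0)) "speed map must be nonnegative" else TRUE
})

#' Intracranial pressure recording
#'
#' @slot samples pressure in mmHg, uniformly sampled.
#' @slot samplingRate Hz.
#' @slot epochs data.frame with columns label, start_s, end_s (e.g. rows
#'   "baseline" and "cpap").
#' @slot subject subject identifier.
#' @export
setClass("ICPRecording",
  representation(samples = "numeric", samplingRate = "numeric",
                 epochs = "data.frame", subject = "character"),
  prototype(epochs = data.frame(label = character(), start_s = numeric(),
                                end_s = numeric()),
            subject = "unknown"))

setValidity("ICPRecording", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Respiratory / cardiac-pulse decomposition of an ICP trace
#'
#' @slot respiratory low-frequency (<= 2 Hz) channel, mmHg.
#' @slot pulse Savitzky-Golay smoothed then high-passed (>= 5 Hz) channel.
#' @slot samplingRate Hz.
#' @slot config filter settings used.
#' @export
setClass("ICPChannels",
  representation(respiratory = "numeric", pulse = "numeric",
                 samplingRate = "numeric", config = "list"))

setValidity("ICPChannels", function(object) {
  if (length(object@respiratory) != length(object@pulse))
    "channels must have equal length" else TRUE
})

#' Lymph-node time-signal curve
#'
#' @slot times minutes from contrast start, strictly increasing.
#' @slot values signal in AU (raw or CSF-normalized).
#' @slot node node label (e.g. "dcLN", "accessory", "submandibular", "CSF").
#' @slot side "left", "right" or "none".
#' @slot normalized whether values are CSF-normalized.
#' @slot volume node VOI volume in mm^3 (NA if unknown).
#' @export
setClass("TSC",
  representation(times = "numeric", values = "numeric", node = "character",
                 side = "character", normalized = "logical",
                 volume = "numeric"),
  prototype(side = "none", normalized = FALSE, volume = NA_real_))

setValidity("TSC", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Two-group voxel-wise study definition
#'
#' @slot groupA,groupB lists of aligned 3D speed-map arrays (um/s), one per
#'   subject, all on \code{grid}.
#' @slot mask logical analysis mask.
#' @slot fwhm smoothing kernel FWHM in mm applied to each map before
#'   statistics (default 0.4).
#' @slot alpha significance level (default 0.05).
#' @slot grid an \linkS4class{ImageGrid}.
#' @export
setClass("GroupStudy",
  representation(groupA = "list", groupB = "list", mask = "array",
                 fwhm = "numeric", alpha = "numeric", grid = "ImageGrid"),
  prototype(fwhm = 0.4, alpha = 0.05))

setValidity("GroupStudy", function(object) {
  msg <- character()
  if (length(object@groupA) < 2L || length(object@groupB) < 2L)
    msg <- c(msg, "each group needs at least 2 subjects")
  dd <- as.integer(object@grid@dims)
  for (m in c(object@groupA, object@groupB))
    if (!identical(dim(m), dd)) { msg <- c(msg, "all maps must share the grid"); break }
  if (!identical(dim(object@mask), dd))
    msg <- c(msg, "mask must match grid dims")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise two-sample t statistic map
#'
#' @slot t pooled-variance t statistic volume (A minus B).
#' @slot pAgtB,pBgtA one-sided p-value volumes for each direction.
#' @slot meanA,meanB smoothed group-mean volumes.
#' @slot df degrees of freedom (nA + nB - 2).
#' @slot sigAgtB,sigBgtA logical significance masks at alpha.
#' @slot included logical mask of voxels actually tested.
#' @slot alpha significance level used.
#' @export
setClass("StatMap",
  representation(t = "array", pAgtB = "array", pBgtA = "array",
                 meanA = "array", meanB = "array", df = "numeric",
                 sigAgtB = "array", sigBgtA = "array", included = "array",
                 alpha = "numeric"))

setValidity("StatMap", function(object) {
  msg <- character()
  p <- c(object@pAgtB[object@included], object@pBgtA[object@included])
  if (length(p) && (min(p) < 0 || max(p) > 1))
    msg <- c(msg, "p values must lie in [0,1]")
  if (any(object@sigAgtB & !object@included) || any(object@sigBgtA & !object@included))
    msg <- c(msg, "significance masks must be subsets of the included mask")
  if (length(msg)) msg else TRUE
})
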
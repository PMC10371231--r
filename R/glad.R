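#' @include AllGenerics.R romt.R
NULL

# Internal worker: RK4 trace through a concatenated per-substep velocity
# stack. V: (n x 3 x S) voxels/substep; seeds in voxel coords;
# umPerVoxStep: length-S conversion to um/s for the per-step speeds.
traceWorker <- function(V, dims, seedsVox, umPerVoxStep, grid,
                        retainVox = 0.5, provenance = list()) {
  S <- length(umPerVoxStep)
  tr <- .cppTrace(V, dims, S, seedsVox)
  posVox <- tr$positions                     # (S+1, 3, p)
  spd <- tr$speeds * umPerVoxStep            # recycles down columns: S x p
  p <- dim(posVox)[3]
  # arc length traversed, voxel units
  if (p > 0) {
    steps <- posVox[-1, , , drop = FALSE] - posVox[-(S + 1), , , drop = FALSE]
    arc <- apply(sqrt(steps[, 1, , drop = FALSE]^2 +
                      steps[, 2, , drop = FALSE]^2 +
                      steps[, 3, , drop = FALSE]^2), 3, sum)
  } else arc <- numeric()
  posMm <- posVox
  for (a in 1:3)
    posMm[, a, ] <- (posVox[, a, ] + 0.5) * grid@voxelSize[a] + grid@origin[a]
  new("PathlineSet", positions = posMm, speeds = spd,
      seeds = round(seedsVox), retained = arc >= retainVox, grid = grid,
      provenance = c(provenance, list(retainVox = retainVox, nSteps = S)))
}

#' @describeIn tracePathlines Trace from the first frame of a solved series.
#'
#' Seeds are the voxel centers inside \code{mask} whose first-frame density
#' exceeds \code{seedThreshold} times the in-mask maximum; integration is
#' one classical RK4 step per solver substep through the trilinearly
#' interpolated velocity (piecewise constant in pseudo-time), concatenated
#' across intervals; positions are clamped to the grid. A pathline is
#' retained when its traversed arc length reaches \code{retainVox} voxels.
#'
#' @param mask logical array (defaults to the grid's brain mask, else all).
#' @param seedThreshold fraction of the in-mask first-frame maximum a voxel
#'   must exceed to seed a pathline (default 0.1).
#' @param retainVox retention threshold: minimum traversed arc length,
#'   voxels (default 0.5).
#' @export
setMethod("tracePathlines", "list",
          function(x, mask = NULL, seedThreshold = 0.1, retainVox = 0.5) {
  if (!length(x) || !all(vapply(x, is, TRUE, "IntervalSolution")))
    stop("x must be a non-empty list of IntervalSolution", call. = FALSE)
  grid <- x[[1]]@velocity@grid
  dims <- as.integer(grid@dims)
  for (s in x)
    if (!identical(as.integer(s@velocity@grid@dims), dims))
      stop("interval solutions must share a grid", call. = FALSE)
  if (is.null(mask))
    mask <- if ("brain" %in% names(grid@masks)) grid@masks$brain
            else array(TRUE, dims)
  rho0 <- x[[1]]@trajectory[, , , 1]
  inMax <- max(rho0[mask])
  seedIdx <- which(mask & rho0 > seedThreshold * inMax, arr.ind = TRUE)
  if (!nrow(seedIdx))
    stop("no seeds: no in-mask voxel exceeds seedThreshold = ",
         seedThreshold, " of the first-frame maximum", call. = FALSE)
  seedsVox <- seedIdx - 1                    # 0-based voxel-centre coords
  V <- unlist(lapply(x, function(s) as.numeric(s@velocity@data)),
              use.names = FALSE)
  um <- unlist(lapply(x, function(s) {
    rep(s@velocity@grid@voxelSize[1] * 1000 * s@velocity@nSubsteps /
          s@velocity@frameInterval, s@velocity@nSubsteps)
  }), use.names = FALSE)
  traceWorker(V, dims, seedsVox, um, grid, retainVox,
              provenance = list(seedThreshold = seedThreshold,
                                nSeeds = nrow(seedsVox),
                                nIntervals = length(x)))
})

#' @describeIn tracePathlines Trace explicit seeds through one velocity field.
#' @param seeds matrix (p, 3) of seed positions in physical mm.
#' @export
setMethod("tracePathlines", "VelocityField",
          function(x, seeds, retainVox = 0.5) {
  grid <- x@grid
  dims <- as.integer(grid@dims)
  seedsVox <- mmToVox(as.matrix(seeds), grid)
  msub <- dim(x@data)[5]
  um <- rep(grid@voxelSize[1] * 1000 * x@nSubsteps / x@frameInterval, msub)
  traceWorker(as.numeric(x@data), dims, seedsVox, um, grid, retainVox,
              provenance = list(seedThreshold = NA, nSeeds = nrow(seedsVox),
                                nIntervals = 1L))
})

#' Deposit pathline speeds into a voxel speed map
#'
#' Each retained pathline deposits its per-step speed into the voxel
#' containing that step's start position; a voxel's value is the arithmetic
#' mean of all speeds deposited there (order-independent), and voxels
#' visited by no retained pathline are zero.
#'
#' @param pathlines a \linkS4class{PathlineSet}.
#' @param grid target \linkS4class{ImageGrid} (defaults to the pathlines'
#'   grid).
#' @return a \linkS4class{SpeedMap} in um/s.
#' @export
speedMap <- function(pathlines, grid = NULL) {
  stopifnot(is(pathlines, "PathlineSet"))
  if (is.null(grid)) grid <- pathlines@grid
  dims <- as.integer(grid@dims)
  pos <- pathlines@positions
  for (a in 1:3)
    pos[, a, ] <- (pos[, a, ] - grid@origin[a]) / grid@voxelSize[a] - 0.5
  dep <- .cppSpeedDeposit(pos, pathlines@speeds, pathlines@retained, dims)
  m <- array(0, dims)
  hit <- dep$count > 0
  m[hit] <- dep$sum[hit] / dep$count[hit]
  new("SpeedMap", map = m, grid = grid,
      provenance = c(pathlines@provenance,
                     list(nRetained = sum(pathlines@retained))))
}

#' Mean solute speed and volume transport flux of a compartment
#'
#' \code{meanSpeed} is the average of all strictly positive speed-map values
#' inside the mask (0 if none); \code{vFlux} is the volume of the pathline
#' network passing through the compartment — the count of in-mask voxels
#' with positive speed times the voxel volume, in mm^3. In the brain-tissue
#' compartment the v-flux measures glymphatic transport.
#'
#' @param map a \linkS4class{SpeedMap}.
#' @param mask logical array on the same grid.
#' @param label compartment label carried into the result.
#' @return data.frame with compartment, meanSpeed_um_s, vFlux_mm3,
#'   nPositive, maskVolume_mm3.
#' @export
transportMetrics <- function(map, mask, label = "whole brain") {
  stopifnot(is(map, "SpeedMap"))
  if (!identical(dim(mask), dim(map@map)))
    stop("mask must match the speed map grid", call. = FALSE)
  if (!any(mask)) stop("empty compartment mask", call. = FALSE)
  voxVol <- prod(map@grid@voxelSize)
  vals <- map@map[mask]
  pos <- vals[vals > 0]
  data.frame(compartment = label,
             meanSpeed_um_s = if (length(pos)) mean(pos) else 0,
             vFlux_mm3 = length(pos) * voxVol,
             nPositive = length(pos),
             maskVolume_mm3 = sum(mask) * voxVol,
             stringsAsFactors = FALSE)
}

#' Velocity flux vectors of a pathline set
#'
#' One displacement vector per retained pathline, connecting its start to
#' its endpoint — how far and in what direction the solute was transported.
#'
#' @param pathlines a \linkS4class{PathlineSet}.
#' @return data.frame with start (mm), displacement (mm) and magnitude (mm)
#'   columns, one row per retained pathline.
#' @export
fluxVectors <- function(pathlines) {
  stopifnot(is(pathlines, "PathlineSet"))
  keep <- which(pathlines@retained)
  S1 <- dim(pathlines@positions)[1]
  start <- t(pathlines@positions[1, , keep, drop = TRUE])
  end <- t(pathlines@positions[S1, , keep, drop = TRUE])
  if (length(keep) == 1L) { start <- matrix(start, 1); end <- matrix(end, 1) }
  if (!length(keep))
    return(data.frame(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      magnitude = numeric()))
  disp <- end - start
  data.frame(x0 = start[, 1], y0 = start[, 2], z0 = start[, 3],
             dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
             magnitude = sqrt(rowSums(disp^2)))
}
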
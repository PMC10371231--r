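# shared fixtures, all built in code

# isotropic 3D Gaussian blob on an n^3 grid (voxel units, centre/width in
# voxel coordinates measured from 0.5-offset centres)
gaussBlob <- function(n, ctr, w) {
  x <- seq_len(n) - 0.5
  r2 <- outer(outer((x - ctr[1])^2, (x - ctr[2])^2, "+"), (x - ctr[3])^2, "+")
  exp(-r2 / (2 * w^2))
}

# small, fast phantom spec used across module tests
tinySpec <- function(...) {
  args <- list(gridDims = c(16L, 16L, 16L), voxelSize = 0.3,
               frameInterval = 300, nFrames = 3L, velocityKind = "constant",
               velocityMagnitude = 0.6, sigmaTrue = 1e-4, bolusWidth = 0.6,
               bolusAmplitude = 30, noiseSd = 0, seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantomSpec, args)
}

# centroid of a 3D density in 0-based voxel coordinates
blobCentroid <- function(rho) {
  d <- dim(rho)
  idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  tot <- sum(rho)
  c(sum(idx$x * rho), sum(idx$y * rho), sum(idx$z * rho)) / tot - 1
}

# synthetic aligned speed-map cohorts: a positive base pattern plus
# smoothed per-subject noise, mimicking pathline speed maps
nullCohort <- function(n, dims = c(10L, 10L, 10L), seed = 1L, shift = 0) {
  base <- 1 + gaussBlob(dims[1], dims / 2, 3)
  lapply(seq_len(n), function(s) {
    set.seed(seed * 1000L + s)
    noise <- gaussianSmooth(array(rnorm(prod(dims), 0, 0.3), dims), 0.3, 0.3)
    pmax(base + shift + noise, 1e-3)
  })
}

# velocity field object with `msub` identical substeps from an (x,y,z,3)
# voxels-per-substep array
constantVF <- function(vArr, msub, grid, frameInterval = 300) {
  d <- dim(vArr)
  data <- array(0, c(d[1:3], 3L, msub))
  for (k in seq_len(msub)) data[, , , , k] <- vArr
  new("VelocityField", data = data, grid = grid,
      frameInterval = frameInterval, nSubsteps = as.integer(msub))
}
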
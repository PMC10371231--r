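test_that("zero velocity yields stationary, unretained pathlines", {
  grid <- imageGrid3D(c(12L, 12L, 12L), 0.3)
  vf <- constantVF(array(0, c(12, 12, 12, 3)), 4L, grid)
  seeds <- voxToMm(cbind(c(3, 6), c(6, 6), c(6, 6)) - 0, grid)
  pl <- tracePathlines(vf, seeds = seeds)
  expect_equal(sum(retained(pl)), 0L)
  p <- pathPositions(pl)
  expect_equal(p[5, , 1], p[1, , 1], tolerance = 1e-14)
})

test_that("constant velocity gives straight pathlines of identical displacement", {
  grid <- imageGrid3D(c(16L, 16L, 16L), 0.3)
  v <- array(0, c(16, 16, 16, 3)); v[, , , 1] <- 0.5   # voxels/substep
  vf <- constantVF(v, 8L, grid, frameInterval = 300)
  seeds <- voxToMm(cbind(c(2, 4, 3), c(5, 8, 10), c(8, 8, 8)), grid)
  pl <- tracePathlines(vf, seeds = seeds)
  fv <- fluxVectors(pl)
  # every vector equals v * T = 0.5 voxels/substep * 8 substeps * 0.3 mm
  expect_equal(fv$dx, rep(1.2, 3), tolerance = 1e-10)
  expect_equal(fv$dy, rep(0, 3), tolerance = 1e-12)
  expect_equal(fv$magnitude, rep(1.2, 3), tolerance = 1e-10)
  expect_true(all(retained(pl)))
  # per-step speed is |v| in um/s: 0.5 vox/substep * 0.3 mm * 1000 * 8/300 s
  expect_equal(as.numeric(pathSpeeds(pl)), rep(0.5 * 0.3 * 1000 * 8 / 300, 24),
               tolerance = 1e-10)
})

test_that("a full rigid-rotation revolution in 64 RK4 steps closes its orbit", {
  n <- 24L
  grid <- imageGrid3D(c(n, n, n), 0.3)
  ctr <- (n / 2) * 0.3                           # mm, grid centre
  # rotation about z with omega * T = 2 pi over 64 substeps
  msub <- 64L
  theta <- 2 * pi / msub                         # radians per substep
  x <- ((1:n) - 0.5)
  v <- array(0, c(n, n, n, 3))
  for (j in 1:n) {
    v[, j, , 1] <- -theta * (x[j] - n / 2)       # -omega (y - yc)
    v[j, , , 2] <- theta * (x[j] - n / 2)        #  omega (x - xc)
  }
  vf <- constantVF(v, msub, grid)
  r0 <- 4 * 0.3                                  # 4-voxel orbit radius, mm
  seeds <- matrix(c(ctr + r0, ctr, ctr), 1)
  pl <- tracePathlines(vf, seeds = seeds)
  p <- pathPositions(pl)
  radii <- sqrt((p[, 1, 1] - ctr)^2 + (p[, 2, 1] - ctr)^2)
  expect_lt(max(abs(radii - r0)) / r0, 0.01)     # radius drift < 1%
  # flux vector of the closed orbit is < 2% of the circumference
  fv <- fluxVectors(pl)
  expect_lt(fv$magnitude, 0.02 * 2 * pi * r0)
})

test_that("speed maps deposit per-step speeds as voxel means", {
  grid <- imageGrid3D(c(12L, 12L, 12L), 0.3)
  # one pathline of constant speed crossing k voxels marks exactly those
  v <- array(0, c(12, 12, 12, 3)); v[, , , 1] <- 1
  vf <- constantVF(v, 4L, grid)
  pl <- tracePathlines(vf, seeds = voxToMm(matrix(c(2, 6, 6), 1), grid))
  sm <- speedMap(pl)
  s <- 1 * 0.3 * 1000 * 4 / 300
  hit <- which(speedVolume(sm) > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 4L)                    # start voxels of 4 steps
  expect_equal(unname(speedVolume(sm)[hit]), rep(s, 4), tolerance = 1e-10)
  # mean over a single pathline's deposit equals its mean speed
  expect_equal(mean(speedVolume(sm)[hit]), mean(pathSpeeds(pl)),
               tolerance = 1e-10)

  # two one-step pathlines with speeds 2 and 4 um/s sharing their start
  # voxel: that voxel averages to 3 um/s
  pos <- array(0, c(2, 3, 2))
  pos[1, , 1] <- c(2, 6, 6); pos[2, , 1] <- c(3, 6, 6)
  pos[1, , 2] <- c(2, 6, 6); pos[2, , 2] <- c(1, 6, 6)
  posMm <- pos
  for (a in 1:3) posMm[, a, ] <- (pos[, a, ] + 0.5) * 0.3
  plShared <- new("PathlineSet", positions = posMm,
                  speeds = matrix(c(2, 4), 1, 2),
                  seeds = matrix(c(2, 6, 6, 2, 6, 6), 2, 3, byrow = TRUE),
                  retained = c(TRUE, TRUE), grid = grid,
                  provenance = list())
  smShared <- speedMap(plShared)
  expect_equal(speedVolume(smShared)[3, 7, 7], 3)
})

test_that("transport metrics count positive speeds and partition across masks", {
  grid <- imageGrid3D(c(6L, 6L, 6L), 0.3)
  m <- array(0, c(6, 6, 6))
  m[1, 1, 1] <- 1; m[2, 1, 1] <- 3               # in-mask positives {1, 3}
  sm <- new("SpeedMap", map = m, grid = grid)
  mask <- array(TRUE, c(6, 6, 6))
  tm <- transportMetrics(sm, mask)
  expect_equal(tm$meanSpeed_um_s, 2)
  expect_equal(tm$vFlux_mm3, 2 * 0.3^3, tolerance = 1e-12)

  # an all-zero map has zero metrics
  tm0 <- transportMetrics(new("SpeedMap", map = m * 0, grid = grid), mask)
  expect_equal(tm0$meanSpeed_um_s, 0)
  expect_equal(tm0$vFlux_mm3, 0)

  # CSF + tissue v-flux sums to brain v-flux when the masks partition it
  set.seed(14)
  m2 <- array(pmax(rnorm(216), 0), c(6, 6, 6))
  sm2 <- new("SpeedMap", map = m2, grid = grid)
  brain <- array(TRUE, c(6, 6, 6))
  csf <- array(rep(c(TRUE, FALSE), length.out = 216), c(6, 6, 6))
  tissue <- !csf
  expect_equal(transportMetrics(sm2, csf)$vFlux_mm3 +
                 transportMetrics(sm2, tissue)$vFlux_mm3,
               transportMetrics(sm2, brain)$vFlux_mm3, tolerance = 1e-12)

  expect_error(transportMetrics(sm, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("lowering the seed threshold never decreases v-flux", {
  spec <- tinySpec(velocityMagnitude = 0.9)
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  pc <- floorDensity(ser)
  sols <- solveSeries(pc, romtConfig(nSubsteps = 4L, maxOuterIterations = 8L,
                                     gnCgMaxit = 10L))
  mask <- array(TRUE, dim = spec$gridDims)
  vflux <- vapply(c(0.5, 0.25, 0.1, 0.05), function(th) {
    sm <- speedMap(tracePathlines(sols, mask = mask, seedThreshold = th))
    transportMetrics(sm, mask)$vFlux_mm3
  }, numeric(1))
  expect_true(all(diff(vflux) >= 0))
})

test_that("flux vector magnitude equals the norm of the displacement", {
  spec <- tinySpec(velocityKind = "smooth_random", velocityMagnitude = 1.2)
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  sols <- solveSeries(floorDensity(ser),
                      romtConfig(nSubsteps = 4L, maxOuterIterations = 6L,
                                 gnCgMaxit = 8L))
  pl <- tracePathlines(sols, retainVox = 0)
  fv <- fluxVectors(pl)
  expect_gt(nrow(fv), 0)
  expect_equal(fv$magnitude, sqrt(fv$dx^2 + fv$dy^2 + fv$dz^2),
               tolerance = 1e-12)
  # no-seed error names the threshold
  expect_error(tracePathlines(sols, seedThreshold = 10), "seedThreshold")
})
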
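test_that("advect-diffuse substep reduces to its limiting cases", {
  dims <- c(8L, 8L, 8L)
  rho <- array(runif(prod(dims)), dims)
  zeroV <- array(0, c(dims, 3))

  # v = 0, sigma = 0: identity
  expect_equal(advectDiffuseStep(rho, zeroV, romtConfig(sigma = 0)), rho,
               tolerance = 1e-14)

  # unit x velocity, sigma = 0: interior impulse shifts one voxel
  imp <- array(0, dims); imp[4, 4, 4] <- 1
  vx <- zeroV; vx[, , , 1] <- 1
  out <- advectDiffuseStep(imp, vx, romtConfig(sigma = 0))
  expect_equal(out[5, 4, 4], 1, tolerance = 1e-14)
  expect_equal(sum(out), 1, tolerance = 1e-14)
})

test_that("implicit diffusion matches a dense-matrix oracle on an 8^3 grid", {
  dims <- c(8L, 8L, 8L)
  n1 <- dims[1]
  # dense 7-point Neumann Laplacian built independently via Kronecker sums
  lap1d <- function(n) {
    L <- diag(-2, n); L[cbind(1:(n-1), 2:n)] <- 1; L[cbind(2:n, 1:(n-1))] <- 1
    L[1, 1] <- -1; L[n, n] <- -1                  # zero-flux ends
    L
  }
  I1 <- diag(n1)
  Ld <- kronecker(I1, kronecker(I1, lap1d(n1))) +
        kronecker(I1, kronecker(lap1d(n1), I1)) +
        kronecker(lap1d(n1), kronecker(I1, I1))
  sigma <- 0.05
  rho <- as.numeric(gaussBlob(8, c(4, 4, 4), 1.2))
  oracle <- solve(diag(length(rho)) - sigma * Ld, rho)
  got <- advectDiffuseStep(array(rho, dims), array(0, c(dims, 3)),
                           romtConfig(sigma = sigma, cgTol = 1e-12,
                                      cgMaxit = 2000))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-8)
})

test_that("forward solve composes substeps exactly and conserves mass", {
  dims <- c(16L, 16L, 16L)
  rho <- array(0, dims); rho[6:10, 6:10, 6:10] <- 1
  msub <- 4L
  set.seed(21)
  V <- array(rnorm(prod(dims) * 3 * msub, 0, 0.15), c(dims, 3, msub))
  cfg <- romtConfig(sigma = 0.002, nSubsteps = msub)

  traj <- forwardSolve(rho, V, cfg)
  # composition property: m manual substeps agree bit for bit
  cur <- rho
  for (k in seq_len(msub)) {
    cur <- advectDiffuseStep(cur, V[, , , , k], cfg)
    expect_identical(as.numeric(traj[, , , k + 1]), as.numeric(cur))
  }
  # interior-supported flow: total mass drift < 1e-8 relative
  masses <- apply(traj, 4, sum)
  expect_lt(max(abs(masses - masses[1])) / masses[1], 1e-8)

  # zero velocity, sigma = 0: all frames identical
  t0 <- forwardSolve(rho, array(0, c(dims, 3, msub)), romtConfig(sigma = 0))
  for (k in 2:(msub + 1)) expect_equal(t0[, , , k], rho, tolerance = 1e-14)

  # constant velocity totalling displacement d moves the centroid by d
  d <- c(2, 1, 0)
  Vc <- array(0, c(dims, 3, msub))
  for (a in 1:3) Vc[, , , a, ] <- d[a] / msub
  tc <- forwardSolve(rho, Vc, romtConfig(sigma = 0))
  shift <- blobCentroid(tc[, , , msub + 1]) - blobCentroid(rho)
  expect_lt(sqrt(sum((shift - d)^2)), 0.1)
})

test_that("rOMT energy matches an independent quadrature oracle", {
  dims <- c(8L, 8L, 8L)
  rho0 <- gaussBlob(8, c(3.5, 4, 4), 1.2)
  rho1 <- gaussBlob(8, c(4.5, 4, 4), 1.2)
  msub <- 3L
  cfg <- romtConfig(sigma = 0.01, beta = 500, nSubsteps = msub,
                    cgTol = 1e-12, cgMaxit = 2000)

  # v = 0, identical frames, sigma = 0: zero energy
  z <- romtEnergy(rho0, rho0, array(0, c(dims, 3, msub)),
                  romtConfig(sigma = 0, beta = 500, nSubsteps = msub))
  expect_equal(unname(z["total"]), 0, tolerance = 1e-14)

  # v = 0, sigma = 0: energy collapses to beta * ||rho0 - rho1||^2
  e0 <- romtEnergy(rho0, rho1, array(0, c(dims, 3, msub)),
                   romtConfig(sigma = 0, beta = 500, nSubsteps = msub))
  expect_equal(unname(e0["total"]), 500 * sum((rho0 - rho1)^2),
               tolerance = 1e-10)

  # stored velocity: direct re-summation over the stored trajectory
  set.seed(33)
  V <- array(rnorm(prod(dims) * 3 * msub, 0, 0.2), c(dims, 3, msub))
  e <- romtEnergy(rho0, rho1, V, cfg)
  traj <- forwardSolve(rho0, V, cfg)
  kinOracle <- 0
  for (k in seq_len(msub)) {
    spd2 <- V[, , , 1, k]^2 + V[, , , 2, k]^2 + V[, , , 3, k]^2
    kinOracle <- kinOracle + sum(traj[, , , k] * spd2)
  }
  kinOracle <- kinOracle * msub
  misOracle <- 500 * sum((traj[, , , msub + 1] - rho1)^2)
  expect_equal(unname(e["kinetic"]), kinOracle, tolerance = 1e-10)
  expect_equal(unname(e["mismatch"]), misOracle, tolerance = 1e-10)
  expect_equal(unname(e["total"]), kinOracle + misOracle, tolerance = 1e-10)
})

test_that("adjoint gradient matches central finite differences", {
  set.seed(42)
  dims <- c(6L, 6L, 6L); n <- prod(dims)
  rho0 <- array(runif(n, 0.1, 1), dims)
  rho1 <- array(runif(n, 0.1, 1), dims)
  msub <- 3L; sigma <- 0.01; beta <- 100
  V <- array(rnorm(3 * n * msub, 0, 0.2), c(dims, 3, msub))
  mask <- rep(TRUE, n)
  eg <- glymphflow:::.cppEnergyGrad(rho0, rho1, V, dims, msub, sigma, beta,
                                    mask, TRUE, 1e-12, 2000)
  h <- 1e-5
  for (k in 1:3) {
    dir <- rnorm(length(eg$gradient))
    dir <- dir / sqrt(sum(dir^2))
    dV <- array(dir, dim(V))
    Ep <- glymphflow:::.cppEnergyGrad(rho0, rho1, V + h * dV, dims, msub,
                                      sigma, beta, mask, FALSE, 1e-12, 2000)$total
    Em <- glymphflow:::.cppEnergyGrad(rho0, rho1, V - h * dV, dims, msub,
                                      sigma, beta, mask, FALSE, 1e-12, 2000)$total
    fd <- (Ep - Em) / (2 * h)
    expect_equal(sum(eg$gradient * dir), fd, tolerance = 1e-4)
  }
})

test_that("solving identical frames returns (near) zero velocity immediately", {
  rho <- gaussBlob(12, c(6, 6, 6), 1.5) + 1e-4
  sol <- solvePair(rho, rho, romtConfig(sigma = 0, nSubsteps = 4L))
  expect_lt(mean(abs(sol@velocity@data)), 1e-3)
  expect_equal(unname(sol@energy["total"]), 0, tolerance = 1e-12)
})

test_that("the solver descends: accepted energies never increase", {
  rho0 <- gaussBlob(12, c(5, 6, 6), 1.5) + 1e-4
  rho1 <- gaussBlob(12, c(7, 6, 6), 1.5) + 1e-4
  sol <- solvePair(rho0, rho1, romtConfig(maxOuterIterations = 8L,
                                          gnCgMaxit = 10L))
  e <- energyLog(sol)$total
  expect_true(all(diff(e) <= 1e-12 * abs(e[-length(e)])))
  # final energy is no worse than the v = 0 start
  expect_lte(e[length(e)], e[1])
  # and the solve is deterministic: identical inputs, identical outputs
  sol2 <- solvePair(rho0, rho1, romtConfig(maxOuterIterations = 8L,
                                           gnCgMaxit = 10L))
  expect_identical(sol@velocity@data, sol2@velocity@data)
})

test_that("kinetic energy approaches the W2 limit as sigma -> 0, beta -> infinity", {
  # translated Gaussians: the squared Wasserstein-2 distance is mass * |d|^2
  rho0 <- gaussBlob(16, c(6.5, 8, 8), 1.6)
  rho1 <- gaussBlob(16, c(8.5, 8, 8), 1.6)
  target <- sum(rho0) * 4                        # d = 2 voxels
  settings <- list(c(sigma = 0.02, beta = 3e2),
                   c(sigma = 0.005, beta = 3e3),
                   c(sigma = 1e-4, beta = 3e4))
  err <- vapply(settings, function(s) {
    sol <- solvePair(rho0, rho1,
                     romtConfig(sigma = s["sigma"], beta = s["beta"],
                                nSubsteps = 4L, maxOuterIterations = 25L,
                                gnCgMaxit = 20L, convergenceTol = 1e-6))
    abs(unname(sol@energy["kinetic"]) - target) / target
  }, numeric(1))
  # monotone trend toward the analytic value over the three settings
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_lt(err[3], 0.15)
})

test_that("solveSeries returns one solution per adjacent pair", {
  dims <- c(10L, 10L, 10L)
  mk <- function(frames) {
    f <- array(unlist(frames), c(dims, length(frames)))
    new("PercentChangeSeries", frames = f,
        frameTimes = seq_along(frames) * 300 - 300,
        baselineIndices = integer(), units = "percent",
        grid = imageGrid3D(dims, 0.3))
  }
  blob <- gaussBlob(10, c(5, 5, 5), 1.3)
  # three identical frames: two near-zero solutions
  s3 <- solveSeries(mk(list(blob, blob, blob)),
                    romtConfig(nSubsteps = 2L, maxOuterIterations = 5L))
  expect_length(s3, 2L)
  for (s in s3) expect_lt(mean(abs(s@velocity@data)), 1e-3)

  # five frames: four solutions, each carrying its frame times
  s5 <- solveSeries(mk(replicate(5, blob, simplify = FALSE)),
                    romtConfig(nSubsteps = 2L, maxOuterIterations = 2L))
  expect_length(s5, 4L)
  expect_equal(s5[[3]]@frameTimes, c(600, 900))

  # piecewise motion: translation in interval 1, static in interval 2
  b2 <- gaussBlob(10, c(6.5, 5, 5), 1.3)
  cfg <- romtConfig(nSubsteps = 4L, maxOuterIterations = 15L, gnCgMaxit = 15L)
  sp <- solveSeries(mk(list(blob + 1e-4, b2 + 1e-4, b2 + 1e-4)), cfg)
  disp1 <- mean(abs(sp[[1]]@velocity@data)) * 4
  disp2 <- mean(abs(sp[[2]]@velocity@data)) * 4
  expect_gt(disp1, 10 * max(disp2, 1e-6))
})
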
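#' @include AllGenerics.R
NULL

#' rOMT solver configuration
#'
#' The regularized optimal mass transport model transports the first frame
#' of each adjacent pair onto the second through \code{nSubsteps} advection-
#' diffusion substeps, minimizing
#' \deqn{E(v) = m \sum_k \sum_i \rho_k(i) |v_k(i)|^2 +
#'       \beta \sum_i (\rho_m(i) - \rho_1(i))^2}
#' over the per-substep velocity \code{v} (voxel units; the kinetic term is
#' scaled so a pure translation by d has energy mass * |d|^2, the squared
#' Wasserstein-2 distance).
#'
#' @param sigma diffusion coefficient of the transport constraint,
#'   voxel^2 per substep (default 0.002).
#' @param beta endpoint-mismatch weight (default 1e4).
#' @param nSubsteps substeps m per frame pair (default 8).
#' @param maxOuterIterations Gauss-Newton outer iteration budget (default 30).
#' @param cgTol,cgMaxit inner conjugate-gradient tolerance and iteration cap
#'   for the implicit diffusion solve.
#' @param gnCgTol,gnCgMaxit relative tolerance and iteration cap of the
#'   conjugate-gradient solve of the Gauss-Newton normal equations
#'   (matrix-free, via the sensitivity/adjoint recursion through the
#'   substeps).
#' @param gnDamping Levenberg-style diagonal damping added to the
#'   Gauss-Newton operator, keeping it positive definite where the density
#'   vanishes.
#' @param lineSearchContraction,lineSearchMaxTrials Armijo backtracking
#'   parameters.
#' @param convergenceTol stop when the relative energy decrease of an
#'   accepted iteration falls below this.
#' @return a validated list of class \code{"RomtConfig"}.
#' @export
romtConfig <- function(sigma = 0.002, beta = 1e4, nSubsteps = 8L,
                       maxOuterIterations = 30L, cgTol = 1e-8, cgMaxit = 200L,
                       gnCgTol = 0.1, gnCgMaxit = 30L, gnDamping = 1e-6,
                       lineSearchContraction = 0.5, lineSearchMaxTrials = 10L,
                       convergenceTol = 1e-4) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (nSubsteps < 1L) stop("nSubsteps must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, beta = beta, nSubsteps = as.integer(nSubsteps),
                 maxOuterIterations = as.integer(maxOuterIterations),
                 cgTol = cgTol, cgMaxit = as.integer(cgMaxit),
                 gnCgTol = gnCgTol, gnCgMaxit = as.integer(gnCgMaxit),
                 gnDamping = gnDamping,
                 lineSearchContraction = lineSearchContraction,
                 lineSearchMaxTrials = as.integer(lineSearchMaxTrials),
                 convergenceTol = convergenceTol),
            class = "RomtConfig")
}

checkVelocityArg <- function(v, dims, msub) {
  v <- as.array(v)
  if (length(v) != prod(dims) * 3 * msub)
    stop("velocity array has wrong length for grid/substeps", call. = FALSE)
  if (any(!is.finite(v))) stop("velocity must be finite", call. = FALSE)
  v
}

#' One advection-diffusion substep
#'
#' Operator splitting: (1) mass-preserving push-forward advection — each
#' voxel's mass is deposited at its displaced position via trilinear
#' weights, with displaced positions clamped inside the domain; (2) implicit
#' diffusion \code{(I - sigma L) rho' = rho_adv} with L the 7-point Neumann
#' Laplacian, solved by conjugate gradient.
#'
#' @param rho 3D nonnegative density array.
#' @param v velocity for this substep: array (x, y, z, 3) in voxels/substep.
#' @param config a \code{\link{romtConfig}}.
#' @return the advected-diffused density (same dims).
#' @examples
#' rho <- array(0, c(8, 8, 8)); rho[4, 4, 4] <- 1
#' v <- array(0, c(8, 8, 8, 3)); v[, , , 1] <- 1
#' out <- advectDiffuseStep(rho, v, romtConfig(sigma = 0))
#' which(out == 1)  # impulse moved one voxel in x
#' @export
advectDiffuseStep <- function(rho, v, config = romtConfig()) {
  dims <- dim(rho)
  stopifnot(length(dims) == 3L, min(rho) >= 0)
  v <- checkVelocityArg(v, dims, 1L)
  adv <- .cppAdvect(rho, v, dims)
  if (config$sigma == 0) return(adv)
  sol <- .cppDiffuseCG(adv, dims, config$sigma, config$cgTol, config$cgMaxit)
  if (sol$residual > config$cgTol * 100)
    stop(sprintf("diffusion CG did not converge (relative residual %.3e)",
                 sol$residual), call. = FALSE)
  sol$x
}

#' Forward advection-diffusion trajectory
#'
#' Applies \code{\link{advectDiffuseStep}} once per substep and returns all
#' intermediate densities. Total mass is conserved to near machine precision
#' when no mass is clamped at the domain boundary.
#'
#' @param rho0 initial 3D density.
#' @param velocity a \linkS4class{VelocityField} or a raw (x, y, z, 3, m)
#'   array in voxels/substep.
#' @param config a \code{\link{romtConfig}} (its \code{nSubsteps} must match
#'   the velocity's substep count when a raw array is given).
#' @return 4D array (x, y, z, substep + 1).
#' @export
forwardSolve <- function(rho0, velocity, config = romtConfig()) {
  dims <- dim(rho0)
  V <- if (is(velocity, "VelocityField")) velocity@data else velocity
  msub <- dim(V)[5]
  V <- checkVelocityArg(V, dims, msub)
  traj <- .cppForward(rho0, V, dims, msub, config$sigma, config$cgTol,
                      config$cgMaxit)
  array(traj, c(dims, msub + 1L))
}

#' rOMT energy of a candidate velocity
#'
#' @param rho0,rho1 the two nonnegative frames.
#' @param velocity a \linkS4class{VelocityField} or raw (x, y, z, 3, m)
#'   array, voxels/substep.
#' @param config a \code{\link{romtConfig}}.
#' @return named numeric: total, kinetic, mismatch.
#' @export
romtEnergy <- function(rho0, rho1, velocity, config = romtConfig()) {
  dims <- dim(rho0)
  V <- if (is(velocity, "VelocityField")) velocity@data else velocity
  msub <- dim(V)[5]
  V <- checkVelocityArg(V, dims, msub)
  mask <- rep(TRUE, prod(dims))
  r <- .cppEnergyGrad(rho0, rho1, V, dims, msub, config$sigma, config$beta,
                      mask, FALSE, config$cgTol, config$cgMaxit)
  c(total = r$total, kinetic = r$kinetic, mismatch = r$mismatch)
}

# Inexact CG solve of the Gauss-Newton normal equations H p = -g, with H
# applied matrix-free through the linearized forward/adjoint substep
# recursion. Truncated early (Steihaug-style) if negative curvature appears
# from round-off.
gnDirection <- function(g, hvp, tol, maxit) {
  p <- numeric(length(g))
  r <- -g
  d <- r
  rr <- sum(r^2)
  stop2 <- tol^2 * rr
  for (it in seq_len(maxit)) {
    Hd <- hvp(d)
    dHd <- sum(d * Hd)
    if (dHd <= 0) {
      if (it == 1L) p <- r                 # fall back to steepest descent
      break
    }
    alpha <- rr / dHd
    p <- p + alpha * d
    r <- r - alpha * Hd
    rrNew <- sum(r^2)
    if (rrNew <= stop2) break
    d <- r + (rrNew / rr) * d
    rr <- rrNew
  }
  p
}

#' Solve the rOMT problem for one frame pair
#'
#' Minimizes the rOMT energy over the per-substep velocity field by
#' Gauss-Newton: the gradient is obtained by an adjoint recursion backwards
#' through the m advection-diffusion substeps, the Gauss-Newton step by a
#' matrix-free conjugate-gradient solve whose operator products run the
#' linearized (sensitivity) recursion forwards and its adjoint backwards,
#' followed by Armijo backtracking, starting from v = 0. The
#' accepted-iteration energy log is non-increasing and the whole solve is
#' deterministic.
#'
#' @param rho0,rho1 nonnegative 3D arrays on the same grid (floored
#'   percent-change frames).
#' @param config a \code{\link{romtConfig}}.
#' @param grid optional \linkS4class{ImageGrid}; defaults to unit 0.3 mm
#'   voxels.
#' @param mask optional logical array; velocity is constrained to zero
#'   outside it (defaults to the grid's brain mask, else the whole domain).
#' @param frameTimes numeric(2), acquisition times (s) of the two frames;
#'   sets the physical time scale of the recovered velocity.
#' @return an \linkS4class{IntervalSolution}.
#' @export
solvePair <- function(rho0, rho1, config = romtConfig(), grid = NULL,
                      mask = NULL, frameTimes = c(0, 300)) {
  dims <- dim(rho0)
  stopifnot(identical(dims, dim(rho1)), length(dims) == 3L)
  if (min(rho0) < 0 || min(rho1) < 0)
    stop("frames must be nonnegative (apply floorDensity first)", call. = FALSE)
  if (is.null(grid)) grid <- imageGrid3D(dims, 0.3)
  if (is.null(mask))
    mask <- if ("brain" %in% names(grid@masks)) grid@masks$brain
            else array(TRUE, dims)
  msub <- config$nSubsteps
  n <- prod(dims)
  maskVec <- as.logical(mask)

  evalEG <- function(v, wantGrad = TRUE) {
    .cppEnergyGrad(rho0, rho1, v, dims, msub, config$sigma, config$beta,
                   maskVec, wantGrad, config$cgTol, config$cgMaxit)
  }

  v <- numeric(3 * n * msub)
  cur <- evalEG(v)
  if (!is.finite(cur$total)) stop("non-finite initial energy", call. = FALSE)
  g <- cur$gradient
  log <- data.frame(iter = 0L, total = cur$total, kinetic = cur$kinetic,
                    mismatch = cur$mismatch, step = NA_real_,
                    lineTrials = 0L)
  converged <- FALSE

  for (it in seq_len(config$maxOuterIterations)) {
    gnorm <- sqrt(sum(g^2))
    if (gnorm == 0) { converged <- TRUE; break }
    hvp <- function(dv)
      .cppGnHvp(cur$trajectory, v, dv, dims, msub, config$sigma, config$beta,
                maskVec, config$gnDamping, config$cgTol, config$cgMaxit)
    d <- gnDirection(g, hvp, config$gnCgTol, config$gnCgMaxit)
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- -gnorm^2 }        # safeguard
    alpha <- 1
    accepted <- FALSE
    trial <- NULL
    for (ls in seq_len(config$lineSearchMaxTrials)) {
      vNew <- v + alpha * d
      trial <- evalEG(vNew)
      if (is.finite(trial$total) &&
          trial$total <= cur$total + 1e-4 * alpha * gd) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * config$lineSearchContraction
    }
    if (!accepted) {
      if (it == 1L)
        warning("line search failed at first iteration; returning v = 0")
      break
    }
    relDecrease <- (cur$total - trial$total) / max(abs(cur$total), 1e-300)
    v <- vNew
    cur <- trial
    g <- cur$gradient
    log <- rbind(log, data.frame(iter = it, total = cur$total,
                                 kinetic = cur$kinetic,
                                 mismatch = cur$mismatch, step = alpha,
                                 lineTrials = ls))
    if (relDecrease < config$convergenceTol) { converged <- TRUE; break }
  }

  interval <- diff(frameTimes)
  vf <- new("VelocityField",
            data = array(v, c(dims, 3L, msub)),
            grid = grid, frameInterval = interval, nSubsteps = msub)
  traj <- array(cur$trajectory, c(dims, msub + 1L))
  traj[traj < 0] <- 0                       # CG round-off
  new("IntervalSolution", velocity = vf, trajectory = traj,
      energy = c(total = cur$total, kinetic = cur$kinetic,
                 mismatch = cur$mismatch),
      iterations = log,
      config = c(unclass(config), list(converged = converged)),
      frameTimes = as.numeric(frameTimes))
}

#' Solve the rOMT problem for every adjacent frame pair
#'
#' Runs \code{\link{solvePair}} independently between each pair of adjacent
#' frames of a preprocessed percent-change series, yielding one
#' \linkS4class{IntervalSolution} per pair (F - 1 in total). Frames are
#' floored to positive density first if needed.
#'
#' @param pc a \linkS4class{PercentChangeSeries} (ideally from
#'   \code{\link{preprocessSeries}}).
#' @param config a \code{\link{romtConfig}}.
#' @param mask optional logical array constraining the velocity.
#' @param verbose print per-pair energy summaries.
#' @return list of \linkS4class{IntervalSolution}.
#' @export
solveSeries <- function(pc, config = romtConfig(), mask = NULL,
                        verbose = FALSE) {
  stopifnot(is(pc, "PercentChangeSeries"))
  nf <- dim(pc@frames)[4]
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  if (min(pc@frames) < 0) pc <- floorDensity(pc)
  sols <- vector("list", nf - 1L)
  for (k in seq_len(nf - 1L)) {
    sols[[k]] <- solvePair(pc@frames[, , , k], pc@frames[, , , k + 1L],
                           config = config, grid = pc@grid, mask = mask,
                           frameTimes = pc@frameTimes[k + 0:1])
    if (verbose)
      message(sprintf("pair %d/%d: energy %.4g after %d iterations", k,
                      nf - 1L, sols[[k]]@energy["total"],
                      nrow(sols[[k]]@iterations) - 1L))
  }
  sols
}
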
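#' @include AllGenerics.R
NULL

#' Specify a transport phantom
#'
#' Defines the ground-truthed synthetic phantom used to validate every stage
#' of the pipeline: a Gaussian tracer bolus transported by a known velocity
#' field with diffusion on a 3D grid, imaged at a fixed frame interval. The
#' defaults mirror the acquisition the pipeline targets: 32^3 grid of 0.3 mm
#' isotropic voxels, 5 post-contrast frames at a 300 s interval.
#'
#' @param gridDims integer(3), voxels per axis (>= 8 each).
#' @param voxelSize isotropic voxel size, mm.
#' @param frameInterval seconds between frames.
#' @param nFrames number of post-contrast frames (>= 3).
#' @param velocityKind one of "constant", "rotation", "smooth_random", "zero".
#' @param velocityMagnitude mm displaced per frame interval ("constant" sets
#'   |v| everywhere; "smooth_random" sets the RMS magnitude).
#' @param velocityAxis direction of the constant velocity (normalized).
#' @param omega angular speed for "rotation", rad/s.
#' @param rotationAxis,rotationCenter axis (unit vector) and center (mm) of
#'   the rotation; center defaults to the grid center.
#' @param sigmaTrue diffusion coefficient, mm^2/s. Default 2e-4 is of the
#'   order of the free diffusivity of a small gadolinium chelate in tissue.
#' @param bolusCenter initial Gaussian bolus center, mm; default places it
#'   upstream of the grid center along the velocity axis so the advected
#'   tracer stays interior.
#' @param bolusWidth Gaussian standard deviation, mm.
#' @param bolusAmplitude peak amplitude in percent-signal-change units.
#' @param source optional infusion inlet: list(center mm, radius mm,
#'   rate percent-units/s), emulating continuous intrathecal infusion.
#' @param contrast optional planted regional contrast: list(center mm,
#'   radius mm, factor) multiplying the velocity inside a sphere.
#' @param noiseSd additive Gaussian noise, percent-change units, per voxel
#'   per frame.
#' @param nBaseline number of pre-contrast baseline frames emitted when
#'   simulating in raw-signal units.
#' @param baselineSignal raw-signal baseline level (signal units; 100 makes
#'   percent change numerically equal to the tracer density).
#' @param seed integer seed making the phantom reproducible.
#' @return a validated list of class \code{"PhantomSpec"}.
#' @examples
#' spec <- phantomSpec(gridDims = c(16, 16, 16), nFrames = 3)
#' @export
phantomSpec <- function(gridDims = c(32L, 32L, 32L), voxelSize = 0.3,
                        frameInterval = 300, nFrames = 5L,
                        velocityKind = c("constant", "rotation",
                                         "smooth_random", "zero"),
                        velocityMagnitude = 1.2,
                        velocityAxis = c(1, 0, 0),
                        omega = 0.01, rotationAxis = c(0, 0, 1),
                        rotationCenter = NULL,
                        sigmaTrue = 2e-4,
                        bolusCenter = NULL, bolusWidth = 0.9,
                        bolusAmplitude = 30,
                        source = NULL, contrast = NULL,
                        noiseSd = 1.0, nBaseline = 3L, baselineSignal = 100,
                        seed = 1L) {
  velocityKind <- match.arg(velocityKind)
  gridDims <- as.integer(gridDims)
  if (length(gridDims) != 3L || any(gridDims < 8L))
    stop("gridDims must be three integers >= 8", call. = FALSE)
  if (nFrames < 3L) stop("nFrames must be >= 3", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  if (bolusAmplitude < 0) stop("bolusAmplitude must be >= 0", call. = FALSE)
  if (sigmaTrue < 0) stop("sigmaTrue must be >= 0", call. = FALSE)
  extent <- gridDims * voxelSize
  if (is.null(rotationCenter)) rotationCenter <- extent / 2
  if (is.null(bolusCenter)) {
    # upstream placement: back off from the center along the flow direction
    # by half the total ground-truth travel, clipped to stay well inside
    travel <- velocityMagnitude * (nFrames - 1)
    ax <- velocityAxis / sqrt(sum(velocityAxis^2))
    bolusCenter <- extent / 2 - ax * min(travel / 2, extent[1] / 4)
  }
  spec <- list(gridDims = gridDims, voxelSize = voxelSize,
               frameInterval = frameInterval, nFrames = as.integer(nFrames),
               velocityKind = velocityKind,
               velocityMagnitude = velocityMagnitude,
               velocityAxis = velocityAxis / sqrt(sum(velocityAxis^2)),
               omega = omega, rotationAxis = rotationAxis,
               rotationCenter = rotationCenter,
               sigmaTrue = sigmaTrue, bolusCenter = bolusCenter,
               bolusWidth = bolusWidth, bolusAmplitude = bolusAmplitude,
               source = source, contrast = contrast, noiseSd = noiseSd,
               nBaseline = as.integer(nBaseline),
               baselineSignal = baselineSignal, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

phantomGrid <- function(spec) {
  imageGrid3D(spec$gridDims, spec$voxelSize)
}

# analytic bolus density (percent-change units) at physical positions (mm)
bolusDensity <- function(spec, pos) {
  d2 <- rowSums(sweep(pos, 2, spec$bolusCenter, "-")^2)
  spec$bolusAmplitude * exp(-d2 / (2 * spec$bolusWidth^2))
}

#' Build the ground-truth velocity field of a phantom
#'
#' Evaluates the phantom's velocity model at voxel centers (mm/s) and packs
#' it, with its analytic closure and derived summaries, into a
#' \linkS4class{GroundTruth}. Kinds: \code{"zero"} (no flow),
#' \code{"constant"} (identical vector everywhere), \code{"rotation"}
#' (rigid rotation \code{omega x r} about the stated axis), and
#' \code{"smooth_random"} (band-limited Gaussian-filtered white noise with
#' the stated RMS magnitude). An optional \code{contrast} region multiplies
#' the field inside a sphere, planting a regional speed difference.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeVelocityField(phantomSpec(velocityKind = "zero"))
#' gt@expectedMeanSpeed   # 0
#' @export
makeVelocityField <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- phantomGrid(spec)
  baseFun <- switch(spec$velocityKind,
    zero = function(pos) matrix(0, nrow(pos), 3L),
    constant = {
      vmm <- spec$velocityMagnitude / spec$frameInterval  # mm/s
      function(pos) matrix(vmm * spec$velocityAxis, nrow(pos), 3L, byrow = TRUE)
    },
    rotation = {
      w <- spec$omega * spec$rotationAxis / sqrt(sum(spec$rotationAxis^2))
      ctr <- spec$rotationCenter
      function(pos) {
        r <- sweep(pos, 2, ctr, "-")
        cbind(w[2] * r[, 3] - w[3] * r[, 2],
              w[3] * r[, 1] - w[1] * r[, 3],
              w[1] * r[, 2] - w[2] * r[, 1])
      }
    },
    smooth_random = {
      # band-limited lattice field, trilinearly interpolated off-lattice
      set.seed(spec$seed + 104729L)
      n <- prod(spec$gridDims)
      comp <- lapply(1:3, function(i) {
        w <- array(rnorm(n), spec$gridDims)
        .cppGaussSmooth(w, spec$gridDims, rep(2.0, 3))
      })
      rms <- sqrt(mean(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2))
      vrms <- spec$velocityMagnitude / spec$frameInterval
      comp <- lapply(comp, function(v) v * vrms / rms)
      V <- c(comp[[1]], comp[[2]], comp[[3]])
      dims <- spec$gridDims
      vs <- spec$voxelSize
      function(pos) {
        vox <- pos / vs - 0.5
        interpVelocityLattice(V, dims, vox)
      }
    },
    stop("unknown velocity kind '", spec$velocityKind, "'", call. = FALSE))
  velFun <- if (is.null(spec$contrast)) baseFun else {
    ctr <- spec$contrast$center; rad <- spec$contrast$radius
    fac <- spec$contrast$factor
    edge <- spec$contrast$edge                 # mm; 0/NULL = hard boundary
    function(pos) {
      v <- baseFun(pos)
      r <- sqrt(rowSums(sweep(pos, 2, ctr, "-")^2))
      s <- as.numeric(r <= rad)
      if (!is.null(edge) && edge > 0) {
        out <- r > rad
        s[out] <- exp(-(r[out] - rad)^2 / (2 * edge^2))
      }
      v * (1 + (fac - 1) * s)
    }
  }
  centers <- as.matrix(expand.grid(x = seq_len(spec$gridDims[1]) - 0.5,
                                   y = seq_len(spec$gridDims[2]) - 0.5,
                                   z = seq_len(spec$gridDims[3]) - 0.5)) *
    spec$voxelSize
  vtab <- velFun(centers)
  vel <- array(vtab, c(spec$gridDims, 3L))
  occupied <- bolusDensity(spec, centers) > 0.01 * spec$bolusAmplitude
  spd <- sqrt(rowSums(vtab^2))
  new("GroundTruth", velocityTrue = vel, velocityFun = velFun,
      sigmaTrue = spec$sigmaTrue,
      expectedMeanSpeed = mean(spd[occupied]) * 1e3,
      displacementTrue = vel * spec$frameInterval, grid = grid)
}

# trilinear interpolation of a lattice vector field at fractional voxel coords
interpVelocityLattice <- function(V, dims, vox) {
  out <- matrix(0, nrow(vox), 3L)
  n <- prod(dims)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), dims[a] - 1)
  i0 <- pmin(floor(vox[, 1]), dims[1] - 2); fx <- vox[, 1] - i0
  j0 <- pmin(floor(vox[, 2]), dims[2] - 2); fy <- vox[, 2] - j0
  k0 <- pmin(floor(vox[, 3]), dims[3] - 2); fz <- vox[, 3] - k0
  for (c in 0:1) for (b in 0:1) for (a in 0:1) {
    w <- (if (a) fx else 1 - fx) * (if (b) fy else 1 - fy) *
         (if (c) fz else 1 - fz)
    idx <- (i0 + a) + dims[1] * ((j0 + b) + dims[2] * (k0 + c)) + 1
    out[, 1] <- out[, 1] + w * V[idx]
    out[, 2] <- out[, 2] + w * V[n + idx]
    out[, 3] <- out[, 3] + w * V[2 * n + idx]
  }
  out
}

#' Simulate a tracer image series from a phantom
#'
#' Integrates the advection-diffusion transport equation
#' \eqn{\partial\rho/\partial t + \nabla\cdot(\rho v) = \sigma\Delta\rho}
#' with zero-flux boundaries on a refined grid (2x spatial, at least 4x
#' temporal with CFL-limited explicit substeps) using a flux-form upwind
#' scheme, then downsamples to the phantom resolution by mean pooling. This
#' integrator is deliberately independent of the rOMT solver's forward
#' operator, so parameter-recovery tests cannot be self-fulfilling.
#'
#' Output units: with \code{units = "signal"} (default) the series carries
#' \code{nBaseline} pre-contrast frames at \code{baselineSignal} followed by
#' post-contrast frames \code{baselineSignal * (1 + rho/100)}; with
#' \code{units = "percent"} the tracer density is returned directly. Additive
#' Gaussian noise (percent-change units) is applied per voxel per frame.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param truth the matching \code{\link{makeVelocityField}} output.
#' @param units "signal" or "percent".
#' @return a \linkS4class{DCESeries} (grid carries a whole-domain
#'   \code{brain} mask).
#' @examples
#' spec <- phantomSpec(gridDims = c(12, 12, 12), nFrames = 3, noiseSd = 0,
#'                     velocityKind = "zero", sigmaTrue = 0)
#' ser <- simulateTracerSeries(spec, makeVelocityField(spec))
#' @export
simulateTracerSeries <- function(spec, truth, units = c("signal", "percent")) {
  stopifnot(inherits(spec, "PhantomSpec"), is(truth, "GroundTruth"))
  units <- match.arg(units)
  rd <- spec$gridDims * 2L                  # refined dims
  dx <- spec$voxelSize / 2
  # refined-lattice voxel centers, mm
  cx <- (seq_len(rd[1]) - 0.5) * dx
  cy <- (seq_len(rd[2]) - 0.5) * dx
  cz <- (seq_len(rd[3]) - 0.5) * dx

  faceV <- function(xs, ys, zs, comp) {
    g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    truth@velocityFun(g)[, comp]
  }
  xf <- (0:rd[1]) * dx                       # x-face planes
  yf <- (0:rd[2]) * dx
  zf <- (0:rd[3]) * dx
  vxf <- faceV(xf, cy, cz, 1L)
  vyf <- faceV(cx, yf, cz, 2L)
  vzf <- faceV(cx, cy, zf, 3L)

  vmax <- max(abs(vxf), abs(vyf), abs(vzf), 1e-30)
  # CFL: unsplit upwind + explicit diffusion, total Courant budget 0.4
  rate <- 3 * vmax / dx + 6 * spec$sigmaTrue / dx^2
  stepsPerFrame <- max(4L, as.integer(ceiling(spec$frameInterval * rate / 0.4)))
  if (stepsPerFrame > 2e5)
    stop("velocity/diffusion magnitude violates the CFL budget at refined ",
         "resolution (", stepsPerFrame, " substeps per frame needed); ",
         "reduce velocityMagnitude, sigmaTrue or frameInterval", call. = FALSE)
  dt <- spec$frameInterval / stepsPerFrame
  dnum <- spec$sigmaTrue * dt / dx^2

  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  rho <- array(bolusDensity(spec, centers), rd)
  if (spec$bolusAmplitude == 0 && is.null(spec$source))
    stop("phantom needs a bolus or a source", call. = FALSE)
  srcIdx <- NULL
  if (!is.null(spec$source)) {
    d2 <- rowSums(sweep(centers, 2, spec$source$center, "-")^2)
    srcIdx <- which(d2 <= spec$source$radius^2)
  }

  downsample <- function(v) {
    d <- spec$gridDims
    a <- array(v, c(2L, d[1], 2L, d[2], 2L, d[3]))
    out <- apply(a, c(2L, 4L, 6L), mean)
    array(out, d)
  }

  nf <- spec$nFrames
  framesPc <- array(0, c(spec$gridDims, nf))
  framesPc[, , , 1L] <- downsample(rho)
  cvx <- vxf * dt / dx; cvy <- vyf * dt / dx; cvz <- vzf * dt / dx
  for (k in 2:nf) {
    if (is.null(srcIdx)) {
      rho <- .cppUpwind(rho, cvx, cvy, cvz, rd, dnum, stepsPerFrame)
    } else {
      # apply the inlet in short bursts between transport substeps
      burst <- max(1L, stepsPerFrame %/% 20L)
      done <- 0L
      while (done < stepsPerFrame) {
        nstep <- min(burst, stepsPerFrame - done)
        rho <- .cppUpwind(rho, cvx, cvy, cvz, rd, dnum, nstep)
        rho[srcIdx] <- rho[srcIdx] + spec$source$rate * dt * nstep
        done <- done + nstep
      }
    }
    framesPc[, , , k] <- downsample(rho)
  }

  set.seed(spec$seed)
  grid <- phantomGrid(spec)
  grid@masks$brain <- array(TRUE, spec$gridDims)
  tInt <- spec$frameInterval
  if (units == "percent") {
    if (spec$noiseSd > 0)
      framesPc <- framesPc + array(rnorm(length(framesPc), 0, spec$noiseSd),
                                   dim(framesPc))
    new("PercentChangeSeries", frames = framesPc,
        frameTimes = (seq_len(nf) - 1) * tInt,
        baselineIndices = integer(), units = "percent", grid = grid,
        meta = list(spec = spec[setdiff(names(spec), "contrast")],
                    stepsPerFrame = stepsPerFrame))
  } else {
    nb <- spec$nBaseline
    sig <- array(spec$baselineSignal, c(spec$gridDims, nb + nf))
    sig[, , , nb + seq_len(nf)] <-
      spec$baselineSignal * (1 + framesPc / 100)
    if (spec$noiseSd > 0)
      sig <- sig + array(rnorm(length(sig), 0,
                               spec$noiseSd * spec$baselineSignal / 100),
                         dim(sig))
    new("DCESeries", frames = sig,
        frameTimes = c(-(nb:1), seq_len(nf) - 1) * tInt,
        baselineIndices = seq_len(nb), units = "signal", grid = grid,
        meta = list(stepsPerFrame = stepsPerFrame))
  }
}

#' Specify a synthetic ICP recording
#'
#' Defaults follow the physiology the analysis targets: intracranial
#' pressure sampled at 10 kHz containing a cardiac oscillation at 4.22 Hz
#' (253 beats/min) and a respiratory oscillation at 0.73 Hz (44 breaths/min).
#'
#' @param duration_s trace length, s.
#' @param samplingRate Hz (must exceed twice the cardiac frequency).
#' @param baseline mean ICP, mmHg.
#' @param cardiacFreq,cardiacAmp cardiac frequency (Hz) and sinusoid
#'   amplitude (mmHg).
#' @param respFreq,respAmp respiratory frequency (Hz) and amplitude (mmHg).
#' @param drift linear drift, mmHg/s.
#' @param noiseSd additive Gaussian noise, mmHg.
#' @param seed integer seed.
#' @return a validated list of class \code{"ICPSpec"}.
#' @export
icpSpec <- function(duration_s = 30, samplingRate = 10000, baseline = 5,
                    cardiacFreq = 4.22, cardiacAmp = 0.25,
                    respFreq = 0.73, respAmp = 0.4,
                    drift = 0, noiseSd = 0.02, seed = 1L) {
  if (cardiacFreq <= 0 || respFreq <= 0)
    stop("frequencies must be positive", call. = FALSE)
  if (samplingRate <= 2 * cardiacFreq)
    stop("samplingRate must exceed twice the cardiac frequency", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, samplingRate = samplingRate,
                 baseline = baseline, cardiacFreq = cardiacFreq,
                 cardiacAmp = cardiacAmp, respFreq = respFreq,
                 respAmp = respAmp, drift = drift, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "ICPSpec")
}

#' Generate a synthetic ICP waveform
#'
#' \eqn{p(t) = baseline + respAmp \sin(2\pi f_r t) + cardiacAmp
#' \sin(2\pi f_c t) + drift \cdot t + noise}; bitwise reproducible for a
#' fixed seed.
#'
#' @param spec an \code{\link{icpSpec}}.
#' @param epochs optional epoch annotation data.frame (label, start_s,
#'   end_s); defaults to one "baseline" epoch covering the trace.
#' @param subject subject id.
#' @return an \linkS4class{ICPRecording}.
#' @examples
#' rec <- makeIcpWaveform(icpSpec(duration_s = 5, samplingRate = 1000,
#'                                noiseSd = 0))
#' @export
makeIcpWaveform <- function(spec, epochs = NULL, subject = "synthetic") {
  stopifnot(inherits(spec, "ICPSpec"))
  n <- round(spec$duration_s * spec$samplingRate)
  t <- (seq_len(n) - 1) / spec$samplingRate
  p <- spec$baseline +
    spec$respAmp * sin(2 * pi * spec$respFreq * t) +
    spec$cardiacAmp * sin(2 * pi * spec$cardiacFreq * t) +
    spec$drift * t
  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    p <- p + rnorm(n, 0, spec$noiseSd)
  }
  if (is.null(epochs))
    epochs <- data.frame(label = "baseline", start_s = 0,
                         end_s = spec$duration_s)
  new("ICPRecording", samples = p, samplingRate = spec$samplingRate,
      epochs = epochs, subject = subject)
}

#' Generate a gamma-variate lymph-node uptake curve
#'
#' \eqn{y(t) = A \tau^\alpha e^{\alpha(1-\tau)}} with
#' \eqn{\tau = (t - t_0)/(t_{peak} - t_0)} for \eqn{t > t_0}, else 0 — the
#' standard tracer-bolus uptake shape, peaking at exactly \code{tPeak} with
#' value \code{amplitude}. Emulates deep cervical lymph-node drainage
#' kinetics (peak near 87 min in the target system).
#'
#' @param times sample times, minutes.
#' @param t0 uptake onset, minutes.
#' @param tPeak peak time, minutes (> t0).
#' @param alpha gamma-variate shape (> 0).
#' @param amplitude peak value, AU.
#' @param noiseSd additive Gaussian noise, AU.
#' @param seed integer seed.
#' @param node,side labels for the returned curve.
#' @return a \linkS4class{TSC}.
#' @examples
#' tsc <- makeTsc(seq(0, 180, by = 5), t0 = 10, tPeak = 87, alpha = 3,
#'                amplitude = 0.11, noiseSd = 0)
#' @export
makeTsc <- function(times, t0 = 10, tPeak = 87, alpha = 3, amplitude = 0.11,
                    noiseSd = 0, seed = 1L, node = "dcLN", side = "left") {
  if (tPeak <= t0) stop("tPeak must exceed t0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  tau <- pmax(times - t0, 0) / (tPeak - t0)
  y <- amplitude * tau^alpha * exp(alpha * (1 - tau))
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noiseSd)
  }
  new("TSC", times = as.numeric(times), values = y, node = node, side = side,
      normalized = TRUE)
}
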
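test_that("velocity field kinds produce the stated geometry", {
  # zero: all vectors vanish
  gtZero <- makeVelocityField(tinySpec(velocityKind = "zero"))
  expect_true(all(gtZero@velocityTrue == 0))
  expect_identical(gtZero@expectedMeanSpeed, 0)

  # constant: 1.2 mm per 300 s interval is 4 um/s everywhere
  gtConst <- makeVelocityField(phantomSpec(velocityMagnitude = 1.2,
                                           frameInterval = 300))
  spd <- sqrt(apply(gtConst@velocityTrue^2, 1:3, sum)) * 1e3
  expect_equal(range(spd), c(4, 4), tolerance = 1e-12)
  expect_equal(gtConst@expectedMeanSpeed, 4, tolerance = 1e-12)

  # rotation: |v| = omega * r; a point at radius 2 mm moves at 20 um/s
  spec <- phantomSpec(velocityKind = "rotation", omega = 0.01)
  gtRot <- makeVelocityField(spec)
  p <- matrix(spec$rotationCenter + c(2, 0, 0), 1)
  expect_equal(sqrt(sum(gtRot@velocityFun(p)^2)) * 1e3, 20,
               tolerance = 1e-10)

  # smooth_random: stated RMS magnitude, reproducible for a fixed seed
  spec2 <- tinySpec(velocityKind = "smooth_random", velocityMagnitude = 0.9)
  gtR1 <- makeVelocityField(spec2)
  gtR2 <- makeVelocityField(spec2)
  expect_identical(gtR1@velocityTrue, gtR2@velocityTrue)
  rms <- sqrt(mean(apply(gtR1@velocityTrue^2, 1:3, sum)))
  expect_equal(rms, 0.9 / 300, tolerance = 1e-9)

  expect_error(phantomSpec(velocityKind = "spiral"))
})

test_that("identity dynamics: zero velocity and zero diffusion freeze the bolus", {
  spec <- tinySpec(velocityKind = "zero", sigmaTrue = 0)
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  f <- frames(ser)
  expect_equal(f[, , , 2], f[, , , 1], tolerance = 1e-12)
  expect_equal(f[, , , 3], f[, , , 1], tolerance = 1e-12)
})

test_that("pure diffusion matches the analytic heat kernel within 2% L2", {
  w0 <- 0.9; sig <- 2e-4                      # mm, mm^2/s
  spec <- phantomSpec(gridDims = c(32L, 32L, 32L), velocityKind = "zero",
                      sigmaTrue = sig, bolusWidth = w0, nFrames = 3L,
                      noiseSd = 0, bolusCenter = rep(4.8, 3))
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  x <- (1:32 - 0.5) * 0.3
  for (k in 2:3) {
    t <- (k - 1) * 300
    wt2 <- w0^2 + 2 * sig * t                  # variance grows by 2 sigma t
    amp <- spec$bolusAmplitude * (w0^2 / wt2)^1.5
    r2 <- outer(outer((x - 4.8)^2, (x - 4.8)^2, "+"), (x - 4.8)^2, "+")
    ana <- amp * exp(-r2 / (2 * wt2))
    rel <- sqrt(sum((frames(ser)[, , , k] - ana)^2) / sum(ana^2))
    expect_lt(rel, 0.02)
  }
})

test_that("constant flow advects the bolus centroid by v t within 0.2 voxel per frame", {
  spec <- phantomSpec(velocityMagnitude = 1.2, sigmaTrue = 1e-5, noiseSd = 0,
                      nFrames = 4L)
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  c0 <- blobCentroid(frames(ser)[, , , 1])
  for (k in 2:4) {
    ck <- blobCentroid(frames(ser)[, , , k])
    expected <- c0 + c((k - 1) * 1.2 / 0.3, 0, 0)
    expect_lt(sqrt(sum((ck - expected)^2)), 0.2 * (k - 1))
  }
})

test_that("noise-free tracer mass is conserved to relative 1e-6", {
  spec <- tinySpec(velocityMagnitude = 0.9, sigmaTrue = 2e-4)
  ser <- simulateTracerSeries(spec, makeVelocityField(spec), units = "percent")
  m <- apply(frames(ser), 4, sum)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
})

test_that("centroid displacement is linear in velocity magnitude", {
  disp <- vapply(c(0.3, 0.6, 1.2), function(mag) {
    spec <- tinySpec(velocityMagnitude = mag, sigmaTrue = 0)
    ser <- simulateTracerSeries(spec, makeVelocityField(spec),
                                units = "percent")
    blobCentroid(frames(ser)[, , , 2])[1] -
      blobCentroid(frames(ser)[, , , 1])[1]
  }, numeric(1))
  expect_equal(disp[2] / disp[1], 2, tolerance = 0.02)
  expect_equal(disp[3] / disp[2], 2, tolerance = 0.02)
})

test_that("generators are bitwise reproducible for a fixed seed", {
  spec <- tinySpec(noiseSd = 1.5)
  s1 <- simulateTracerSeries(spec, makeVelocityField(spec))
  s2 <- simulateTracerSeries(spec, makeVelocityField(spec))
  expect_identical(frames(s1), frames(s2))

  r1 <- makeIcpWaveform(icpSpec(duration_s = 2, samplingRate = 500))
  r2 <- makeIcpWaveform(icpSpec(duration_s = 2, samplingRate = 500))
  expect_identical(r1@samples, r2@samples)

  t1 <- makeTsc(seq(0, 180, 5), noiseSd = 0.01, seed = 3L)
  t2 <- makeTsc(seq(0, 180, 5), noiseSd = 0.01, seed = 3L)
  expect_identical(t1@values, t2@values)
})

test_that("ICP waveform has the constructed composition", {
  # all amplitudes zero: constant trace at baseline
  flat <- makeIcpWaveform(icpSpec(duration_s = 2, samplingRate = 1000,
                                  cardiacAmp = 0, respAmp = 0, drift = 0,
                                  noiseSd = 0, baseline = 5))
  expect_equal(range(flat@samples), c(5, 5), tolerance = 1e-12)

  # a lone 0.25 mmHg cardiac sinusoid spans 0.5 mmHg peak to peak
  card <- makeIcpWaveform(icpSpec(duration_s = 5, samplingRate = 2000,
                                  cardiacAmp = 0.25, respAmp = 0,
                                  noiseSd = 0))
  expect_equal(diff(range(card@samples)), 0.5, tolerance = 1e-6)

  # composite, noise-free: spectral peaks at exactly f_r and f_c
  fs <- 1000; dur <- 50
  comp <- makeIcpWaveform(icpSpec(duration_s = dur, samplingRate = fs,
                                  cardiacFreq = 4.22, respFreq = 0.73,
                                  noiseSd = 0))
  sp <- Mod(fft(comp@samples - mean(comp@samples)))[1:(dur * fs / 2)]
  freqs <- (seq_along(sp) - 1) / dur
  pk <- order(sp, decreasing = TRUE)[1:4]     # leakage pairs
  expect_true(any(abs(freqs[pk] - 0.73) < 1 / dur + 1e-9))
  expect_true(any(abs(freqs[pk] - 4.22) < 1 / dur + 1e-9))

  expect_error(icpSpec(samplingRate = 5, cardiacFreq = 4))
})

test_that("gamma-variate uptake curve follows its closed form", {
  # alpha = 1, t0 = 0, tPeak = 1: y(t) = A t e^(1-t); y(2) = 2A/e
  A <- 0.13
  tsc <- makeTsc(c(0, 1, 2), t0 = 0, tPeak = 1, alpha = 1, amplitude = A)
  expect_equal(tsc@values, c(0, A, 2 * A / exp(1)), tolerance = 1e-12)

  # noise-free curve peaks at the grid time nearest tPeak
  times <- seq(0, 180, by = 5)
  tsc2 <- makeTsc(times, t0 = 10, tPeak = 87, alpha = 3, amplitude = 1)
  expect_equal(times[which.max(tsc2@values)],
               times[which.min(abs(times - 87))])

  # zero amplitude gives the zero curve
  expect_true(all(makeTsc(times, amplitude = 0)@values == 0))
  expect_error(makeTsc(times, t0 = 90, tPeak = 80))
})
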
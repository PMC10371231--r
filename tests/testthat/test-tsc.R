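neckSeries <- function(nodeCurve, csfCurve, dims = c(8L, 8L, 8L)) {
  nf <- length(nodeCurve)
  f <- array(0, c(dims, nf))
  nodeMask <- array(FALSE, dims); nodeMask[2:3, 2:3, 2] <- TRUE
  csfMask <- array(FALSE, dims); csfMask[6:7, 6:7, 6] <- TRUE
  for (k in seq_len(nf)) {
    fr <- f[, , , k]
    fr[nodeMask] <- nodeCurve[k]
    fr[csfMask] <- csfCurve[k]
    f[, , , k] <- fr
  }
  list(series = new("DCESeries", frames = f,
                    frameTimes = (seq_len(nf) - 1) * 300,
                    baselineIndices = integer(), units = "signal",
                    grid = imageGrid3D(dims, 0.2)),
       nodeMask = nodeMask, csfMask = csfMask)
}

test_that("extraction normalizes node curves by the CSF reference", {
  # node signal 90 against a CSF maximum of 1000 gives 0.09 AU
  fx <- neckSeries(nodeCurve = c(10, 90, 50), csfCurve = c(100, 1000, 400))
  tscs <- extractAndNormalize(fx$series, list(dcLN.left = fx$nodeMask),
                              fx$csfMask)
  expect_equal(tscs$dcLN.left@values, c(10, 90, 50) / 1000,
               tolerance = 1e-12)
  expect_equal(max(tscs$dcLN.left@values), 0.09, tolerance = 1e-12)
  expect_identical(tscs$dcLN.left@node, "dcLN")
  expect_identical(tscs$dcLN.left@side, "left")
  # CSF curve is returned raw
  expect_equal(tscs$CSF@values, c(100, 1000, 400), tolerance = 1e-12)
  # node volume is voxel count times voxel volume
  expect_equal(tscs$dcLN.left@volume, 4 * 0.2^3, tolerance = 1e-12)

  # a node identical to CSF normalizes to peak 1
  fx2 <- neckSeries(nodeCurve = c(1, 5, 3), csfCurve = c(1, 5, 3))
  t2 <- extractAndNormalize(fx2$series, list(dcLN = fx2$nodeMask),
                            fx2$csfMask)
  expect_equal(max(t2$dcLN@values), 1, tolerance = 1e-12)

  # a one-voxel VOI returns exactly that voxel's series
  one <- array(FALSE, c(8, 8, 8)); one[4, 4, 4] <- TRUE
  ser <- fx$series
  ser@frames[4, 4, 4, ] <- c(7, 11, 13)
  t3 <- extractAndNormalize(ser, list(probe = one), fx$csfMask)
  expect_equal(t3$probe@values * 1000, c(7, 11, 13), tolerance = 1e-12)

  expect_error(extractAndNormalize(fx$series,
                                   list(bad = array(FALSE, c(8, 8, 8))),
                                   fx$csfMask), "bad")
})

test_that("normalized metrics are invariant to global raw scaling", {
  fx <- neckSeries(nodeCurve = c(5, 40, 90, 60, 30),
                   csfCurve = c(50, 900, 1000, 700, 500))
  get <- function(scale) {
    ser <- fx$series
    ser@frames <- ser@frames * scale
    tscs <- extractAndNormalize(ser, list(dcLN = fx$nodeMask), fx$csfMask)
    tscMetrics(smoothTsc(tscs$dcLN))
  }
  m1 <- get(1); mk <- get(37.2)
  expect_equal(mk$peakMagnitude_au, m1$peakMagnitude_au, tolerance = 1e-10)
  expect_equal(mk$auc_au_min, m1$auc_au_min, tolerance = 1e-10)
  expect_equal(mk$timeToPeak_min, m1$timeToPeak_min)
})

test_that("the 2-step moving average matches brute force and lags one point", {
  t4 <- makeTsc(c(0, 5, 10, 15), t0 = 0, tPeak = 7, alpha = 2, amplitude = 1)
  t4@values <- c(0, 2, 4, 6)
  sm <- smoothTsc(t4)
  expect_equal(sm@values, c(1, 3, 5))
  expect_equal(sm@times, c(5, 10, 15))

  # constant curve stays constant, one point shorter
  tc <- t4; tc@values <- rep(3.3, 4)
  expect_equal(smoothTsc(tc)@values, rep(3.3, 3))

  # random curve equals brute-force pairwise means
  set.seed(4)
  tr <- makeTsc(seq(0, 180, 5), noiseSd = 0.05, seed = 4L)
  smr <- smoothTsc(tr)
  brute <- vapply(2:length(tr@values),
                  function(i) mean(tr@values[c(i - 1, i)]), numeric(1))
  expect_equal(smr@values, brute, tolerance = 1e-14)

  # smoothing never increases the maximum of a nonnegative curve
  expect_lte(max(smr@values), max(tr@values))

  one <- t4; one@times <- 0; one@values <- 1
  expect_error(smoothTsc(one), "2 points")
})

test_that("curve metrics read peak, time to peak and AUC correctly", {
  # noise-free gamma-variate peaking at 87 min on a 5-min grid
  times <- seq(0, 180, by = 5)
  tsc <- makeTsc(times, t0 = 10, tPeak = 87, alpha = 3, amplitude = 0.11)
  m <- tscMetrics(smoothTsc(tsc))
  expect_lte(abs(m$timeToPeak_min - 87), 5)      # within one frame interval

  # constant curve c over 180 min: AUC = 180 c, peak at the first point
  const <- makeTsc(times, amplitude = 0)
  const@values <- rep(0.4, length(times))
  mc <- tscMetrics(const)
  expect_equal(mc$auc_au_min, 180 * 0.4, tolerance = 1e-12)
  expect_equal(mc$timeToPeak_min, 0)

  # AUC is additive over contiguous sub-windows
  set.seed(6)
  noisy <- makeTsc(times, noiseSd = 0.02, seed = 6L)
  whole <- tscMetrics(noisy)$auc_au_min
  a <- tscMetrics(noisy, window = c(0, 90))$auc_au_min
  b <- tscMetrics(noisy, window = c(90, 180))$auc_au_min
  expect_equal(a + b, whole, tolerance = 1e-10)

  expect_error(tscMetrics(noisy, window = c(500, 600)), "empty")
})

test_that("time-to-peak is robust to 5% noise (median error within one frame)", {
  times <- seq(0, 180, by = 5)
  # the estimator's noise-free answer is the reference: deviations are then
  # attributable to noise alone
  clean <- tscMetrics(smoothTsc(makeTsc(times, t0 = 10, tPeak = 87,
                                        alpha = 3,
                                        amplitude = 0.11)))$timeToPeak_min
  errs <- vapply(1:20, function(s) {
    tsc <- makeTsc(times, t0 = 10, tPeak = 87, alpha = 3, amplitude = 0.11,
                   noiseSd = 0.05 * 0.11, seed = s)
    tscMetrics(smoothTsc(tsc))$timeToPeak_min - clean
  }, numeric(1))
  expect_lte(median(abs(errs)), 5)
})
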
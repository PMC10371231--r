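#' @include AllGenerics.R
NULL

#' ICP channel-splitting configuration
#'
#' @param respCutoff low-pass cutoff of the respiratory channel, Hz
#'   (default 2).
#' @param pulseCutoff high-pass cutoff of the pulse channel, Hz (default 5).
#' @param sgWindow Savitzky-Golay window length in samples (default 45, as
#'   applied to the raw waveform before the high-pass).
#' @param sgOrder Savitzky-Golay polynomial order (default 3).
#' @param filterOrder Butterworth order; both filters are applied
#'   forward-backward (zero phase) for amplitude fidelity.
#' @param promFrac trough prominence threshold for respiratory cycle
#'   delimitation, as a fraction of the channel RMS (default 0.5).
#' @param compensate divide measured pulse pressure by the analytic
#'   amplitude response of the Savitzky-Golay + high-pass cascade at the
#'   estimated cardiac fundamental. The high-pass cutoff sits above typical
#'   rodent heart rates (4.22 Hz at 253 beats/min), so the cascade
#'   attenuates the cardiac fundamental itself; the compensation restores
#'   the true cyclic amplitude and is recorded in provenance.
#' @return list of class \code{"IcpConfig"}.
#' @export
icpConfig <- function(respCutoff = 2, pulseCutoff = 5, sgWindow = 45L,
                      sgOrder = 3L, filterOrder = 4L, promFrac = 0.5,
                      compensate = TRUE) {
  structure(list(respCutoff = respCutoff, pulseCutoff = pulseCutoff,
                 sgWindow = as.integer(sgWindow), sgOrder = as.integer(sgOrder),
                 filterOrder = as.integer(filterOrder), promFrac = promFrac,
                 compensate = compensate),
            class = "IcpConfig")
}

# zero-phase Butterworth via signal::filtfilt, operating on the demeaned
# trace so the large DC offset does not excite boundary transients
zeroPhaseButter <- function(x, order, cutoffHz, fs, type) {
  bf <- signal::butter(order, cutoffHz / (fs / 2), type)
  mu <- if (type == "low") mean(x) else 0
  as.numeric(signal::filtfilt(bf, x - mean(x))) + (if (type == "low") mu else 0)
}

# amplitude response of the applied pulse cascade at frequency f (Hz):
# |H_sg(f)| * |H_butter(f)|^2 (forward-backward squares the magnitude)
pulseCascadeResponse <- function(f, fs, config) {
  w <- 2 * pi * f / fs
  sg <- signal::sgolay(p = config$sgOrder, n = config$sgWindow)
  cc <- sg[(config$sgWindow + 1) / 2, ]         # central FIR coefficients
  k <- seq_along(cc) - (config$sgWindow + 1) / 2
  hSg <- abs(sum(cc * cos(k * w)))               # symmetric FIR, real response
  bf <- signal::butter(config$filterOrder, config$pulseCutoff / (fs / 2), "high")
  z <- exp(1i * w)
  hB <- abs(sum(bf$b * z^(-(seq_along(bf$b) - 1))) /
            sum(bf$a * z^(-(seq_along(bf$a) - 1))))
  hSg * hB^2
}

#' Split an ICP recording into respiratory and pulse channels
#'
#' Respiratory channel: zero-phase low-pass at \code{respCutoff} (2 Hz).
#' Pulse channel: Savitzky-Golay smoothing (45 points, order 3) of the raw
#' waveform followed by a zero-phase high-pass at \code{pulseCutoff} (5 Hz).
#' Both channels have the length of the input and the whole operation is
#' deterministic.
#'
#' @param rec an \linkS4class{ICPRecording} with rate >= 20 Hz.
#' @param config an \code{\link{icpConfig}}.
#' @return an \linkS4class{ICPChannels}.
#' @export
splitChannels <- function(rec, config = icpConfig()) {
  stopifnot(is(rec, "ICPRecording"))
  fs <- rec@samplingRate
  if (fs < 20) stop("sampling rate must be >= 20 Hz", call. = FALSE)
  n <- length(rec@samples)
  if (n < 3 * max(config$sgWindow, round(fs / config$respCutoff)))
    stop("recording shorter than 3 filter windows", call. = FALSE)
  resp <- zeroPhaseButter(rec@samples, config$filterOrder, config$respCutoff,
                          fs, "low")
  sm <- as.numeric(signal::sgolayfilt(rec@samples, p = config$sgOrder,
                                      n = config$sgWindow))
  pulse <- zeroPhaseButter(sm, config$filterOrder, config$pulseCutoff,
                           fs, "high")
  new("ICPChannels", respiratory = resp, pulse = pulse, samplingRate = fs,
      config = unclass(config))
}

#' Decimate an ICP recording (anti-aliased)
#'
#' Optional speed-up before analysis; channel amplitudes at physiological
#' frequencies are unaffected well below the new Nyquist rate.
#'
#' @param rec an \linkS4class{ICPRecording}.
#' @param targetRate Hz (default 1000).
#' @return a decimated \linkS4class{ICPRecording}.
#' @export
icpDecimate <- function(rec, targetRate = 1000) {
  stopifnot(is(rec, "ICPRecording"))
  q <- rec@samplingRate / targetRate
  if (q <= 1) return(rec)
  if (abs(q - round(q)) > 1e-9)
    stop("sampling rate must be an integer multiple of targetRate", call. = FALSE)
  q <- as.integer(round(q))
  mu <- mean(rec@samples)
  anti <- zeroPhaseButter(rec@samples, 8L, 0.4 * targetRate,
                          rec@samplingRate, "low")
  new("ICPRecording", samples = anti[seq(1L, length(anti), by = q)],
      samplingRate = targetRate, epochs = rec@epochs, subject = rec@subject)
}

#' Per-cycle amplitude series of the ICP channels
#'
#' Respiratory cycles are delimited by troughs of the respiratory channel
#' (prominence at least \code{promFrac} of the channel RMS); the
#' respiratory delta is the max-min within each cycle. The pulse pressure
#' is the max-min of the pulse channel within consecutive windows of one
#' estimated cardiac period (dominant periodogram frequency above 3 Hz),
#' corrected for the filter cascade's amplitude response at that frequency
#' when \code{compensate} is set.
#'
#' @param channels an \linkS4class{ICPChannels}.
#' @return list of class \code{"IcpAmplitudes"}: \code{respCycles}
#'   (data.frame start_s, end_s, delta_mmHg), \code{pulseWindows}
#'   (data.frame t_s, pp_mmHg), \code{cardiacFreq_hz},
#'   \code{responseFactor}.
#' @export
cyclicAmplitudes <- function(channels) {
  stopifnot(is(channels, "ICPChannels"))
  fs <- channels@samplingRate
  cfg <- channels@config
  x <- channels@respiratory
  xc <- x - mean(x)
  rms <- sqrt(mean(xc^2))
  if (rms < 1e-12) {
    return(structure(list(
      respCycles = data.frame(start_s = numeric(), end_s = numeric(),
                              delta_mmHg = numeric()),
      pulseWindows = data.frame(t_s = numeric(), pp_mmHg = numeric()),
      cardiacFreq_hz = NA_real_, responseFactor = NA_real_,
      samplingRate = fs), class = "IcpAmplitudes"))
  }
  # candidate troughs: local minima of the (smooth) respiratory channel
  d <- diff(x)
  cand <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  if (length(cand) >= 2L) {
    # prominence: rise to the lower of the neighbouring segment maxima
    segMax <- vapply(seq_len(length(cand) - 1L), function(i)
      max(x[cand[i]:cand[i + 1L]]), numeric(1))
    lmax <- c(max(x[1:cand[1]]), segMax)
    rmax <- c(segMax, max(x[cand[length(cand)]:length(x)]))
    prom <- pmin(lmax, rmax) - x[cand]
    cand <- cand[prom >= cfg$promFrac * rms]
  }
  if (length(cand) < 2L)
    stop("no detectable respiratory cycles in the respiratory channel",
         call. = FALSE)
  respCycles <- data.frame(
    start_s = (cand[-length(cand)] - 1) / fs,
    end_s = (cand[-1] - 1) / fs,
    delta_mmHg = vapply(seq_len(length(cand) - 1L), function(i) {
      seg <- x[cand[i]:cand[i + 1L]]
      max(seg) - min(seg)
    }, numeric(1)))

  # cardiac fundamental: dominant periodogram peak above 3 Hz
  p <- channels@pulse - mean(channels@pulse)
  np <- length(p)
  spec <- Mod(fft(p)[seq_len(floor(np / 2))])^2
  freqs <- (seq_len(floor(np / 2)) - 1) * fs / np
  hi <- freqs > 3
  if (!any(hi) || max(spec[hi]) < 1e-20 * np)
    stop("no detectable cardiac oscillation in the pulse channel",
         call. = FALSE)
  fc <- freqs[hi][which.max(spec[hi])]
  fac <- if (isTRUE(cfg$compensate))
    pulseCascadeResponse(fc, fs, cfg) else 1
  win <- max(2L, as.integer(round(fs / fc)))
  starts <- seq(1L, np - win + 1L, by = win)
  pulseWindows <- data.frame(
    t_s = (starts - 1 + win / 2) / fs,
    pp_mmHg = vapply(starts, function(s) {
      seg <- channels@pulse[s:(s + win - 1L)]
      (max(seg) - min(seg)) / fac
    }, numeric(1)))
  structure(list(respCycles = respCycles, pulseWindows = pulseWindows,
                 cardiacFreq_hz = fc, responseFactor = fac,
                 samplingRate = fs),
            class = "IcpAmplitudes")
}

#' Baseline-normalized per-epoch amplitude summary
#'
#' For each annotated epoch, restricts to its first \code{nCycles}
#' respiratory cycles, forms 1-second-interval means of the mean ICP, the
#' respiratory delta and the pulse pressure (the amplitude channels), then
#' averages over the epoch. Each epoch's metrics are divided by the
#' baseline epoch's to give normalized values (baseline ratios are exactly
#' 1).
#'
#' @param amps an \code{"IcpAmplitudes"} from \code{\link{cyclicAmplitudes}}
#'   computed on the whole recording.
#' @param rec the \linkS4class{ICPRecording} carrying epoch annotations.
#' @param nCycles respiratory cycles per epoch (default 10).
#' @param baselineLabel label of the reference epoch (default "baseline").
#' @return data.frame, one row per epoch: meanICP_mmHg, respDelta_mmHg,
#'   pulsePressure_mmHg and their normalized counterparts.
#' @export
epochSummary <- function(amps, rec, nCycles = 10L,
                         baselineLabel = "baseline") {
  stopifnot(inherits(amps, "IcpAmplitudes"), is(rec, "ICPRecording"))
  ep <- rec@epochs
  if (!baselineLabel %in% ep$label)
    stop("missing '", baselineLabel, "' epoch", call. = FALSE)
  fs <- rec@samplingRate
  rows <- lapply(seq_len(nrow(ep)), function(i) {
    cyc <- amps$respCycles
    cyc <- cyc[cyc$start_s >= ep$start_s[i] & cyc$end_s <= ep$end_s[i], ]
    if (!nrow(cyc))
      stop("epoch '", ep$label[i], "' contains no respiratory cycles",
           call. = FALSE)
    cyc <- head(cyc, nCycles)
    span <- c(cyc$start_s[1], cyc$end_s[nrow(cyc)])
    secs <- seq(floor(span[1]), ceiling(span[2]) - 1)
    perSec <- lapply(secs, function(s0) {
      i0 <- max(1L, floor(s0 * fs) + 1L)
      i1 <- min(length(rec@samples), ceiling((s0 + 1) * fs))
      mid <- s0 + 0.5
      j <- which(cyc$start_s <= mid & cyc$end_s >= mid)
      pw <- amps$pulseWindows
      pk <- pw$pp_mmHg[pw$t_s >= s0 & pw$t_s < s0 + 1]
      c(meanICP = mean(rec@samples[i0:i1]),
        respDelta = if (length(j)) cyc$delta_mmHg[j[1]] else NA_real_,
        pulse = if (length(pk)) mean(pk) else NA_real_)
    })
    ps <- do.call(rbind, perSec)
    data.frame(epoch = ep$label[i],
               meanICP_mmHg = mean(ps[, "meanICP"], na.rm = TRUE),
               respDelta_mmHg = mean(ps[, "respDelta"], na.rm = TRUE),
               pulsePressure_mmHg = mean(ps[, "pulse"], na.rm = TRUE),
               nCyclesUsed = nrow(cyc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  b <- out[out$epoch == baselineLabel, ][1, ]
  out$normMeanICP <- out$meanICP_mmHg / b$meanICP_mmHg
  out$normRespDelta <- out$respDelta_mmHg / b$respDelta_mmHg
  out$normPulsePressure <- out$pulsePressure_mmHg / b$pulsePressure_mmHg
  out
}
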
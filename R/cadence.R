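#' Preprocess a raw wrist recording into a band-limited magnitude series
#'
#' Computes the vector magnitude \eqn{\sqrt{x^2+y^2+z^2}}, removes the
#' gravity/posture component by subtracting a 5-s rolling median, then
#' band-passes 0.4–3.0 Hz with a 4th-order zero-phase Butterworth filter
#' (order-2 design applied forward and backward). The arm-swing band of
#' usual-paced walking (0.4–1.5 Hz stride frequency) passes untouched;
#' DC/posture drift and high-frequency sensor noise are removed.
#'
#' @param recording A `walk_recording` (see [simulate_walk()] or
#'   [read_walk_csv()]).
#' @return Object of class `magnitude_series`: `time_s`, `mag_g`, `fs`.
#' @export
preprocess <- function(recording) {
  stopifnot(inherits(recording, "walk_recording"))
  t <- recording$timestamp_s
  if (length(t) < 2 || diff(range(t)) < 30) stop("recording too short: need >= 30 s")
  dts <- diff(t)
  if (any(dts <= 0)) stop("non-monotone timestamps")
  med_dt <- stats::median(dts)
  if (any(abs(dts - med_dt) > 0.1 * med_dt)) {
    stop("sampling-interval jitter exceeds 10%")
  }
  acc <- cbind(recording$accel_x_g, recording$accel_y_g, recording$accel_z_g)
  if (any(abs(acc) >= 16)) stop("acceleration out of sensor range (16 g)")
  fs <- 1 / med_dt
  vm <- sqrt(rowSums(acc^2))

  k <- round(5 * fs)                      # 5-s rolling median, odd width
  if (k %% 2 == 0) k <- k + 1
  grav <- stats::runmed(vm, k, endrule = "median")
  d <- vm - grav

  bf <- signal::butter(2, c(0.4, 3.0) / (fs / 2), type = "pass")
  mag <- as.numeric(signal::filtfilt(bf, d))

  structure(list(time_s = t, mag_g = mag, fs = fs),
            class = "magnitude_series")
}

#' Estimate the cadence trajectory from a magnitude series
#'
#' Slides a window along the band-limited magnitude signal and takes the
#' dominant periodogram frequency in the arm-swing band 0.4–1.5 Hz as the
#' stride rate; cadence is `120 * f*` steps/min (two steps per arm swing).
#' The spectrum is zero-padded and the peak refined by local quadratic
#' interpolation, giving sub-bin frequency resolution. Windows whose peak
#' does not stand out from the remaining band power are flagged, as are the
#' first and last 3 s (start/turn transients); flagged points are linearly
#' interpolated from unflagged neighbours.
#'
#' @param mag A `magnitude_series` from [preprocess()].
#' @param window_s Window length, s (default 6: at least five stride cycles
#'   at usual cadence).
#' @param step_s Grid spacing, s; the output grid is left-aligned, 0-based.
#' @param band Search band for the stride frequency, Hz.
#' @param min_prominence Minimum ratio of peak power to the median power
#'   over the filter passband for a window to be trusted.
#' @return Object of class `cadence_series`, a data frame with `time_s`,
#'   `cadence_spm` and logical `flag` (TRUE = interpolated).
#' @export
estimate_cadence <- function(mag, window_s = 6, step_s = 1,
                             band = c(0.4, 1.5), min_prominence = 10) {
  stopifnot(inherits(mag, "magnitude_series"))
  fs <- mag$fs
  x <- mag$mag_g
  t0 <- mag$time_s[1]
  nw <- round(window_s * fs)
  n <- length(x)
  if (n < nw) stop("recording too short for the analysis window")
  starts <- seq(0, floor((n - nw) / fs * (1 / step_s)) * step_s, by = step_s)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # taper: smooth
  nfft <- 2^ceiling(log2(nw * 8))                           # mainlobe helps

  freqs <- (0:(nfft / 2)) * fs / nfft
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  passband <- which(freqs >= 0.4 & freqs <= 3.0)

  est <- flag <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    i0 <- round(starts[i] * fs) + 1
    seg <- x[i0:(i0 + nw - 1)]
    seg <- (seg - mean(seg)) * hann
    sp <- Mod(stats::fft(c(seg, rep(0, nfft - nw))))[seq_along(freqs)]^2
    pk <- in_band[which.max(sp[in_band])]
    prom <- sp[pk] / stats::median(sp[passband])
    flag[i] <- prom < min_prominence
    # quadratic refinement of the peak on log power
    if (pk > 1 && pk < length(freqs)) {
      y <- log(sp[(pk - 1):(pk + 1)] + 1e-300)
      denom <- y[1] - 2 * y[2] + y[3]
      shift <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
      shift <- max(-0.5, min(0.5, shift))
    } else shift <- 0
    est[i] <- 120 * (freqs[pk] + shift * fs / nfft)
  }
  flag <- as.logical(flag)
  # start/end transients: first and last 3 s of the walk
  grid <- starts                                   # left-aligned, 0-based
  t_end <- (n - 1) / fs
  flag[grid < 3 | (grid + window_s) > (t_end - 3)] <- TRUE

  if (mean(flag) > 0.5) {
    stop("unreliable cadence: more than half of the windows lack a clear ",
         "spectral peak")
  }
  good <- which(!flag)
  est[flag] <- stats::approx(grid[good], est[good], xout = grid[flag],
                             rule = 2)$y
  # elapsed time from the first sample: grid is already 0-based
  out <- data.frame(time_s = grid, cadence_spm = est, flag = flag)
  class(out) <- c("cadence_series", "data.frame")
  out
}
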
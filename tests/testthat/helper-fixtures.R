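# builders shared across test files

# pure-tone "recording": gravity plus a sinusoid on the forearm axis
mk_tone_recording <- function(freq_hz, amp_g = 0.2, dur_s = 120, fs = 80,
                              noise_sd = 0) {
  t <- seq(0, dur_s, by = 1 / fs)
  n <- length(t)
  structure(
    list(timestamp_s = t,
         accel_x_g = 1 + amp_g * sin(2 * pi * freq_hz * t) +
           rnorm(n, 0, noise_sd),
         accel_y_g = rnorm(n, 0, noise_sd),
         accel_z_g = rnorm(n, 0, noise_sd),
         fs = fs, subject_id = "tone", sex = "female",
         completion_time_s = NA_real_),
    class = "walk_recording")
}

mk_cadence <- function(time_s, cadence_spm, flag = FALSE) {
  d <- data.frame(time_s = time_s, cadence_spm = cadence_spm,
                  flag = rep_len(flag, length(time_s)))
  class(d) <- c("cadence_series", "data.frame")
  d
}

mk_smoothed <- function(time_s, fitted) {
  structure(list(time_s = time_s, fitted = fitted, lambda = NA, edf = NA,
                 coef = NULL, knots = NULL, gcv = NA),
            class = "smoothed_trajectory")
}

lin_profile <- function(c0, c1, over = 400, ...) {
  walk_profile(function(t) c0 + (c1 - c0) * pmin(t / over, 1), ...)
}

# sample a 3-level ordinal outcome from cumulative logits
# P(Y > j) = plogis(slope_j * x + cut_j); proportional odds iff slopes equal
r_ord3 <- function(x, slopes = c(0.8, 0.8), cuts = c(1, -1)) {
  stopifnot(cuts[1] > cuts[2])
  p1 <- plogis(slopes[1] * x + cuts[1])
  p2 <- plogis(slopes[2] * x + cuts[2])
  u <- runif(length(x))
  ordered(1 + (u < p1) + (u < p2), levels = 1:3)
}

linear_truth <- function(w, at) {
  approx(w$truth$time_s, w$truth$cadence_spm, xout = at, rule = 2)$y
}
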
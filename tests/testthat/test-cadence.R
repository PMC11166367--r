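test_that("preprocessing removes gravity and respects the passband", {
  # static posture: magnitude is constant, output vanishes
  static <- mk_tone_recording(0, amp_g = 0, dur_s = 60)
  m <- preprocess(static)
  core <- m$mag_g[(10 * 80):(50 * 80)]
  expect_lt(max(abs(core)), 1e-9)

  # 1 Hz tone is inside 0.4-3.0 Hz: amplitude preserved within 5%
  m1 <- preprocess(mk_tone_recording(1, amp_g = 0.2))
  core1 <- m1$mag_g[(10 * 80):(110 * 80)]
  expect_equal(max(abs(core1)), 0.2, tolerance = 0.05)

  # 5 Hz is deep in the stopband of the order-4 zero-phase filter
  m5 <- preprocess(mk_tone_recording(5, amp_g = 0.2))
  core5 <- m5$mag_g[(10 * 80):(110 * 80)]
  expect_lt(max(abs(core5)), 0.02)
})

test_that("invalid recordings are rejected", {
  short <- mk_tone_recording(1, dur_s = 20)
  expect_error(preprocess(short), "too short")
  bad <- mk_tone_recording(1, dur_s = 60)
  bad$timestamp_s[100] <- bad$timestamp_s[102]
  expect_error(preprocess(bad), "monotone|jitter")
  big <- mk_tone_recording(1, dur_s = 60)
  big$accel_y_g[5] <- 20
  expect_error(preprocess(big), "16 g")
})

test_that("a pure stride tone maps to cadence = 120 x frequency", {
  cs <- estimate_cadence(preprocess(mk_tone_recording(0.9)))
  interior <- !cs$flag
  expect_true(all(abs(cs$cadence_spm[interior] - 108) < 0.5))
})

test_that("cadence tracks the generator ground truth on a declining walk", {
  w <- simulate_walk(lin_profile(110, 90, seed = 31))
  cs <- estimate_cadence(preprocess(w$recording))
  err <- cs$cadence_spm - linear_truth(w, cs$time_s)
  expect_lt(sqrt(mean(err^2)), 3)
})

test_that("white noise alone has no trustworthy spectral peak", {
  set.seed(8)
  noise <- mk_tone_recording(0, amp_g = 0, dur_s = 120, noise_sd = 0.1)
  expect_error(estimate_cadence(preprocess(noise)), "unreliable cadence")
})

test_that("cadence is invariant to amplitude scaling and equivariant to time shifts", {
  w <- simulate_walk(lin_profile(108, 96, seed = 41))
  m <- preprocess(w$recording)
  cs <- estimate_cadence(m)
  m3 <- m
  m3$mag_g <- 3 * m$mag_g
  expect_equal(estimate_cadence(m3)$cadence_spm, cs$cadence_spm,
               tolerance = 1e-9)

  shifted <- w$recording
  shifted$timestamp_s <- shifted$timestamp_s + 17
  cs_s <- estimate_cadence(preprocess(shifted))
  # elapsed-time grid: same values, the absolute shift is carried by the
  # caller's clock
  expect_equal(cs_s$cadence_spm, cs$cadence_spm, tolerance = 1e-8)
})

test_that("estimator is accurate and nearly unbiased across random profiles", {
  set.seed(77)
  errs <- c()
  for (i in 1:10) {
    c0 <- runif(1, 95, 120)
    p <- lin_profile(c0, c0 - runif(1, 0, 25),
                     step_length_m = runif(1, 0.6, 0.8), seed = 700 + i)
    w <- simulate_walk(p)
    cs <- estimate_cadence(preprocess(w$recording))
    e <- cs$cadence_spm - linear_truth(w, cs$time_s)
    expect_lt(sqrt(mean(e^2)), 3)
    errs <- c(errs, e)
  }
  expect_lt(abs(mean(errs)), 1)
})

test_that("walk and cadence CSV round trips preserve the data", {
  w <- simulate_walk(lin_profile(110, 100, seed = 51))
  f <- tempfile(fileext = ".csv")
  write_walk_csv(w$recording, f)
  back <- read_walk_csv(f, subject_id = "S1", sex = "male",
                        completion_time_s = w$recording$completion_time_s)
  expect_equal(back$accel_x_g, w$recording$accel_x_g, tolerance = 1e-10)
  expect_equal(back$fs, 80, tolerance = 1e-6)

  cs <- estimate_cadence(preprocess(w$recording))
  f2 <- tempfile(fileext = ".csv")
  write_cadence_csv(cs, f2)
  cs2 <- read_cadence_csv(f2)
  expect_equal(cs2$cadence_spm, cs$cadence_spm, tolerance = 1e-10)
  expect_identical(cs2$flag, cs$flag)
  unlink(c(f, f2))
})
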
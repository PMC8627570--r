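# Wave-parameter estimators on sequences with known ground truth.

test_that("straight-line swimmer has zero excursion and recovers its speed", {
  p <- swimmer_params(amp_pp_tail_bl = 0, speed_bl_s = 1.3)
  sq <- generate_midline_sequence(p, 100, 80)
  f <- body_frame(sq)
  expect_lt(max(abs(f$h)), 1e-9)
  expect_equal(estimate_speed(f), 1.3, tolerance = 1e-6)
  expect_error(estimate_frequency(f), "no oscillation")
  expect_error(estimate_wavelength(f), "wave not resolved")
})

test_that("tail excursion is sinusoidal at f with half-amplitude A_pp/2", {
  p <- swimmer_params(wavelength_bl = 0.6, frequency_hz = 4,
                      amp_pp_tail_bl = 0.12, amp_ratio = 2, speed_bl_s = 1.5)
  sq <- generate_midline_sequence(p, 250, 500)
  f <- body_frame(sq)
  ht <- f$h[100, ]   # s = 1, where the envelope reaches A_pp/2
  expect_equal(max(abs(ht)), 0.06, tolerance = 0.02)
  expect_equal(as.numeric(estimate_frequency(f)), 4, tolerance = 0.005)
})

test_that("station-holding oscillation is rejected for lack of net travel", {
  p <- swimmer_params(speed_bl_s = 0, amp_pp_tail_bl = 0.12,
                      wavelength_bl = 0.6, frequency_hz = 4)
  sq <- generate_midline_sequence(p, 100, 100)
  expect_error(body_frame(sq), "no net travel")
})

test_that("estimates are invariant to heading rotation and frame rate", {
  base <- wave_kinematics(generate_midline_sequence(
    swimmer_params(heading_deg = 0), 250, 400))
  rot <- wave_kinematics(generate_midline_sequence(
    swimmer_params(heading_deg = 37), 250, 400))
  for (v in c("speed_bl_s", "frequency_hz", "amp_pp_bl", "wavelength_bl",
              "wave_speed_bl_s"))
    expect_equal(rot[[v]], base[[v]], tolerance = 0.01)
  ## doubling frame rate leaves estimates unchanged
  fast <- wave_kinematics(generate_midline_sequence(
    swimmer_params(heading_deg = 0), 500, 800))
  for (v in c("speed_bl_s", "frequency_hz", "wavelength_bl"))
    expect_equal(fast[[v]], base[[v]], tolerance = 0.01)
})

test_that("frequency estimation is robust to sampling rate", {
  p <- swimmer_params(frequency_hz = 4.1, wavelength_bl = 0.53,
                      amp_pp_tail_bl = 0.11, amp_ratio = 1.7,
                      speed_bl_s = 1.12)
  f1000 <- estimate_frequency(body_frame(
    generate_midline_sequence(p, 1000, 1000)))
  f250 <- estimate_frequency(body_frame(
    generate_midline_sequence(p, 250, 250)))
  expect_equal(as.numeric(f1000), as.numeric(f250), tolerance = 0.01)
  expect_equal(as.numeric(f1000), 4.1, tolerance = 0.005)
})

test_that("amplitude estimator recovers the printed sham values", {
  sq <- generate_midline_sequence(sham_params(), 250, 500)
  a <- estimate_amplitude(body_frame(sq))
  expect_equal(a$amp_pp_bl, 0.16, tolerance = 0.02)
  expect_equal(a$amp_ratio, 4.8, tolerance = 0.05)
})

test_that("wavelength estimator recovers short and long waves", {
  gill <- estimate_wavelength(body_frame(
    generate_midline_sequence(gill_params(), 250, 250)))
  expect_equal(as.numeric(gill), 0.53, tolerance = 0.02)
  expect_false(attr(gill, "fit_based"))
  ## under one half-wave on the body forces the flagged sinusoid-fit path
  p <- swimmer_params(wavelength_bl = 2, frequency_hz = 3,
                      amp_pp_tail_bl = 0.12, amp_ratio = 1.5,
                      speed_bl_s = 1.5)
  lam <- estimate_wavelength(body_frame(
    generate_midline_sequence(p, 100, 150)))
  expect_true(attr(lam, "fit_based"))
  expect_equal(as.numeric(lam), 2, tolerance = 0.05)
})

test_that("wave speed equals lambda * f and standing waves are rejected", {
  p <- swimmer_params(wavelength_bl = 0.6, frequency_hz = 4,
                      amp_pp_tail_bl = 0.12, amp_ratio = 1.5, speed_bl_s = 1.5)
  sq <- generate_midline_sequence(p, 250, 400)
  V <- estimate_wave_speed(body_frame(sq))
  expect_equal(as.numeric(V), 2.4, tolerance = 0.03)
  expect_gt(attr(V, "r_squared"), 0.99)

  ## a standing wave (sum of counter-propagating waves) has no phase slope
  f <- body_frame(sq)
  tt <- f$time_s
  f$h <- outer(sin(2 * pi * f$s / 0.6), cos(2 * pi * 4 * tt)) * 0.05
  expect_error(estimate_wave_speed(f, f = 4), "incoherent wave")
})

test_that("steady-state filter passes constant speed and fails a ramp", {
  sq <- generate_midline_sequence(sham_params(), 250, 300)
  ss <- steady_state_filter(sq)
  expect_true(ss$pass)
  expect_lt(max(abs(ss$cycle_speeds_bl_s - 1.83)), 0.02)

  ## add +50% speed ramp over a 4 s clip: displacement 0.5*a*t^2 along
  ## heading; with ~14 cycle windows the cycle speeds span well over 15%
  ramp <- generate_midline_sequence(sham_params(), 250, 1000)
  tt <- ramp$time_s
  a_bl <- 0.5 * 1.83 / max(tt)
  extra <- 0.5 * a_bl * tt^2 * sq$scale
  for (j in seq_along(tt)) ramp$xy[, 1, j] <- ramp$xy[, 1, j] + extra[j]
  expect_false(steady_state_filter(ramp)$pass)
  expect_error(wave_kinematics(ramp), "not steady")

  ## small midline noise stays below the steadiness tolerance
  noisy <- generate_midline_sequence(
    sham_params(noise_sd_bl = 0.005, seed = 3), 250, 300)
  expect_true(steady_state_filter(noisy)$pass)
})

test_that("too-short sequences raise insufficient-cycles errors", {
  sq <- generate_midline_sequence(sham_params(), 250, 60)  # < 1 cycle
  expect_error(steady_state_filter(sq), "insufficient cycles")
  expect_error(estimate_frequency(body_frame(sq)), "insufficient cycles")
})

test_that("waves per body is the reciprocal wavelength", {
  expect_equal(waves_per_body(0.53), 1.887, tolerance = 1e-3)
  expect_equal(waves_per_body(1), 1)
  expect_equal(waves_per_body(0.5), 2)
  expect_error(waves_per_body(0), "wavelength")
})

test_that("outputs are unchanged when the pixel scale is doubled", {
  sq <- generate_midline_sequence(gill_params(), 250, 250)
  k1 <- wave_kinematics(track_frames(render_frames(
    sq, render_spec(pixels_per_bl = 100, follow = TRUE))))
  k2 <- wave_kinematics(track_frames(render_frames(
    sq, render_spec(pixels_per_bl = 200, follow = TRUE))))
  for (v in c("speed_bl_s", "frequency_hz", "amp_pp_bl", "wavelength_bl"))
    expect_equal(k1[[v]], k2[[v]], tolerance = 0.02)
})

test_that("mean excursion over whole cycles vanishes at every station", {
  sq <- generate_midline_sequence(sham_params(), 250, 418)  # ~6 cycles
  f <- body_frame(sq)
  tc <- swimkin:::crossing_times(swimkin:::station_series(f, 0.95), f$time_s)
  jj <- f$time_s >= tc[1] & f$time_s < tc[length(tc)]
  env <- estimate_amplitude(f)$envelope$pp
  expect_lt(max(abs(rowMeans(f$h[, jj])) / (env / 2)), 0.05)
})
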
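# Synthetic swimmer generator: wave construction, rendering, cohorts.

test_that("parameter validation rejects non-physical swimmers", {
  expect_error(swimmer_params(wavelength_bl = 0), "wavelength")
  expect_error(swimmer_params(frequency_hz = -1), "frequency")
  expect_error(swimmer_params(amp_pp_tail_bl = 1.2), "amp_pp_tail_bl")
  expect_error(swimmer_params(amp_ratio = 0.5), "amp_ratio")
  expect_error(swimmer_params(noise_sd_bl = -0.1), "noise_sd_bl")
})

test_that("sampling adequacy is enforced with an informative error", {
  p <- swimmer_params(frequency_hz = 4)
  expect_error(generate_midline_sequence(p, 30, 10), "sampling adequacy")
  expect_silent(generate_midline_sequence(p, 40, 10))
})

test_that("uniform envelope gives equal head and tail excursion", {
  p <- swimmer_params(amp_ratio = 1, amp_pp_tail_bl = 0.1,
                      wavelength_bl = 0.6, frequency_hz = 4)
  sq <- generate_midline_sequence(p, 250, 250)
  f <- body_frame(sq)
  pp <- apply(f$h, 1, function(z) max(z) - min(z))
  expect_equal(pp[1], pp[length(pp)], tolerance = 0.01)
  a <- estimate_amplitude(f)
  expect_equal(a$amp_ratio, 1, tolerance = 0.02)
})

test_that("wave crest travels at phase speed lambda * f", {
  p <- swimmer_params(wavelength_bl = 0.6, frequency_hz = 4,
                      amp_pp_tail_bl = 0.12, amp_ratio = 1, speed_bl_s = 1.5)
  sq <- generate_midline_sequence(p, 500, 100)
  f <- body_frame(sq)
  ## track one crest across frames while it stays on the body; crest
  ## position refined by a parabola through the three bracketing samples
  crest <- function(j) {
    y <- f$h[, j]
    i <- which(diff(sign(diff(y))) < 0) + 1
    i <- i[which.max(y[i])]
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    f$s[i] + 0.5 * (y[i - 1] - y[i + 1]) / den * (f$s[2] - f$s[1])
  }
  s1 <- crest(1)
  for (dj in c(10, 20, 30)) {
    expected <- s1 + 0.6 * 4 * dj / 500
    if (expected < 0.95)
      expect_equal(crest(1 + dj), expected, tolerance = 0.01)
  }
})

test_that("envelope ratio of generated excursion matches amp_ratio", {
  p <- swimmer_params(amp_ratio = 4.8, amp_pp_tail_bl = 0.16)
  sq <- generate_midline_sequence(p, 250, 250)
  f <- body_frame(sq)
  pp <- apply(f$h, 1, function(z) max(z) - min(z))
  expect_equal(pp[length(pp)] / pp[1], 4.8, tolerance = 0.048)
})

test_that("generated body is inextensible and noise returns the truth", {
  p <- swimmer_params(noise_sd_bl = 0.01, seed = 99)
  sq <- generate_midline_sequence(p, 250, 50)
  len <- apply(sq$truth, 3, function(m) sum(sqrt(rowSums(diff(m)^2))))
  expect_lt(sd(len) / mean(len), 0.005)
  expect_equal(mean(len) / p$body_length_mm, 1, tolerance = 0.001)
  ## noisy coordinates differ from truth by about the configured SD
  dev <- sd(sq$xy - sq$truth)
  expect_equal(dev, 0.01 * p$body_length_mm, tolerance = 0.05)
})

test_that("noise-free extraction recovers printed 5th-gill parameters", {
  p <- gill_params()
  sq <- generate_midline_sequence(p, 1000, 1000)
  k <- wave_kinematics(sq)
  expect_equal(k$wavelength_bl, 0.53, tolerance = 0.02)
  expect_equal(k$frequency_hz, 4.1, tolerance = 0.02)
  expect_equal(k$amp_pp_bl, 0.11, tolerance = 0.02)
  expect_equal(k$speed_bl_s, 1.12, tolerance = 0.02)
})

test_that("straight body renders a symmetric silhouette", {
  p <- swimmer_params(amp_pp_tail_bl = 0, heading_deg = 0, speed_bl_s = 1)
  sq <- generate_midline_sequence(p, 100, 3)
  stk <- render_frames(sq, render_spec())
  img <- stk$frames[[1]]
  row0 <- stk$truth_px[1, 2, 1] - stk$origin[1, 1]
  on <- which(img > 0, arr.ind = TRUE)
  expect_equal(mean(on[, 1]), row0, tolerance = 0.05)
  ## symmetric: same pixel count above and below the midline row
  expect_equal(sum(on[, 1] < row0 - 0.5), sum(on[, 1] > row0 + 0.5))
})

test_that("foreground pixel area is conserved while the body bends", {
  stk <- sham_clip()$stack
  areas <- vapply(stk$frames[seq(1, 300, by = 10)], sum, numeric(1))
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.02)
})

test_that("single-frame stacks render but are rejected by time estimators", {
  p <- sham_params()
  sq <- generate_midline_sequence(p, 250, 1)
  stk <- render_frames(sq, render_spec())
  expect_length(stk$frames, 1)
  mask <- segment_body(stk$frames[[1]])
  m <- extract_midline(mask)
  expect_s3_class(m, "body_midline")
  expect_error(body_frame(sq), "insufficient|frame")
})

test_that("a fixed image_size too small for the track is an error naming the frame", {
  p <- swimmer_params(speed_bl_s = 2)
  sq <- generate_midline_sequence(p, 100, 60)
  expect_error(render_frames(sq, render_spec(image_size = c(80, 200))),
               "field of view at frame [0-9]+")
})

test_that("ground-truth rendered midline agrees with the analytic one", {
  clip <- sham_clip()
  stk <- clip$stack
  k <- stk$pixels_per_bl / clip$seq$scale
  expect_equal(max(abs(stk$truth_px[, 1, 10] - clip$seq$xy[, 1, 10] * k)), 0,
               tolerance = 1e-8)
})

test_that("cohort generation is seed-reproducible and validates sizes", {
  spec <- cohort_spec(seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_error(cohort_spec(n = c(sham = 0, fifth_gill = 11, mid_body = 3)),
               ">= 1")
  expect_error(cohort_spec(regen_range = c(-5, 50)), "regen_range")
})

test_that("zero SDs give every individual exactly the group mean", {
  zero_sds <- list(
    sham       = c(wavelength_bl = 0, amp_pp_tail_bl = 0, frequency_hz = 0,
                   speed_bl_s = 0, amp_ratio = 0),
    fifth_gill = c(wavelength_bl = 0, amp_pp_tail_bl = 0, frequency_hz = 0,
                   speed_bl_s = 0, amp_ratio = 0),
    mid_body   = c(wavelength_bl = 0, amp_pp_tail_bl = 0, frequency_hz = 0,
                   speed_bl_s = 0, amp_ratio = 0))
  co <- generate_cohort(cohort_spec(sds = zero_sds, seed = 1))
  sham <- co[co$treatment == "sham", ]
  expect_true(all(sham$wavelength_bl == 0.79))
  expect_true(all(sham$speed_bl_s == 1.83))
  gill <- co[co$treatment == "fifth_gill", ]
  expect_true(all(gill$frequency_hz == 4.1))
})

test_that("cohort draws center on the configured group means", {
  spec <- cohort_spec(n = c(sham = 30, fifth_gill = 3, mid_body = 3),
                      trials_per_individual = 1, seed = 5)
  co <- generate_cohort(spec)
  sham <- co[co$treatment == "sham", ]
  se <- 0.08 / sqrt(30)
  expect_lt(abs(mean(sham$speed_bl_s) - 1.83), 3 * se)
  ## regeneration: missing for sham, inside the configured range otherwise
  expect_true(all(is.na(sham$regeneration_pct)))
  trans <- co[co$treatment != "sham", ]
  expect_true(all(trans$regeneration_pct >= 33.3 &
                  trans$regeneration_pct <= 84.2))
})
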
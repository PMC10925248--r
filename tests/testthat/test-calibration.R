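test_that("eye model fit: median centre, dispersion gate, radius estimate", {
  set.seed(21)
  samples <- cbind(180 + rnorm(100, 0, 0.2), 135 + rnorm(100, 0, 0.2))
  m <- fit_eye_model(samples, radius_px = 259.1)
  expect_equal(m$center_ref, c(180, 135), tolerance = 0.1)
  # oracle: the per-axis median itself
  expect_equal(m$center_ref, c(median(samples[, 1]), median(samples[, 2])))
  # closed form r = delta_px / sin(delta_deg)
  expect_equal(estimate_radius_px(45, 10), 45 / sin(10 * pi / 180))
  expect_equal(estimate_radius_px(45, 10), 259.1, tolerance = 0.1)
  expect_error(fit_eye_model(matrix(numeric(0), 0, 2)), "samples")
  drift <- cbind(180 + seq(0, 30, length.out = 50), 135 + numeric(50))
  expect_error(fit_eye_model(drift), "unstable")
})

test_that("eye-model mapping follows asin with the stated sign convention", {
  m <- fit_eye_model(cbind(rep(180, 10), rep(135, 10)), radius_px = 259.1)
  expect_equal(model_pixels_to_degrees(m, c(180, 135))$h_deg, 0)
  expect_equal(model_pixels_to_degrees(m, c(180 + 259.1 / 2, 135))$h_deg, 30)
  dy <- -259.1 * sin(10 * pi / 180)
  expect_equal(model_pixels_to_degrees(m, c(180, 135 + dy))$v_deg, 10)
  oor <- model_pixels_to_degrees(m, c(180 + 300, 135))
  expect_false(oor$in_range)
  expect_true(is.nan(oor$h_deg))
})

test_that("regression recovers an exact linear device and reports residuals", {
  grid <- expand.grid(h = c(-10, 0, 10), v = c(-10, 0, 10))
  # synthetic linear device: x = (h + 20) / 0.1, i.e. h = 0.1 x - 20
  raw <- cbind((grid$h + 20) / 0.1, (grid$v + 5) / 0.2)
  cal <- fit_regression(raw, cbind(grid$h, grid$v))
  expect_equal(unname(cal$coef_h), c(-20, 0.1, 0), tolerance = 1e-9)
  expect_equal(unname(cal$coef_v[1]), -5 / 0.2 * 0.2, tolerance = 1e-9)
  expect_equal(unname(cal$residual_rms_deg), c(0, 0), tolerance = 1e-9)
  # collinear targets: rank-deficient -> error
  flat <- cbind(seq(0, 80, 10), rep(0, 9))
  expect_error(fit_regression(flat, cbind(seq(-20, 20, 5), rep(0, 9))),
               "collinear|rank|degenerate")
  expect_error(fit_regression(raw[1:2, ], cbind(grid$h, grid$v)[1:2, ]), ">= 3")
})

test_that("noisy 9-point grid residual matches the Monte-Carlo expectation", {
  # gain 0.1 deg/px, pixel noise sigma = 0.5 px -> residual RMS ~ 0.05 deg
  set.seed(31)
  grid <- expand.grid(h = c(-10, 0, 10), v = c(-10, 0, 10))
  resids <- replicate(40, {
    raw <- cbind(grid$h / 0.1 + rnorm(9, 0, 0.5), grid$v / 0.1 + rnorm(9, 0, 0.5))
    cal <- fit_regression(raw, cbind(grid$h, grid$v))
    mean(cal$residual_rms_deg)
  })
  expect_gt(mean(resids), 0.05 * 0.5)
  expect_lt(mean(resids), 0.05 * 1.5)
})

test_that("apply_calibration maps features, flags missing ones, re-zeroes torsion", {
  grid <- expand.grid(h = c(-10, 0, 10), v = c(-10, 0, 10))
  raw <- cbind(grid$h / 0.1, grid$v / 0.1)
  cal <- fit_regression(raw, cbind(grid$h, grid$v))
  d <- new_datum(0, 0, "left", pupil = new_ellipse(c(100, -50), 10, 10, 0),
                 torsion_deg = 2.5)
  cs <- apply_calibration(cal, d)
  expect_equal(cs$h_deg, 10, tolerance = 1e-9)
  expect_equal(cs$v_deg, -5, tolerance = 1e-9)
  expect_equal(cs$torsion_deg, 2.5)
  cal$torsion_ref <- 1
  expect_equal(apply_calibration(cal, d)$torsion_deg, 1.5)
  blink <- new_datum(1, 0, "left", quality = "pupil_not_found")
  csb <- apply_calibration(cal, blink)
  expect_false(csb$valid)
  expect_true(is.nan(csb$h_deg))
  # identity calibration: degrees equal pixels
  ident <- fit_regression(cbind(c(0, 1, 0, 5), c(0, 0, 1, 5)),
                          cbind(c(0, 1, 0, 5), c(0, 0, 1, 5)))
  di <- new_datum(0, 0, "left", pupil = new_ellipse(c(3.5, -2), 5, 5, 0))
  csi <- apply_calibration(ident, di)
  expect_equal(c(csi$h_deg, csi$v_deg), c(3.5, -2), tolerance = 1e-9)
})

test_that("pupil_cr feature route uses the pupil-glint vector", {
  feats <- cbind(c(-10, 0, 10, 0), c(0, -10, 0, 10))
  cal <- fit_regression(feats, feats, feature = "pupil_cr")
  d <- new_datum(0, 0, "left", pupil = new_ellipse(c(105, 95), 10, 10, 0),
                 glints = list(list(center = c(100, 100))))
  cs <- apply_calibration(cal, d)
  expect_equal(c(cs$h_deg, cs$v_deg), c(5, -5), tolerance = 1e-9)
  # no glint -> flagged
  d2 <- new_datum(0, 0, "left", pupil = new_ellipse(c(105, 95), 10, 10, 0))
  expect_false(apply_calibration(cal, d2)$valid)
})

test_that("calibration files round-trip for both types", {
  path <- withr::local_tempfile(fileext = ".cal")
  m <- fit_eye_model(cbind(rep(180, 12), rep(135, 12)), radius_px = 259.1)
  save_calibration(m, path)
  m2 <- load_calibration(path)
  expect_equal(m2$center_ref, m$center_ref)
  expect_equal(m2$radius_px, m$radius_px)
  expect_equal(m2$type, "eye_model")

  grid <- expand.grid(h = c(-5, 0, 5), v = c(-5, 0, 5))
  cal <- fit_regression(cbind(grid$h * 4, grid$v * 4), cbind(grid$h, grid$v),
                        feature = "pupil_cr")
  save_calibration(cal, path)
  cal2 <- load_calibration(path)
  expect_equal(cal2$coef_h, cal$coef_h)
  expect_equal(cal2$coef_v, cal$coef_v)
  expect_equal(cal2$feature, "pupil_cr")
  d <- new_datum(0, 0, "left", pupil = new_ellipse(c(8, -4), 3, 3, 0),
                 glints = list(list(center = c(0, 0))))
  expect_equal(apply_calibration(cal2, d), apply_calibration(cal, d))
})

test_that("target schedules parse and drive behavioural calibration", {
  sched_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# t_start t_end h v", "0.0 1.0 -10 0", "1.0 2.0 0 0",
               "2.0 3.0 10 0", "3.0 4.0 0 -10", "4.0 5.0 0 10"), sched_path)
  sched <- read_target_schedule(sched_path)
  expect_equal(nrow(sched), 5)
  expect_equal(sched$h_deg, c(-10, 0, 10, 0, 0))
  writeLines("0.0 1.0 bad", sched_path)
  expect_error(read_target_schedule(sched_path), "line 1")

  # synthetic recording at 4.5 px/deg around (180, 135)
  fs <- 100
  t <- seq(0, 4.99, by = 1 / fs)
  truth_h <- c(-10, 0, 10, 0, 0)[pmin(floor(t) + 1, 5)]
  truth_v <- c(0, 0, 0, -10, 10)[pmin(floor(t) + 1, 5)]
  rows <- data.frame(frame_number = seq_along(t) - 1, timestamp_s = t,
                     eye = "left", pupil_x = 180 + 4.5 * truth_h,
                     pupil_y = 135 - 4.5 * truth_v, pupil_major = 30,
                     pupil_minor = 30, pupil_angle = 0, glint1_x = NaN,
                     glint1_y = NaN, torsion_deg = NaN, p1_x = NaN, p1_y = NaN,
                     p4_x = NaN, p4_y = NaN, h_deg = NaN, v_deg = NaN,
                     quality = "ok")
  sched2 <- data.frame(t_start = 0:4, t_end = 1:5,
                       h_deg = c(-10, 0, 10, 0, 0), v_deg = c(0, 0, 0, -10, 10))
  cal <- calibrate_from_recording(rows, sched2)
  expect_lt(max(cal$residual_rms_deg), 1e-9)
  d <- new_datum(0, 0, "left", pupil = new_ellipse(c(180 + 4.5 * 7, 135), 30, 30, 0))
  expect_equal(apply_calibration(cal, d)$h_deg, 7, tolerance = 1e-9)
})
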
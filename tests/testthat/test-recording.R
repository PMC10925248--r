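make_rows <- function(n = 10) {
  data.frame(frame_number = 0:(n - 1), timestamp_s = (0:(n - 1)) / 500,
             eye = "left", pupil_x = rnorm(n, 180), pupil_y = rnorm(n, 135),
             pupil_major = 30, pupil_minor = 29.5, pupil_angle = 12.25,
             glint1_x = 135.5, glint1_y = 145.25, torsion_deg = 0.5,
             p1_x = NaN, p1_y = NaN, p4_x = NaN, p4_y = NaN,
             h_deg = 1.5, v_deg = -2.25, quality = "ok",
             stringsAsFactors = FALSE)
}

test_that("data-file round-trip preserves values, NaN tokens and flags", {
  set.seed(8)
  rows <- make_rows(10)
  rows$quality[4] <- "pupil_not_found"
  rows[4, c("pupil_x", "pupil_y", "pupil_major", "pupil_minor",
            "pupil_angle", "h_deg", "v_deg")] <- NaN
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rows(path, rows, header = list(fs = 500))
  back <- read_rows(path)
  hdr <- attr(back, "header")
  attr(back, "header") <- NULL
  expect_equal(back, rows)
  expect_true(is.nan(back$pupil_x[4]))
  expect_equal(back$quality[4], "pupil_not_found")
  expect_equal(hdr$fs, "500")
})

test_that("out-of-order rows refuse to write; malformed lines name themselves", {
  rows <- make_rows(5)
  rows$frame_number <- c(0, 2, 1, 3, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_rows(path, rows), "ordered")
  writeLines(c("# vogkit data v1", "1\t2\t3"), path)
  err <- expect_error(read_rows(path))
  expect_match(conditionMessage(err), "line 2")
})

test_that("velocity: central difference with one-sided endpoints and NaN gaps", {
  tr <- new_trace(rep(3.25, 50), fs = 500)
  expect_true(all(velocity(tr)$x == 0))
  ramp <- new_trace(0.01 * (0:99), fs = 500)
  expect_true(all(abs(velocity(ramp)$x - 5) < 1e-9))
  # sine amplitude check: d/dt A sin(2 pi f t) has amplitude 2 pi f A
  fs <- 500; f <- 4; A <- 3
  t <- (0:2499) / fs
  v <- velocity(new_trace(A * sin(2 * pi * f * t), fs))
  expect_equal(max(abs(v$x)), 2 * pi * f * A, tolerance = 0.01)
  # NaN propagates to neighbours only
  x <- c(0, 1, NaN, 3, 4, 5)
  v2 <- velocity(new_trace(x, fs = 1))$x
  expect_true(is.na(v2[2]) && is.na(v2[4]) && is.na(v2[3]))
  expect_false(anyNA(v2[c(1, 5, 6)]))
  expect_error(new_trace(1:5, fs = 0), "fs")
  expect_error(velocity(new_trace(1, fs = 10)), ">= 2")
})

test_that("rms over non-NaN samples", {
  expect_equal(rms(rep(-4, 7)), 4)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(c(2, -2, 2, -2)), 2)
  expect_equal(rms(c(3, NaN, 4)), sqrt(12.5))
  expect_error(rms(c(NaN, NaN)), "NaN")
})

test_that("rms velocity of iid positional noise matches sigma*fs/sqrt(2)", {
  set.seed(12)
  fs <- 500; sigma <- 0.04; n <- 10000
  tr <- new_trace(rnorm(n, 0, sigma), fs)
  v <- velocity(tr)
  expect_equal(rms(v), sigma * fs / sqrt(2), tolerance = 0.05)
})

test_that("batch processing isolates failures and is deterministic", {
  dir <- withr::local_tempdir()
  traj <- trajectory_fixation(6)
  v1 <- file.path(dir, "a.avi"); v3 <- file.path(dir, "c.avi")
  generate_sequence(traj, test_scene(), video_path = v1, seed = 1)
  generate_sequence(traj, test_scene(), video_path = v3, seed = 2)
  jobs <- list(
    list(video = v1, out = file.path(dir, "a.tsv")),
    list(video = file.path(dir, "missing.avi"), out = file.path(dir, "b.tsv")),
    list(video = v3, out = file.path(dir, "c.tsv")))
  reports <- batch_process(jobs)
  expect_null(reports[[1]]$error)
  expect_null(reports[[3]]$error)
  expect_match(reports[[2]]$error, "missing")
  expect_true(file.exists(file.path(dir, "a.tsv")))
  expect_false(file.exists(file.path(dir, "b.tsv")))
  # same job twice -> byte-identical output
  jobs2 <- list(list(video = v1, out = file.path(dir, "a2.tsv")))
  batch_process(jobs2)
  expect_identical(readBin(file.path(dir, "a.tsv"), "raw", 1e6),
                   readBin(file.path(dir, "a2.tsv"), "raw", 1e6))
})
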
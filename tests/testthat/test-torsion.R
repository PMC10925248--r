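# radially constant test image: I(x, y) = f(atan2(y - cy, x - cx))
angular_image <- function(f, w = 200, h = 200, c0 = c(100, 100), base = 128,
                          amp = 60) {
  X <- matrix(0:(w - 1), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1), h, w)
  phi <- atan2(Y - c0[2], X - c0[1])
  matrix(as.integer(round(pmin(pmax(base + amp * f(phi), 0), 255))), h, w)
}

test_that("unwrap of a radially constant image has identical radius rows", {
  img <- angular_image(function(phi) sin(3 * phi))
  pol <- unwrap_polar(img, c(100, 100), 20, 60, n_angles = 360, n_radii = 10)
  expect_true(all(pol$valid))
  spread <- apply(pol$raster, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 2.5)  # quantization + bilinear only
})

test_that("rotating the texture circularly shifts the polar image", {
  f <- function(phi) sin(3 * phi)
  img0 <- angular_image(f)
  delta <- 10 * pi / 180
  img1 <- angular_image(function(phi) f(phi - delta))
  n_ang <- 360
  p0 <- unwrap_polar(img0, c(100, 100), 25, 55, n_angles = n_ang, n_radii = 8)
  p1 <- unwrap_polar(img1, c(100, 100), 25, 55, n_angles = n_ang, n_radii = 8)
  shift <- round(delta / (2 * pi) * n_ang)  # 10 columns
  row0 <- p0$raster[4, ]
  row1 <- p1$raster[4, ]
  # rotation by +delta: column m of p1 equals column m-shift of p0 (right roll)
  rolled <- c(row0[(n_ang - shift + 1):n_ang], row0[1:(n_ang - shift)])
  expect_lt(mean(abs(row1 - rolled)), 2.5)
})

test_that("annulus clipped by the image edge is masked, not fatal", {
  img <- angular_image(function(phi) cos(phi))
  pol <- unwrap_polar(img, c(10, 100), 20, 60, n_angles = 180, n_radii = 6)
  expect_true(any(!pol$valid))
  expect_true(any(pol$valid))
  expect_true(all(is.finite(pol$raster[pol$valid])))
  expect_error(unwrap_polar(img, c(100, 100), 500, 600), "outside")
})

test_that("iris_profile averages radii, masks sparse angles, centres itself", {
  pol <- structure(list(
    raster = matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4),
    valid = matrix(TRUE, 4, 4),
    angles_deg = c(0, 90, 180, 270), radii = 1:4), class = "vog_polar")
  pr <- iris_profile(pol)
  expect_equal(pr$values, c(1, 2, 3, 4) - 2.5)
  # sin(3*theta) replicated over radii survives up to its mean
  n <- 360
  th <- 2 * pi * (0:(n - 1)) / n
  pol2 <- structure(list(raster = matrix(rep(sin(3 * th), each = 5), nrow = 5),
                         valid = matrix(TRUE, 5, n),
                         angles_deg = th * 180 / pi, radii = 1:5),
                    class = "vog_polar")
  pr2 <- iris_profile(pol2)
  expect_equal(pr2$values, sin(3 * th), tolerance = 1e-10)
  # an angle with under half its radii valid is masked
  pol$valid[, 2] <- c(TRUE, FALSE, FALSE, FALSE)
  pr3 <- iris_profile(pol)
  expect_true(is.na(pr3$values[2]))
  pol$valid[] <- FALSE
  expect_error(iris_profile(pol), "masked")
})

test_that("one noisy radius row perturbs the profile by ~noise/sqrt(n_radii)", {
  set.seed(99)
  n <- 360; n_radii <- 16
  th <- 2 * pi * (0:(n - 1)) / n
  clean <- matrix(rep(sin(5 * th), each = n_radii), nrow = n_radii)
  noisy <- clean
  sigma <- 8
  noisy[7, ] <- noisy[7, ] + rnorm(n, 0, sigma)
  mk <- function(r) structure(list(raster = r, valid = matrix(TRUE, n_radii, n),
                                   angles_deg = th, radii = 1:n_radii),
                              class = "vog_polar")
  d <- iris_profile(mk(noisy))$values - iris_profile(mk(clean))$values
  expect_lt(sd(d), 3 * sigma / n_radii)  # one row of noise averaged over radii
})

test_that("torsion measurement recovers analytic shifts with unit peak", {
  f <- function(th) sin(5 * th * pi / 180) + 0.3 * sin(9 * th * pi / 180)
  ref <- profile_from_function(f)
  probe <- profile_from_function(function(th) f(th - 5))
  r <- measure_torsion(probe, ref)
  expect_true(r$valid)
  expect_equal(r$torsion_deg, 5, tolerance = 0.05)
  expect_gt(r$peak_correlation, 0.99)
  # identity: zero shift, perfect correlation
  r0 <- measure_torsion(ref, ref)
  expect_equal(r0$torsion_deg, 0, tolerance = 1e-9)
  expect_equal(r0$peak_correlation, 1, tolerance = 1e-12)
})

test_that("independent noise fails the correlation threshold", {
  set.seed(5)
  f <- function(th) sin(5 * th * pi / 180) + 0.3 * sin(9 * th * pi / 180)
  ref <- profile_from_function(f)
  probe <- profile_from_function(function(th) rnorm(length(th)))
  r <- measure_torsion(probe, ref)
  expect_false(r$valid)
  expect_lt(r$peak_correlation, 0.4)
})

test_that("measurement is antisymmetric and saturates at the shift limit", {
  f <- function(th) sin(5 * th * pi / 180) + 0.3 * sin(9 * th * pi / 180)
  a <- profile_from_function(function(th) f(th - 3.25))
  b <- profile_from_function(f)
  ab <- measure_torsion(a, b)
  ba <- measure_torsion(b, a)
  expect_lt(abs(ab$torsion_deg + ba$torsion_deg), 0.05)
  # a shift beyond max_shift_deg saturates -> invalid
  far <- profile_from_function(function(th) f(th - 20))
  rs <- measure_torsion(far, b, max_shift_deg = 15)
  expect_false(rs$valid)
})

test_that("reference handling: none, set, reset", {
  tt <- torsion_tracker()
  f <- function(th) sin(5 * th * pi / 180)
  p <- profile_from_function(f)
  r <- tt$measure(p)
  expect_false(r$valid)
  expect_equal(r$reason, "no reference")
  tt$set_reference(p)
  expect_equal(tt$measure(p)$torsion_deg, 0, tolerance = 1e-9)
  # resetting the reference re-zeroes subsequent torsion
  p2 <- profile_from_function(function(th) f(th - 4))
  expect_equal(tt$measure(p2)$torsion_deg, 4, tolerance = 0.05)
  tt$set_reference(p2)
  expect_equal(tt$measure(p2)$torsion_deg, 0, tolerance = 1e-9)
  expect_error(tt$set_reference(list()), "invalid")
})

test_that("end-to-end synthetic torsion recovery within 0.1 deg, robust to occlusion", {
  s <- set_setting(default_settings(), pipeline.track_torsion = TRUE)
  pl <- vog_pipeline(s)
  ref_img <- render_frame(test_scene())$image
  pl$process(new_frame(0, 0, "left", ref_img))  # sets reference
  for (delta in c(-7.5, -2, 4.25)) {
    img <- render_frame(test_scene(torsion_deg = delta))$image
    d <- pl$process(new_frame(1, 0, "left", img))
    expect_equal(d$torsion_deg, delta, tolerance = 0.1)
  }
  # masking a contiguous quarter of angles barely moves the estimate
  img <- render_frame(test_scene(torsion_deg = 4.25))$image
  pup <- track_pupil(img)$ellipse
  ann <- vogkit:::torsion_annulus(pup, s)
  pol <- unwrap_polar(img, pup$center, ann$r_inner, ann$r_outer)
  prof <- iris_profile(pol)
  prof$values[1:180] <- NA; prof$valid[1:180] <- FALSE  # 25% sector
  full <- pl$state$torsion$measure(iris_profile(pol))
  occl <- pl$state$torsion$measure(prof)
  expect_true(occl$valid)
  expect_lt(abs(occl$torsion_deg - full$torsion_deg), 0.2)
})
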
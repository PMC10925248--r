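test_that("binarize_dark is a strict threshold", {
  img <- flat_image(200)
  expect_false(any(binarize_dark(img, 100)))
  expect_false(any(binarize_dark(img, 0)))  # strict <: nothing below 0
  disk <- stamp_disk(flat_image(200), 30, 20, 8, 10)
  m <- binarize_dark(disk, 100)
  expect_identical(m, disk < 100)
  expect_true(any(m))
  # monotone: raising the threshold never shrinks the mask
  set.seed(3)
  noisy <- matrix(sample.int(256, 40 * 40, TRUE) - 1L, 40, 40)
  m1 <- binarize_dark(noisy, 60); m2 <- binarize_dark(noisy, 160)
  expect_true(all(m2[m1]))
})

test_that("component selection filters by area and largest wins", {
  img <- flat_image(200, 120, 80)
  img <- stamp_disk(img, 25, 40, 9.5, 10)    # area ~ 284
  img <- stamp_disk(img, 85, 40, 17, 10)     # area ~ 908
  mask <- binarize_dark(img, 100)
  comp <- find_pupil_component(mask, 500, 2000)
  expect_false(is.null(comp))
  expect_equal(mean(comp$xs), 85, tolerance = 0.01)
  expect_null(find_pupil_component(mask, 2000, 5000))
})

test_that("equal-area ties break toward the image centre", {
  mask <- matrix(FALSE, 41, 61)
  # two 3x3 squares: one at the exact centre, one near the corner
  mask[20:22, 30:32] <- TRUE
  mask[2:4, 2:4] <- TRUE
  comp <- find_pupil_component(mask, 1, 100)
  expect_equal(mean(comp$xs), 30)
  expect_equal(mean(comp$ys), 20)
})

test_that("pupil_centroid equals the brute-force pixel average", {
  # L-shaped blob enumerated explicitly
  pts <- rbind(cbind(0:4, 0), cbind(0, 1:3))  # (x, y) pairs
  comp <- list(xs = pts[, 1], ys = pts[, 2], area = nrow(pts))
  oracle <- colMeans(pts)
  expect_equal(pupil_centroid(comp), unname(oracle))
  # 2x2 square
  comp2 <- list(xs = c(0, 1, 0, 1), ys = c(0, 0, 1, 1), area = 4)
  expect_equal(pupil_centroid(comp2), c(0.5, 0.5))
  expect_error(pupil_centroid(list(xs = numeric(0), ys = numeric(0), area = 0)),
               "empty")
})

test_that("fit_ellipse recovers analytic boundary points to 1e-6", {
  pts <- ellipse_points(c(100, 80), 40, 25, 30, n = 36)
  e <- fit_ellipse(pts)
  expect_equal(e$center, c(100, 80), tolerance = 1e-6)
  expect_equal(e$major, 40, tolerance = 1e-6)
  expect_equal(e$minor, 25, tolerance = 1e-6)
  expect_equal(e$angle_deg, 30, tolerance = 1e-5)
  # exact circle: axes equal, any angle accepted
  circ <- ellipse_points(c(0, 0), 10, 10, 0, n = 24)
  ec <- fit_ellipse(circ)
  expect_equal(ec$center, c(0, 0), tolerance = 1e-6)
  expect_equal(ec$major, 10, tolerance = 1e-6)
  expect_equal(ec$minor, 10, tolerance = 1e-6)
  expect_error(fit_ellipse(pts[1:4, ]), ">= 5")
  expect_error(fit_ellipse(cbind(1:9, 2 * (1:9))), "degenerate|collinear|ellipse")
})

test_that("convex hull handles convex, notched and degenerate components", {
  scene <- test_scene()
  img <- render_frame(scene)$image
  mask <- morph_open3(binarize_dark(img, 80))
  comp <- find_pupil_component(mask, 200, 50000)
  hull <- pupil_convex_hull(comp)
  expect_true(hull$found)
  # hull contains every component pixel (within half-pixel tolerance)
  expect_equal(hull$ellipse$center, pupil_centroid(comp), tolerance = 0.5)

  collinear <- list(xs = c(0, 1, 2), ys = c(0, 1, 2), area = 3)
  expect_false(pupil_convex_hull(collinear)$found)
})

test_that("on a notched pupil, hull and ellipse-fit beat the centroid", {
  scene <- test_scene(eyelid_coverage = 0.3)
  out <- render_frame(scene)
  truth <- c(out$truth$pupil_x, out$truth$pupil_y)
  errs <- vapply(c("centroid", "convex_hull", "ellipse_fit"), function(m) {
    r <- track_pupil(out$image, method = m)
    sqrt(sum((r$ellipse$center - truth)^2))
  }, numeric(1))
  expect_lt(errs[["convex_hull"]], errs[["centroid"]])
  expect_lt(errs[["ellipse_fit"]], errs[["centroid"]])
})

test_that("all three methods agree on a clean synthetic pupil", {
  out <- render_frame(test_scene())
  truth <- c(out$truth$pupil_x, out$truth$pupil_y)
  centers <- lapply(c("centroid", "convex_hull", "ellipse_fit"), function(m) {
    r <- track_pupil(out$image, method = m)
    expect_true(r$found)
    r$ellipse$center
  })
  for (ctr in centers) expect_lt(sqrt(sum((ctr - truth)^2)), 0.5)
  expect_lt(sqrt(sum((centers[[1]] - centers[[3]])^2)), 1)
})

test_that("blink frames give found = FALSE / pupil_not_found", {
  r <- track_pupil(flat_image(220, 360, 360))
  expect_false(r$found)
  pl <- vog_pipeline(default_settings())
  d <- pl$process(new_frame(0, 0, "left", flat_image(220, 360, 360)))
  expect_equal(d$quality, "pupil_not_found")
  expect_true(is.nan(vogkit:::datum_to_row(d)$pupil_x))
})

test_that("detection is translation-equivariant and rotation-consistent", {
  out <- render_frame(test_scene())
  r0 <- track_pupil(out$image)
  shifted <- translate_image(out$image, 7, -3, fill = 200)
  r1 <- track_pupil(shifted)
  expect_equal(r1$ellipse$center - r0$ellipse$center, c(7, -3),
               tolerance = 1e-6)

  fr <- new_frame(0, 0, "left", out$image)
  rot <- preprocess_frame(fr, source_geometry(rotation = 90))[[1]]
  r90 <- track_pupil(rot$image)
  H <- nrow(out$image)
  expect_equal(r90$ellipse$center,
               c(H - 1 - r0$ellipse$center[2], r0$ellipse$center[1]),
               tolerance = 0.2)
})
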
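test_that("raw video round-trip is pixel-exact for AVI and PGM sequences", {
  set.seed(11)
  imgs <- lapply(1:10, function(i) {
    matrix(sample.int(256, 45 * 61, replace = TRUE) - 1L, 45, 61)
  })
  avi <- withr::local_tempfile(fileext = ".avi")
  write_raw_video(avi, imgs)
  expect_identical(read_avi_y8(avi), imgs)

  dir <- withr::local_tempdir()
  write_raw_video(dir, imgs)
  src <- open_video(dir)
  back <- list()
  while (!is.null(f <- src$grab())) back[[length(back) + 1L]] <- f$image
  expect_identical(back, imgs)
})

test_that("empty frame lists and mixed shapes are handled", {
  avi <- withr::local_tempfile(fileext = ".avi")
  write_raw_video(avi, list())
  expect_length(read_avi_y8(avi), 0)
  expect_error(write_raw_video(avi, list(flat_image(0, 10, 10),
                                         flat_image(0, 11, 10))),
               "shape")
})

test_that("open_video assigns frame numbers and side-car timestamps", {
  imgs <- lapply(1:50, function(i) flat_image(i %% 256, 16, 12))
  avi <- withr::local_tempfile(fileext = ".avi")
  write_raw_video(avi, imgs)
  src <- open_video(avi, fps = 500)
  expect_equal(src$n_frames, 50)
  f0 <- src$grab(); f1 <- src$grab()
  expect_equal(f0$frame_number, 0L)
  expect_equal(f1$frame_number, 1L)
  expect_equal(f1$timestamp, 1 / 500)
  expect_equal(dim(f0$image), dim(f1$image))

  ts <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(seq(0, by = 0.002, length.out = 50), digits = 10), ts)
  src2 <- open_video(avi, timestamps_path = ts)
  expect_equal(src2$grab()$timestamp, 0)
  expect_equal(src2$grab()$timestamp, 0.002)

  writeLines("0.0", ts)  # wrong count
  expect_error(open_video(avi, timestamps_path = ts), "count")
})

test_that("corrupt or compressed containers are rejected with the codec named", {
  bad <- withr::local_tempfile(fileext = ".avi")
  writeBin(as.raw(1:64), bad)
  expect_error(read_avi_y8(bad), "RIFF")
  # forge a compressed fourcc in an otherwise valid file
  ok <- withr::local_tempfile(fileext = ".avi")
  write_raw_video(ok, list(flat_image(7, 8, 8)))
  bytes <- readBin(ok, "raw", file.info(ok)$size)
  at <- grepRaw("DIB ", bytes)[1]
  bytes[at:(at + 3)] <- charToRaw("MJPG")
  writeBin(bytes, ok)
  expect_error(read_avi_y8(ok), "MJPG")
})

test_that("preprocess splits, crops, rotates and flips in the stated order", {
  img <- matrix(0L, 540, 720)
  img[, 1:360] <- 10L; img[, 361:720] <- 20L
  fr <- new_frame(0, 0, "both", img)
  halves <- preprocess_frame(fr, source_geometry(split = "left_right_halves"))
  expect_length(halves, 2)
  expect_equal(dim(halves[[1]]$image), c(540, 360))
  expect_equal(halves[[1]]$eye, "left")
  expect_true(all(halves[[1]]$image == 10L))
  expect_true(all(halves[[2]]$image == 20L))

  # crop [100,200)x[100,200): (0,0) of the output is original (100,100)
  set.seed(2)
  img2 <- matrix(sample.int(256, 300 * 300, TRUE) - 1L, 300, 300)
  fr2 <- new_frame(0, 0, "left", img2)
  out <- preprocess_frame(fr2, source_geometry(
    crop = list(x0 = 100, x1 = 200, y0 = 100, y1 = 200)))[[1]]
  expect_equal(dim(out$image), c(100, 100))
  expect_equal(out$image[1, 1], img2[101, 101])
  expect_equal(out$image[100, 100], img2[200, 200])
  expect_error(preprocess_frame(fr2, source_geometry(
    crop = list(x0 = 250, x1 = 350, y0 = 0, y1 = 50))), "bounds")

  # rotation 180 twice is the identity; 90 composes to 180
  r180 <- preprocess_frame(fr2, source_geometry(rotation = 180))[[1]]
  r180b <- preprocess_frame(r180, source_geometry(rotation = 180))[[1]]
  expect_identical(r180b$image, img2)
  r90 <- preprocess_frame(fr2, source_geometry(rotation = 90))[[1]]
  r90b <- preprocess_frame(r90, source_geometry(rotation = 90))[[1]]
  expect_identical(r90b$image, r180$image)

  # flips are involutions
  fh <- preprocess_frame(fr2, source_geometry(flip = "horizontal"))[[1]]
  fh2 <- preprocess_frame(fh, source_geometry(flip = "horizontal"))[[1]]
  expect_identical(fh2$image, img2)
})
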
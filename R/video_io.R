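#' Lossless video input/output
#'
#' Raw eye videos must survive a write/read round-trip bit-identically so
#' recordings can be reprocessed offline without loss. Two open containers
#' are supported: uncompressed 8-bit grayscale AVI (fourcc `DIB `, palettized
#' bottom-up DIB frames) and PGM (P5) image sequences named
#' `frame_%06d.pgm`. Compressed codecs are deliberately unsupported.
#'
#' @name video_io
NULL

u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")

# bottom-up, 4-byte padded rows, as a raw vector
dib_pack <- function(image) {
  h <- nrow(image); w <- ncol(image)
  stride <- ((w + 3) %/% 4) * 4
  out <- raw(stride * h)
  for (r in seq_len(h)) {
    # DIB rows run bottom-up
    row <- image[h - r + 1L, ]
    out[((r - 1L) * stride + 1L):((r - 1L) * stride + w)] <- as.raw(row)
  }
  out
}

dib_unpack <- function(bytes, w, h) {
  stride <- ((w + 3) %/% 4) * 4
  m <- matrix(0L, nrow = h, ncol = w)
  for (r in seq_len(h)) {
    row <- bytes[((r - 1L) * stride + 1L):((r - 1L) * stride + w)]
    m[h - r + 1L, ] <- as.integer(row)
  }
  m
}

#' Write an uncompressed grayscale AVI
#'
#' @param path output `.avi` path
#' @param frames list of integer matrices (identical dimensions, 0-255)
#' @param fps nominal frame rate for the header
#' @return `path`, invisibly
#' @export
write_avi_y8 <- function(path, frames, fps = 500) {
  if (length(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stopf("all frames must share one shape; got %s",
            paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", "))
    }
    rng <- range(vapply(frames, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 255) stopf("pixel values must lie in [0, 255]")
    h <- dims[1, 1]; w <- dims[2, 1]
  } else {
    h <- 0L; w <- 0L
  }
  n <- length(frames)
  stride <- ((w + 3) %/% 4) * 4
  frame_bytes <- stride * h
  con <- file(path, "wb")
  on.exit(close(con))

  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))  # grayscale BGRA palette
  strf_size <- 40 + 256 * 4
  strl_size <- 4 + (8 + 56) + (8 + strf_size)
  hdrl_size <- 4 + (8 + 56) + (8 + strl_size)
  movi_size <- 4 + n * (8 + frame_bytes)
  idx1_size <- n * 16
  riff_size <- 4 + (8 + hdrl_size) + (8 + movi_size) + (8 + idx1_size)

  writeChar("RIFF", con, eos = NULL); u32(con, riff_size)
  writeChar("AVI ", con, eos = NULL)
  writeChar("LIST", con, eos = NULL); u32(con, hdrl_size)
  writeChar("hdrl", con, eos = NULL)
  # avih: MainAVIHeader (56 bytes)
  writeChar("avih", con, eos = NULL); u32(con, 56)
  usec <- if (fps > 0) round(1e6 / fps) else 0
  u32(con, usec)                 # microseconds per frame
  u32(con, frame_bytes * fps)    # max bytes per second
  u32(con, 0)                    # padding granularity
  u32(con, 16)                   # flags: AVIF_HASINDEX
  u32(con, n)                    # total frames
  u32(con, 0)                    # initial frames
  u32(con, 1)                    # streams
  u32(con, frame_bytes)          # suggested buffer size
  u32(con, w); u32(con, h)
  u32(con, c(0, 0, 0, 0))        # reserved
  writeChar("LIST", con, eos = NULL); u32(con, strl_size)
  writeChar("strl", con, eos = NULL)
  # strh: AVIStreamHeader (56 bytes)
  writeChar("strh", con, eos = NULL); u32(con, 56)
  writeChar("vids", con, eos = NULL)
  writeChar("DIB ", con, eos = NULL)
  u32(con, c(0, 0, 0))           # flags, priority+language, initial frames
  u32(con, 1); u32(con, round(fps))  # scale, rate
  u32(con, 0); u32(con, n)       # start, length
  u32(con, frame_bytes)          # suggested buffer size
  u32(con, 4294967295 - 4294967296)  # quality -1
  u32(con, 0)                    # sample size
  u16(con, c(0, 0, 0, 0))        # rcFrame
  # strf: BITMAPINFOHEADER + palette
  writeChar("strf", con, eos = NULL); u32(con, strf_size)
  u32(con, 40)                   # biSize
  u32(con, w); u32(con, h)
  u16(con, 1); u16(con, 8)       # planes, bit count
  u32(con, 0)                    # biCompression = BI_RGB (uncompressed)
  u32(con, frame_bytes)
  u32(con, 0); u32(con, 0)       # ppm
  u32(con, 256); u32(con, 256)   # colours used / important
  writeBin(pal, con)
  # movi
  writeChar("LIST", con, eos = NULL); u32(con, movi_size)
  writeChar("movi", con, eos = NULL)
  for (f in frames) {
    writeChar("00db", con, eos = NULL); u32(con, frame_bytes)
    writeBin(dib_pack(f), con)
  }
  # idx1
  writeChar("idx1", con, eos = NULL); u32(con, idx1_size)
  off <- 4
  for (i in seq_len(n)) {
    writeChar("00db", con, eos = NULL)
    u32(con, 16)                 # AVIIF_KEYFRAME
    u32(con, off); u32(con, frame_bytes)
    off <- off + 8 + frame_bytes
  }
  invisible(path)
}

#' Read an uncompressed grayscale AVI
#'
#' Only fourcc `DIB `/`Y8 `/BI_RGB 8-bit streams are accepted; any other
#' codec is an error naming the fourcc (lossy containers are out of scope).
#'
#' @param path `.avi` path
#' @return list of integer matrices
#' @export
read_avi_y8 <- function(path) {
  if (!file.exists(path)) stopf("video not found: %s", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  gettag <- function(at) {
    r <- bytes[at:(at + 3)]
    r[r == as.raw(0)] <- as.raw(32)  # fourcc may be all-null (= BI_RGB)
    rawToChar(r)
  }
  getu32 <- function(at) {
    sum(as.numeric(bytes[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  }
  if (length(bytes) < 12 || gettag(1) != "RIFF" || gettag(9) != "AVI ") {
    stopf("%s is not an AVI/RIFF file", path)
  }
  w <- NULL; h <- NULL; n_expected <- NULL
  frames <- list()
  # walk top-level and nested LIST chunks
  walk <- function(at, end) {
    while (at + 8 <= end) {
      tag <- gettag(at); size <- getu32(at + 4)
      body <- at + 8
      if (tag == "LIST") {
        ltype <- gettag(body)
        walk(body + 4, body + size)
      } else if (tag == "strh") {
        fourcc <- gettag(body + 4)
        if (!fourcc %in% c("DIB ", "Y8  ", "    ")) {
          stopf("unsupported codec '%s' in %s: only uncompressed DIB/Y8 is readable",
                trimws(fourcc), path)
        }
      } else if (tag == "strf") {
        w <<- getu32(body + 4); h <<- getu32(body + 8)
        compression <- getu32(body + 16)
        if (compression != 0) stopf("compressed AVI stream (biCompression=%d) unsupported", compression)
      } else if (tag %in% c("00db", "00dc")) {
        frames[[length(frames) + 1L]] <<- bytes[body:(body + size - 1L)]
      }
      at <- body + size + (size %% 2)  # chunks are word-aligned
    }
  }
  walk(13, 12 + getu32(5))
  if (is.null(w)) stopf("no video stream format found in %s", path)
  lapply(frames, dib_unpack, w = w, h = h)
}

pgm_path <- function(dir, i) file.path(dir, sprintf("frame_%06d.pgm", i))

write_pgm <- function(path, image) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con, eos = NULL)
  writeBin(as.raw(t(image)), con)  # P5 is row-major top-down
  invisible(path)
}

read_pgm <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header: "P5" ws width ws height ws maxval single-ws, then binary pixels
  ws <- as.raw(c(9, 10, 13, 32))
  pos <- 1L
  token <- function() {
    while (pos <= length(bytes) && bytes[pos] %in% ws) pos <<- pos + 1L
    start <- pos
    while (pos <= length(bytes) && !bytes[pos] %in% ws) pos <<- pos + 1L
    rawToChar(bytes[start:(pos - 1L)])
  }
  magic <- token(); wt <- token(); ht <- token(); mx <- token()
  if (magic != "P5" || is.na(suppressWarnings(as.integer(wt)))) {
    stopf("%s is not a binary PGM (P5)", path)
  }
  w <- as.integer(wt); h <- as.integer(ht)
  pos <- pos + 1L  # single whitespace after maxval
  data <- bytes[pos:(pos + w * h - 1L)]
  matrix(as.integer(data), nrow = h, ncol = w, byrow = TRUE)
}

#' Write frames as raw (lossless) video
#'
#' Dispatches on `path`: `*.avi` writes one uncompressed AVI; any other
#' path is treated as a directory receiving a `frame_%06d.pgm` sequence.
#' The round-trip through [open_video()] is pixel-exact.
#'
#' @param path output path (file or directory)
#' @param frames list of integer matrices, or list of `vog_frame`s
#' @param fps nominal frame rate recorded in the container
#' @return `path`, invisibly
#' @export
write_raw_video <- function(path, frames, fps = 500) {
  imgs <- lapply(frames, function(f) if (inherits(f, "vog_frame")) f$image else f)
  if (length(imgs)) {
    dims <- vapply(imgs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stopf("all frames must share one shape")
    }
  }
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    write_avi_y8(path, imgs, fps = fps)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(imgs)) write_pgm(pgm_path(path, i - 1L), imgs[[i]])
  }
  invisible(path)
}

#' Open a recorded video as a frame source
#'
#' Accepts an uncompressed AVI or a directory of `frame_%06d.pgm` images.
#' Timestamps come from a side-car file (one float, seconds, per line) when
#' given, else `frame_number / fps`.
#'
#' @param path video file or image-sequence directory
#' @param timestamps_path optional side-car timestamp file
#' @param fps nominal frame rate used when no timestamps are supplied
#' @param eye eye label stamped on emitted frames
#' @return a `vog_source`: environment with `$grab()` (returns a
#'   `vog_frame` or `NULL` at end) and `$n_frames`
#' @export
open_video <- function(path, timestamps_path = NULL, fps = 500, eye = "left") {
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    imgs <- read_avi_y8(path)
  } else if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_\\d{6}\\.pgm$", full.names = TRUE))
    imgs <- lapply(files, read_pgm)
  } else {
    stopf("unsupported video path: %s (expect .avi or a pgm-sequence directory)", path)
  }
  n <- length(imgs)
  if (!is.null(timestamps_path)) {
    ts <- as.numeric(readLines(timestamps_path, warn = FALSE))
    if (length(ts) != n) {
      stopf("timestamp count (%d) does not match frame count (%d)", length(ts), n)
    }
    if (anyNA(ts)) stopf("unparseable timestamp in %s", timestamps_path)
  } else {
    ts <- (seq_len(n) - 1) / fps
  }
  frame_source(imgs, timestamps = ts, eye = eye)
}

#' In-memory frame source
#'
#' Wraps a list of images (or `vog_frame`s) as a source usable by
#' [run_session()].
#'
#' @param images list of integer matrices or `vog_frame`s
#' @param timestamps per-frame seconds (default `frame_number / fps`)
#' @param fps used when `timestamps` is `NULL`
#' @param eye eye label
#' @return a `vog_source`
#' @export
frame_source <- function(images, timestamps = NULL, fps = 500, eye = "left") {
  if (is.null(timestamps)) timestamps <- (seq_along(images) - 1) / fps
  stopifnot(length(timestamps) == length(images))
  src <- new.env(parent = emptyenv())
  src$n_frames <- length(images)
  src$pos <- 0L
  src$grab <- function() {
    if (src$pos >= src$n_frames) return(NULL)
    i <- src$pos + 1L
    src$pos <- src$pos + 1L
    f <- images[[i]]
    if (inherits(f, "vog_frame")) return(f)
    new_frame(i - 1L, timestamps[i], eye, f)
  }
  class(src) <- "vog_source"
  src
}

#' Geometric source preprocessing
#'
#' Maps raw camera frames to per-eye frames in the fixed order
#' split -> crop -> rotate -> flip. A both-eye frame is split into
#' left/right halves before any cropping; crop rectangles are half-open
#' `[x0, x1) x [y0, y1)` in 0-based pixel coordinates.
#'
#' @param split `"none"` or `"left_right_halves"`
#' @param crop `NULL` or a list `(x0, x1, y0, y1)`; for split frames a list
#'   of two such rectangles (left, right), applied after the split
#' @param rotation 0, 90, 180 or 270 (degrees, clockwise in image coords)
#' @param flip `"none"`, `"horizontal"` or `"vertical"`
#' @return a `vog_geometry`
#' @export
source_geometry <- function(split = "none", crop = NULL, rotation = 0,
                            flip = "none") {
  stopifnot(split %in% c("none", "left_right_halves"),
            rotation %in% c(0, 90, 180, 270),
            flip %in% c("none", "horizontal", "vertical"))
  structure(list(split = split, crop = crop, rotation = rotation, flip = flip),
            class = "vog_geometry")
}

rotate_image <- function(image, rotation) {
  switch(as.character(rotation),
    "0" = image,
    # 90 deg clockwise in display terms: new[y', x'] with x' = H-1-y, y' = x
    "90" = t(image)[, rev(seq_len(nrow(image))), drop = FALSE],
    "180" = image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))), drop = FALSE],
    "270" = t(image)[rev(seq_len(ncol(image))), , drop = FALSE]
  )
}

crop_image <- function(image, rect) {
  h <- nrow(image); w <- ncol(image)
  if (rect$x0 < 0 || rect$y0 < 0 || rect$x1 > w || rect$y1 > h ||
      rect$x1 <= rect$x0 || rect$y1 <= rect$y0) {
    stopf("crop [%g,%g)x[%g,%g) outside %dx%d frame bounds",
          rect$x0, rect$x1, rect$y0, rect$y1, w, h)
  }
  image[(rect$y0 + 1):rect$y1, (rect$x0 + 1):rect$x1, drop = FALSE]
}

#' Apply source geometry to a frame
#'
#' @param frame a `vog_frame`
#' @param geometry a [source_geometry()]
#' @return list of one (`split = "none"`) or two (left, right) `vog_frame`s
#' @export
preprocess_frame <- function(frame, geometry) {
  stopifnot(inherits(frame, "vog_frame"), inherits(geometry, "vog_geometry"))
  img <- frame$image
  if (geometry$split == "left_right_halves") {
    w <- ncol(img)
    halves <- list(left = img[, 1:(w %/% 2), drop = FALSE],
                   right = img[, (w %/% 2 + 1):w, drop = FALSE])
  } else {
    halves <- stats::setNames(list(img), frame$eye)
  }
  crops <- geometry$crop
  if (!is.null(crops) && !is.null(crops$x0)) crops <- list(crops)  # one rect
  out <- vector("list", length(halves))
  for (i in seq_along(halves)) {
    im <- halves[[i]]
    if (!is.null(crops)) im <- crop_image(im, crops[[min(i, length(crops))]])
    im <- rotate_image(im, geometry$rotation)
    if (geometry$flip == "horizontal") im <- im[, rev(seq_len(ncol(im))), drop = FALSE]
    if (geometry$flip == "vertical") im <- im[rev(seq_len(nrow(im))), , drop = FALSE]
    out[[i]] <- new_frame(frame$frame_number, frame$timestamp, names(halves)[i], im)
  }
  out
}
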
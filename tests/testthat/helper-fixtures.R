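# shared fixture builders (everything is generated in code; no binary data)

# uniform image of one value
flat_image <- function(value, w = 60, h = 40) matrix(as.integer(value), h, w)

# stamp a filled disk of a value onto an image (0-based center coords)
stamp_disk <- function(image, cx, cy, r, value) {
  X <- matrix(0:(ncol(image) - 1), nrow(image), ncol(image), byrow = TRUE)
  Y <- matrix(0:(nrow(image) - 1), nrow(image), ncol(image))
  image[(X - cx)^2 + (Y - cy)^2 <= r^2] <- as.integer(value)
  image
}

# integer translation with constant fill; new(x, y) = old(x - dx, y - dy)
translate_image <- function(image, dx, dy, fill) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(as.integer(fill), h, w)
  xs <- seq_len(w); ys <- seq_len(h)
  sx <- xs - dx; sy <- ys - dy
  okx <- sx >= 1 & sx <= w; oky <- sy >= 1 & sy <= h
  out[ys[oky], xs[okx]] <- image[sy[oky], sx[okx]]
  out
}

# analytic points on an ellipse boundary
ellipse_points <- function(center, a, b, angle_deg, n = 36) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ar <- angle_deg * pi / 180
  x <- center[1] + a * cos(t) * cos(ar) - b * sin(t) * sin(ar)
  y <- center[2] + a * cos(t) * sin(ar) + b * sin(t) * cos(ar)
  cbind(x, y)
}

# iris profile object built directly from a function of angle (degrees)
profile_from_function <- function(f, n_angles = 720, frame_number = 0L) {
  th <- 360 * (seq_len(n_angles) - 1) / n_angles
  vals <- f(th)
  vals <- vals - mean(vals)
  structure(list(values = vals, valid = rep(TRUE, n_angles),
                 frame_number = frame_number),
            class = "vog_iris_profile")
}

# scene used across tests: defaults, optionally eccentric/noisy
test_scene <- function(...) synthetic_scene(...)
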
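#' Frames and per-frame tracking results
#'
#' A `vog_frame` is one grabbed image with its identity metadata; a
#' `vog_datum` is the per-frame, per-eye tracking result (pupil ellipse,
#' glints, torsion, Purkinje points, quality flag). Quality levels: `ok`,
#' `pupil_not_found`, `torsion_low_correlation`, `dropped` (buffer
#' overflow; carries no measurements), `error` (pipeline exception; carries
#' no measurements).
#'
#' @name frame
NULL

QUALITY_LEVELS <- c("ok", "pupil_not_found", "torsion_low_correlation",
                    "dropped", "error")

#' Construct a frame
#' @param frame_number non-negative integer, monotone per source
#' @param timestamp seconds
#' @param eye `"left"`, `"right"` or `"both"`
#' @param image integer matrix, 8-bit grayscale, `image[y+1, x+1]`
#' @return a `vog_frame`
#' @export
new_frame <- function(frame_number, timestamp, eye, image) {
  stopifnot(is_count(frame_number), is.numeric(timestamp),
            eye %in% c("left", "right", "both"), is.matrix(image))
  structure(list(frame_number = as.integer(frame_number),
                 timestamp = as.numeric(timestamp),
                 eye = eye, image = image),
            class = "vog_frame")
}

#' @export
print.vog_frame <- function(x, ...) {
  cat(sprintf("<vog_frame #%d eye=%s t=%.6fs %dx%d>\n", x$frame_number,
              x$eye, x$timestamp, img_width(x$image), img_height(x$image)))
  invisible(x)
}

#' Construct an ellipse
#'
#' Axes are semi-axis lengths in pixels (so a circle of radius 10 has
#' `major == minor == 10`); the angle is that of the major axis from +x
#' toward +y, normalized to [0, 180). If `minor > major` the axes are
#' swapped and the angle rotated by 90 degrees.
#'
#' @param center numeric length-2 `(x, y)` in pixels (sub-pixel)
#' @param major,minor semi-axes in pixels, positive
#' @param angle_deg major-axis angle in degrees
#' @return a `vog_ellipse`
#' @export
new_ellipse <- function(center, major, minor, angle_deg = 0) {
  stopifnot(length(center) == 2, is.finite(major), is.finite(minor),
            major > 0, minor > 0)
  if (minor > major) {
    tmp <- major; major <- minor; minor <- tmp
    angle_deg <- angle_deg + 90
  }
  angle_deg <- angle_deg %% 180
  structure(list(center = as.numeric(center), major = major, minor = minor,
                 angle_deg = angle_deg),
            class = "vog_ellipse")
}

#' @export
print.vog_ellipse <- function(x, ...) {
  cat(sprintf("<ellipse center=(%.2f, %.2f) semi-axes=(%.2f, %.2f) angle=%.1f deg>\n",
              x$center[1], x$center[2], x$major, x$minor, x$angle_deg))
  invisible(x)
}

#' Construct a per-frame tracking datum
#'
#' @param frame_number,timestamp,eye frame identity
#' @param pupil a `vog_ellipse` or `NULL`
#' @param glints list of glints (each with `$center`), possibly empty
#' @param torsion_deg degrees or `NA`
#' @param p1,p4 Purkinje reflection centers (length-2) or `NULL`
#' @param quality one of `"ok"`, `"pupil_not_found"`,
#'   `"torsion_low_correlation"`, `"dropped"`, `"error"`
#' @return a `vog_datum`
#' @export
new_datum <- function(frame_number, timestamp, eye, pupil = NULL,
                      glints = list(), torsion_deg = NA_real_,
                      p1 = NULL, p4 = NULL, quality = "ok") {
  stopifnot(quality %in% QUALITY_LEVELS)
  if (quality %in% c("dropped", "error")) {
    pupil <- NULL; glints <- list(); torsion_deg <- NA_real_
    p1 <- NULL; p4 <- NULL
  }
  if (is.null(pupil)) torsion_deg <- NA_real_  # torsion needs a pupil
  structure(list(frame_number = as.integer(frame_number),
                 timestamp = as.numeric(timestamp), eye = eye,
                 pupil = pupil, glints = glints,
                 torsion_deg = as.numeric(torsion_deg),
                 p1 = p1, p4 = p4, quality = quality),
            class = "vog_datum")
}

# flatten a datum to one data-file row (named list of scalars)
datum_to_row <- function(datum, h_deg = NA_real_, v_deg = NA_real_) {
  px <- function(obj, i) if (is.null(obj)) NaN else as.numeric(obj[i])
  pupil <- datum$pupil
  g1 <- if (length(datum$glints) >= 1) datum$glints[[1]]$center else NULL
  list(
    frame_number = datum$frame_number,
    timestamp_s = datum$timestamp,
    eye = datum$eye,
    pupil_x = if (is.null(pupil)) NaN else pupil$center[1],
    pupil_y = if (is.null(pupil)) NaN else pupil$center[2],
    pupil_major = if (is.null(pupil)) NaN else pupil$major,
    pupil_minor = if (is.null(pupil)) NaN else pupil$minor,
    pupil_angle = if (is.null(pupil)) NaN else pupil$angle_deg,
    glint1_x = px(g1, 1), glint1_y = px(g1, 2),
    torsion_deg = if (is.na(datum$torsion_deg)) NaN else datum$torsion_deg,
    p1_x = px(datum$p1, 1), p1_y = px(datum$p1, 2),
    p4_x = px(datum$p4, 1), p4_y = px(datum$p4, 2),
    h_deg = if (is.na(h_deg)) NaN else h_deg,
    v_deg = if (is.na(v_deg)) NaN else v_deg,
    quality = datum$quality
  )
}
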
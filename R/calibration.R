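#' Calibration: pixels to degrees
#'
#' Raw per-frame features (pupil centre, or pupil-CR vector) are mapped to
#' eye position in degrees of visual angle either by a geometric eye model
#' (pupil centre displaced along a sphere of radius `radius_px`:
#' `h = asin(dx / radius_px)`, `v = -asin(dy / radius_px)`; image y runs
#' down, gaze up is positive) or by per-axis polynomial regression against
#' known fixation targets. Torsion is re-zeroed by subtracting its value at
#' the reference position.
#'
#' @name calibration
NULL

#' Fit a geometric eye model
#'
#' The reference (primary-gaze) pupil position is the per-axis median of
#' fixation samples; the rotation radius comes from a setting or is
#' estimated from a known-amplitude fixation pair via
#' `radius_px = delta_px / sin(delta_deg)`.
#'
#' @param samples matrix/data.frame of pupil centres (x, y) during steady
#'   primary fixation; at least 10 rows
#' @param radius_px eyeball rotation radius in pixels
#' @param max_dispersion_px fixation stability gate: RMS distance of the
#'   samples from their median must not exceed this
#' @return a `vog_calibration` of type `"eye_model"`
#' @export
fit_eye_model <- function(samples, radius_px = 259.1, max_dispersion_px = 5) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stopf("no fixation samples")
  if (nrow(samples) < 10) stopf("need >= 10 fixation samples, got %d", nrow(samples))
  stopifnot(radius_px > 0)
  ctr <- c(median(samples[, 1]), median(samples[, 2]))
  disp <- sqrt(mean((samples[, 1] - ctr[1])^2 + (samples[, 2] - ctr[2])^2))
  if (disp > max_dispersion_px) {
    stopf("fixation unstable: dispersion %.2f px exceeds %.2f px",
          disp, max_dispersion_px)
  }
  structure(list(type = "eye_model", center_ref = ctr, radius_px = radius_px,
                 torsion_ref = 0, feature = "pupil"),
            class = "vog_calibration")
}

#' Estimate the rotation radius from two fixations
#' @param delta_px pixel distance between pupil centres at the two targets
#' @param delta_deg angular separation of the targets in degrees
#' @return radius in pixels, `delta_px / sin(delta_deg)`
#' @export
estimate_radius_px <- function(delta_px, delta_deg) {
  stopifnot(delta_px > 0, delta_deg > 0, delta_deg < 90)
  delta_px / sin(deg2rad(delta_deg))
}

#' Map a pupil centre through the eye model
#'
#' @param model `vog_calibration` of type `"eye_model"`
#' @param pupil_center `(x, y)` pixels
#' @return list `(h_deg, v_deg, in_range)`; out-of-range displacements
#'   (|delta| > radius) give `in_range = FALSE` and `NaN` angles
#' @export
model_pixels_to_degrees <- function(model, pupil_center) {
  stopifnot(model$type == "eye_model")
  dx <- pupil_center[1] - model$center_ref[1]
  dy <- pupil_center[2] - model$center_ref[2]
  if (abs(dx) > model$radius_px || abs(dy) > model$radius_px) {
    return(list(h_deg = NaN, v_deg = NaN, in_range = FALSE))
  }
  list(h_deg = rad2deg(asin(dx / model$radius_px)),
       v_deg = -rad2deg(asin(dy / model$radius_px)),
       in_range = TRUE)
}

#' Fit a regression calibration
#'
#' Per-axis polynomial least squares from raw features to target angles.
#' Degree 1 fits `h = a0 + a1 fx + a2 fy` (and likewise v); degree 2 adds
#' `fx^2` and `fy^2` (no cross-term). Refuses rank-deficient designs
#' (e.g. all targets on one line).
#'
#' @param raw matrix of aggregated raw features, one row per target
#'   (median over each fixation window)
#' @param targets matrix of known `(h_deg, v_deg)`, one row per target
#' @param degree 1 (default) or 2
#' @param feature `"pupil"` or `"pupil_cr"`: which raw feature this
#'   calibration consumes
#' @return a `vog_calibration` of type `"regression"` with per-axis
#'   coefficients and residual RMS (degrees)
#' @export
fit_regression <- function(raw, targets, degree = 1, feature = "pupil") {
  raw <- as.matrix(raw); targets <- as.matrix(targets)
  stopifnot(nrow(raw) == nrow(targets), ncol(raw) == 2, ncol(targets) == 2,
            degree %in% c(1, 2))
  if (nrow(raw) < 3) stopf("need >= 3 calibration targets, got %d", nrow(raw))
  X <- cbind(1, raw[, 1], raw[, 2])
  if (degree == 2) X <- cbind(X, raw[, 1]^2, raw[, 2]^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf("calibration targets are collinear/degenerate: design rank %d < %d",
          qrX$rank, ncol(X))
  }
  coefs <- qr.coef(qrX, targets)
  fitted <- X %*% coefs
  res <- targets - fitted
  rms_axis <- sqrt(colMeans(res^2))
  structure(list(type = "regression", degree = degree, feature = feature,
                 coef_h = coefs[, 1], coef_v = coefs[, 2],
                 residual_rms_deg = c(h = rms_axis[1], v = rms_axis[2]),
                 n_targets = nrow(raw), torsion_ref = 0),
            class = "vog_calibration")
}

#' @export
print.vog_calibration <- function(x, ...) {
  cat(sprintf("<vog_calibration type=%s feature=%s>\n", x$type,
              if (is.null(x$feature)) "pupil" else x$feature))
  if (x$type == "regression") {
    cat(sprintf("  %d targets, residual RMS h=%.4f v=%.4f deg\n",
                x$n_targets, x$residual_rms_deg[1], x$residual_rms_deg[2]))
  } else {
    cat(sprintf("  center_ref=(%.2f, %.2f) radius_px=%.2f\n",
                x$center_ref[1], x$center_ref[2], x$radius_px))
  }
  invisible(x)
}

regression_predict <- function(cal, feat) {
  X <- c(1, feat[1], feat[2])
  if (cal$degree == 2) X <- c(X, feat[1]^2, feat[2]^2)
  c(h = sum(X * cal$coef_h), v = sum(X * cal$coef_v))
}

# pull the raw feature a calibration consumes out of a datum
datum_feature <- function(cal, datum) {
  feature <- if (is.null(cal$feature)) "pupil" else cal$feature
  if (is.null(datum$pupil)) return(NULL)
  pc <- datum$pupil$center
  if (feature == "pupil") return(pc)
  if (!length(datum$glints)) return(NULL)
  pupil_cr_vector(pc, datum$glints[[1]]$center)
}

#' Apply a calibration to a tracking datum
#'
#' @param cal a `vog_calibration`
#' @param datum a `vog_datum`
#' @return list `(h_deg, v_deg, torsion_deg, valid)`; missing features give
#'   `valid = FALSE` with `NaN` values
#' @export
apply_calibration <- function(cal, datum) {
  stopifnot(inherits(cal, "vog_calibration"))
  feat <- datum_feature(cal, datum)
  if (is.null(feat)) {
    return(list(h_deg = NaN, v_deg = NaN, torsion_deg = NaN, valid = FALSE))
  }
  if (cal$type == "eye_model") {
    m <- model_pixels_to_degrees(cal, feat)
    hv <- c(m$h_deg, m$v_deg)
    ok <- m$in_range
  } else {
    hv <- regression_predict(cal, feat)
    ok <- all(is.finite(hv))
  }
  tors <- if (is.na(datum$torsion_deg)) NaN else datum$torsion_deg - cal$torsion_ref
  list(h_deg = unname(hv[1]), v_deg = unname(hv[2]), torsion_deg = tors,
       valid = isTRUE(ok))
}

#' Save / load a calibration file
#'
#' Plain text: `#`-prefixed header stating type, feature and sign
#' conventions, then `key = value` coefficient lines.
#'
#' @param cal a `vog_calibration`
#' @param path file path
#' @return `path` (save) or the calibration (load)
#' @export
save_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "vog_calibration"))
  lines <- c("# vogkit calibration v1",
             "# conventions: h positive rightward (image +x), v positive upward (image -y)",
             sprintf("type = %s", cal$type),
             sprintf("feature = %s", if (is.null(cal$feature)) "pupil" else cal$feature),
             sprintf("torsion_ref = %s", fmt_num(cal$torsion_ref)))
  if (cal$type == "eye_model") {
    lines <- c(lines,
               sprintf("center_ref = %s %s", fmt_num(cal$center_ref[1]), fmt_num(cal$center_ref[2])),
               sprintf("radius_px = %s", fmt_num(cal$radius_px)))
  } else {
    lines <- c(lines,
               sprintf("degree = %d", cal$degree),
               sprintf("coef_h = %s", paste(fmt_num(cal$coef_h), collapse = " ")),
               sprintf("coef_v = %s", paste(fmt_num(cal$coef_v), collapse = " ")),
               sprintf("residual_rms_deg = %s", paste(fmt_num(cal$residual_rms_deg), collapse = " ")),
               sprintf("n_targets = %d", cal$n_targets))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stopf("calibration file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (is.null(kv$type)) stopf("calibration file %s missing 'type'", path)
  if (kv$type == "eye_model") {
    cr <- nums(kv$center_ref)
    cal <- structure(list(type = "eye_model", center_ref = cr,
                          radius_px = nums(kv$radius_px),
                          torsion_ref = nums(kv$torsion_ref),
                          feature = kv$feature),
                     class = "vog_calibration")
  } else if (kv$type == "regression") {
    cal <- structure(list(type = "regression", degree = as.integer(kv$degree),
                          feature = kv$feature,
                          coef_h = nums(kv$coef_h), coef_v = nums(kv$coef_v),
                          residual_rms_deg = {
                            r <- nums(kv$residual_rms_deg)
                            names(r) <- c("h", "v"); r
                          },
                          n_targets = as.integer(kv$n_targets),
                          torsion_ref = nums(kv$torsion_ref)),
                     class = "vog_calibration")
  } else {
    stopf("unknown calibration type '%s' in %s", kv$type, path)
  }
  cal
}

#' Read a fixation-target schedule
#'
#' One target per line: `t_start t_end h_deg v_deg` (seconds, degrees),
#' whitespace separated, `#` comments allowed.
#'
#' @param path schedule file
#' @return data.frame with columns `t_start`, `t_end`, `h_deg`, `v_deg`
#' @export
read_target_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (length(v) != 4 || anyNA(v)) {
      stopf("target schedule %s line %d: expected 't_start t_end h_deg v_deg'",
            path, i)
    }
    v
  })
  m <- do.call(rbind, rows)
  data.frame(t_start = m[, 1], t_end = m[, 2], h_deg = m[, 3], v_deg = m[, 4])
}

#' Behavioural calibration from a recording and a target schedule
#'
#' For each scheduled target, samples in the middle 50 percent of the dwell
#' are aggregated by the per-axis median of the raw feature; the aggregated
#' points are fit with [fit_regression()].
#'
#' @param rows data-file rows (see [read_rows()])
#' @param schedule data.frame from [read_target_schedule()]
#' @param feature `"pupil"` or `"pupil_cr"`
#' @param degree polynomial degree passed to [fit_regression()]
#' @return a `vog_calibration`
#' @export
calibrate_from_recording <- function(rows, schedule, feature = "pupil",
                                     degree = 1) {
  feats <- matrix(NA_real_, nrow(schedule), 2)
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$t_start[i]; t1 <- schedule$t_end[i]
    lo <- t0 + 0.25 * (t1 - t0); hi <- t0 + 0.75 * (t1 - t0)
    sel <- rows$timestamp_s >= lo & rows$timestamp_s <= hi & rows$quality == "ok"
    if (!any(sel)) stopf("no usable samples for target %d (%.2f-%.2fs)", i, t0, t1)
    if (feature == "pupil") {
      feats[i, ] <- c(median(rows$pupil_x[sel]), median(rows$pupil_y[sel]))
    } else {
      feats[i, ] <- c(median(rows$pupil_x[sel] - rows$glint1_x[sel]),
                      median(rows$pupil_y[sel] - rows$glint1_y[sel]))
    }
  }
  fit_regression(feats, cbind(schedule$h_deg, schedule$v_deg),
                 degree = degree, feature = feature)
}
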
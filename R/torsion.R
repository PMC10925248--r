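#' Ocular torsion from the iris pattern
#'
#' Torsion (cyclorotation about the line of sight) is measured by
#' unwrapping an annulus of iris around the pupil into polar coordinates,
#' collapsing it to a 1-D angular intensity profile, and circularly
#' cross-correlating that profile against a stored reference profile. The
#' shift of the correlation peak, refined by parabolic interpolation, is
#' the torsion angle. Positive torsion is a rotation of the iris pattern
#' toward increasing polar angle (`atan2(y - cy, x - cx)` in image
#' coordinates, i.e. from +x toward +y).
#'
#' @name torsion
NULL

#' Unwrap an iris annulus to polar coordinates
#'
#' Sample `(k, m)` is the bilinear interpolation of the image at
#' `center + radius_k * (cos theta_m, sin theta_m)` with
#' `theta_m = 360 m / n_angles` degrees. Samples falling outside the image
#' are masked invalid.
#'
#' @param image 8-bit grayscale integer matrix
#' @param center pupil centre `(x, y)` in pixels
#' @param r_inner,r_outer annulus radii in pixels, `r_outer > r_inner > 0`
#' @param n_angles angular samples over \[0, 360)
#' @param n_radii radial samples over \[r_inner, r_outer\]
#' @return a `vog_polar`: `raster` (n_radii x n_angles), `valid` mask,
#'   `angles_deg`, `radii`
#' @export
unwrap_polar <- function(image, center, r_inner, r_outer,
                         n_angles = 720, n_radii = 20) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  h <- nrow(image); w <- ncol(image)
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 || center[2] > h - 1) {
    stopf("annulus centre (%.1f, %.1f) outside image", center[1], center[2])
  }
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rad <- seq(r_inner, r_outer, length.out = n_radii)
  xs <- center[1] + outer(rad, cos(ang))          # n_radii x n_angles
  ys <- center[2] + outer(rad, sin(ang))
  valid <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  if (!any(valid)) stopf("annulus entirely outside image")
  x0 <- floor(pmin(pmax(xs, 0), w - 1 - 1e-9))
  y0 <- floor(pmin(pmax(ys, 0), h - 1 - 1e-9))
  fx <- xs - x0; fy <- ys - y0
  iv <- function(dx, dy) {
    as.numeric(image[cbind(as.vector(y0 + dy) + 1L, as.vector(x0 + dx) + 1L)])
  }
  v <- (1 - as.vector(fx)) * (1 - as.vector(fy)) * iv(0, 0) +
       as.vector(fx) * (1 - as.vector(fy)) * iv(1, 0) +
       (1 - as.vector(fx)) * as.vector(fy) * iv(0, 1) +
       as.vector(fx) * as.vector(fy) * iv(1, 1)
  raster <- matrix(v, nrow = n_radii)
  raster[!valid] <- NA_real_
  structure(list(raster = raster, valid = valid,
                 angles_deg = rad2deg(ang), radii = rad),
            class = "vog_polar")
}

#' Collapse a polar iris image to an angular profile
#'
#' Per-angle mean over valid radii; an angle is masked when fewer than half
#' of its radial samples are valid. The profile is mean-subtracted over its
#' valid angles.
#'
#' @param polar a `vog_polar` from [unwrap_polar()]
#' @param frame_number source frame recorded for provenance
#' @return a `vog_iris_profile`: `values` (length n_angles, NA at masked
#'   angles), `valid`, `frame_number`
#' @export
iris_profile <- function(polar, frame_number = NA_integer_) {
  stopifnot(inherits(polar, "vog_polar"))
  n_radii <- nrow(polar$raster)
  n_valid <- colSums(polar$valid)
  vals <- colSums(ifelse(polar$valid, polar$raster, 0)) / pmax(n_valid, 1)
  ok <- n_valid >= n_radii / 2
  if (!any(ok)) stopf("all angles masked; no iris signal")
  vals[!ok] <- NA_real_
  vals[ok] <- vals[ok] - mean(vals[ok])
  structure(list(values = vals, valid = ok, frame_number = frame_number),
            class = "vog_iris_profile")
}

#' Measure torsion against a reference profile
#'
#' Normalized circular cross-correlation over integer sample shifts within
#' `+/- max_shift_deg`, restricted at each shift to jointly valid angles;
#' the peak shift is refined by parabolic interpolation over its two
#' neighbours. The result is invalid when the peak correlation is below
#' `correlation_threshold`, when fewer than 25 percent of angles are
#' jointly valid, or when the peak saturates at the shift limit.
#'
#' @param profile,reference `vog_iris_profile`s with equal length
#' @param max_shift_deg search half-range in degrees
#' @param correlation_threshold minimum acceptable peak correlation
#' @return list `(torsion_deg, peak_correlation, valid)`
#' @export
measure_torsion <- function(profile, reference, max_shift_deg = 15,
                            correlation_threshold = 0.5) {
  stopifnot(inherits(profile, "vog_iris_profile"),
            inherits(reference, "vog_iris_profile"))
  p <- profile$values; r <- reference$values
  n <- length(p)
  if (length(r) != n) stopf("profile lengths differ (%d vs %d)", n, length(r))
  step <- 360 / n
  K <- max(1L, round(max_shift_deg / step))
  shifts <- (-K):K
  cors <- rep(NA_real_, length(shifts))
  min_overlap <- 0.25 * n
  pv <- profile$valid; rv <- reference$valid
  for (i in seq_along(shifts)) {
    k <- shifts[i]
    # reference rotated by +k samples: ref_shift[m] = r[(m - k) mod n]
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
    rs <- r[idx]; rsv <- rv[idx]
    j <- pv & rsv
    if (sum(j) < min_overlap) next
    a <- p[j] - mean(p[j]); b <- rs[j] - mean(rs[j])
    den <- sqrt(sum(a^2) * sum(b^2))
    cors[i] <- if (den > 0) sum(a * b) / den else NA_real_
  }
  if (all(is.na(cors))) {
    return(list(torsion_deg = NA_real_, peak_correlation = NA_real_, valid = FALSE))
  }
  best <- which.max(cors)
  peak <- cors[best]
  saturated <- best == 1L || best == length(shifts)
  shift <- shifts[best]
  if (!saturated && !is.na(cors[best - 1]) && !is.na(cors[best + 1])) {
    y1 <- cors[best - 1]; y2 <- peak; y3 <- cors[best + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      shift <- shift + 0.5 * (y1 - y3) / den
    }
  }
  torsion <- shift * step
  list(torsion_deg = torsion, peak_correlation = peak,
       valid = !saturated && peak >= correlation_threshold)
}

#' Iris reference for torsion
#'
#' Torsion is relative: a reference profile defines the zero. The torsion
#' tracker object stores the reference and exposes measurement against it.
#'
#' @param settings a `vog_settings` (torsion parameters)
#' @return a `vog_torsion_tracker` environment with `$set_reference(profile)`,
#'   `$reference`, `$measure(profile)`
#' @export
torsion_tracker <- function(settings = default_settings()) {
  tt <- new.env(parent = emptyenv())
  tt$reference <- NULL
  tt$set_reference <- function(profile) {
    if (!inherits(profile, "vog_iris_profile") || !any(profile$valid)) {
      stopf("invalid iris profile for reference")
    }
    tt$reference <- profile
    invisible(profile)
  }
  tt$measure <- function(profile) {
    if (is.null(tt$reference)) {
      return(list(torsion_deg = NA_real_, peak_correlation = NA_real_,
                  valid = FALSE, reason = "no reference"))
    }
    measure_torsion(profile, tt$reference,
                    max_shift_deg = settings$pipeline$max_shift_deg,
                    correlation_threshold = settings$pipeline$correlation_threshold)
  }
  class(tt) <- "vog_torsion_tracker"
  tt
}

# annulus radii derived from the tracked pupil each frame, so dilation is
# tolerated: r_inner hugs the pupil, r_outer adds the iris band width
torsion_annulus <- function(pupil, settings) {
  r_inner <- pupil$major + 2
  list(r_inner = r_inner, r_outer = r_inner + settings$pipeline$iris_width_px)
}
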
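#' Synthetic infrared eye-image generator
#'
#' Renders the features every pipeline needs, with analytic ground truth:
#' a dark elliptical pupil on a textured iris disk over bright sclera,
#' bright Gaussian glints (P1), an optional dimmer P4 reflection displaced
#' in proportion to gaze, optional eyelid occlusion and additive Gaussian
#' noise. The projection model is deliberately simple: the pupil centre is
#' displaced by `radius_px * (sin h, -sin v)` from the eye centre and the
#' pupil circle foreshortens to an ellipse (minor axis along the gaze
#' direction, scaled by the cosine of the eccentricity); there is no
#' corneal refraction or perspective. The iris texture is a sum of angular
#' harmonics so the torsion correlation peak is analytically predictable.
#'
#' @name synthetic
NULL

#' Describe a synthetic scene
#'
#' Defaults emulate one eye of a 720x540 binocular infrared camera after
#' the left/right split, at realistic proportions: ~30 px pupil radius,
#' ~80 px iris radius, eyeball rotation radius 259.1 px (about 4.5 px per
#' degree), glint fixed in the image (illuminator and camera rigid), 8-bit
#' intensities pupil ~20, iris ~130, sclera ~200, glint amplitude 250.
#'
#' @param width,height image size in pixels
#' @param eye_center eyeball centre projection `(x, y)` in pixels
#' @param radius_px eyeball rotation radius in pixels
#' @param gaze_h_deg,gaze_v_deg,torsion_deg eye pose (degrees)
#' @param pupil_radius,iris_radius pre-projection radii in pixels
#' @param pupil_level,iris_level,sclera_level,eyelid_level base intensities
#' @param harmonics iris texture: list of `c(k, amplitude, phase)` angular
#'   harmonics (pairwise-coprime k avoids degenerate correlation peaks)
#' @param glints list of `list(offset, amplitude, sigma)`; offsets are
#'   image-fixed displacements from `eye_center`
#' @param p4 `NULL` or `list(base_offset, gain_px_per_deg, amplitude,
#'   sigma)`: P4 sits near P1 and moves with gaze at the stated gain
#' @param eyelid_coverage fraction of the pupil diameter covered from the
#'   top by the upper lid (0 = none)
#' @param noise_sd additive Gaussian noise, 8-bit intensity levels
#' @param edge_px softness (ramp width) of pupil/iris edges
#' @return a `vog_scene`
#' @export
synthetic_scene <- function(width = 360, height = 360,
                            eye_center = c(180, 180), radius_px = 259.1,
                            gaze_h_deg = 0, gaze_v_deg = 0, torsion_deg = 0,
                            pupil_radius = 30, iris_radius = 80,
                            pupil_level = 20, iris_level = 130,
                            sclera_level = 200, eyelid_level = 180,
                            harmonics = list(c(5, 25, 0.5), c(9, 15, 1.1),
                                             c(13, 10, 2.3)),
                            glints = list(list(offset = c(-45, -35),
                                               amplitude = 250, sigma = 1.5)),
                            p4 = NULL, eyelid_coverage = 0, noise_sd = 0,
                            edge_px = 1.5) {
  stopifnot(pupil_radius < iris_radius, radius_px > 0,
            eyelid_coverage >= 0, eyelid_coverage <= 1)
  structure(as.list(environment()), class = "vog_scene")
}

#' Render one synthetic frame
#'
#' Noise (if any) consumes the current RNG stream; seed with `set.seed()`
#' (or use [generate_sequence()], which seeds once per sequence) for
#' reproducible renders.
#'
#' @param scene a [synthetic_scene()]
#' @return list `(image, truth)`: an integer matrix and a truth row (list
#'   with gaze, torsion, projected pupil ellipse, glint/P1/P4 centres)
#' @export
render_frame <- function(scene) {
  stopifnot(inherits(scene, "vog_scene"))
  w <- scene$width; h <- scene$height
  hr <- deg2rad(scene$gaze_h_deg); vr <- deg2rad(scene$gaze_v_deg)
  d <- scene$radius_px * c(sin(hr), -sin(vr))
  pc <- scene$eye_center + d
  sin_e <- sqrt(sum(d^2)) / scene$radius_px
  if (sin_e > 1) stopf("gaze eccentricity exceeds the projection model")
  cos_e <- sqrt(1 - sin_e^2)
  a <- scene$pupil_radius              # semi-major, perpendicular to gaze dir
  b <- scene$pupil_radius * cos_e      # semi-minor, along gaze dir
  angle <- if (sin_e < 1e-12) 0 else (rad2deg(atan2(d[2], d[1])) + 90) %% 180

  X <- matrix(0:(w - 1), nrow = h, ncol = w, byrow = TRUE)
  Y <- matrix(0:(h - 1), nrow = h, ncol = w)
  dx <- X - pc[1]; dy <- Y - pc[2]
  rr <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)

  tex <- matrix(scene$iris_level, h, w)
  trad <- deg2rad(scene$torsion_deg)
  for (hm in scene$harmonics) {
    tex <- tex + hm[2] * sin(hm[1] * (phi - trad) + hm[3])
  }
  ramp <- function(signed_dist) clamp(signed_dist / scene$edge_px + 0.5, 0, 1)
  img <- matrix(scene$sclera_level, h, w)
  w_iris <- ramp(scene$iris_radius - rr)
  img <- img + w_iris * (tex - img)
  # pupil: signed distance approx from normalized ellipse coordinate
  arad <- deg2rad(angle)
  u <- cos(arad) * dx + sin(arad) * dy
  v2 <- -sin(arad) * dx + cos(arad) * dy
  q <- sqrt((u / a)^2 + (v2 / b)^2)
  w_pup <- ramp((1 - q) * b)
  img <- img + w_pup * (scene$pupil_level - img)
  # upper eyelid: horizontal edge measured down from the pupil top
  if (scene$eyelid_coverage > 0) {
    y_lid <- pc[2] - b_vert(a, b, arad) * (1 - 2 * scene$eyelid_coverage)
    # coverage is of the pupil's vertical extent; lid covers y < y_lid
    w_lid <- ramp(y_lid - Y)
    img <- img + w_lid * (scene$eyelid_level - img)
  }
  glint_centers <- list()
  for (g in scene$glints) {
    gc <- scene$eye_center + g$offset
    img <- img + g$amplitude * exp(-((X - gc[1])^2 + (Y - gc[2])^2) / (2 * g$sigma^2))
    glint_centers[[length(glint_centers) + 1]] <- gc
  }
  p4c <- NULL
  if (!is.null(scene$p4)) {
    p1c <- glint_centers[[1]]
    p4c <- p1c + scene$p4$base_offset +
      scene$p4$gain_px_per_deg * c(scene$gaze_h_deg, -scene$gaze_v_deg)
    img <- img + scene$p4$amplitude *
      exp(-((X - p4c[1])^2 + (Y - p4c[2])^2) / (2 * scene$p4$sigma^2))
  }
  if (scene$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, scene$noise_sd), h, w)
  }
  img <- matrix(as.integer(round(clamp(img, 0, 255))), h, w)
  truth <- list(h_deg = scene$gaze_h_deg, v_deg = scene$gaze_v_deg,
                torsion_deg = scene$torsion_deg,
                pupil_x = pc[1], pupil_y = pc[2], pupil_major = a,
                pupil_minor = b, pupil_angle = angle,
                glint_x = if (length(glint_centers)) glint_centers[[1]][1] else NaN,
                glint_y = if (length(glint_centers)) glint_centers[[1]][2] else NaN,
                p4_x = if (is.null(p4c)) NaN else p4c[1],
                p4_y = if (is.null(p4c)) NaN else p4c[2])
  list(image = img, truth = truth)
}

# vertical half-extent of an ellipse with semi-axes a (at angle arad) and b
b_vert <- function(a, b, arad) sqrt((a * sin(arad))^2 + (b * cos(arad))^2)

#' Render a gaze/torsion trajectory to video plus truth file
#'
#' One RNG seeding covers the whole sequence, so the same seed yields a
#' bit-identical video.
#'
#' @param trajectory data.frame with columns `h_deg`, `v_deg`,
#'   `torsion_deg` (one row per frame); see the `trajectory_*` helpers
#' @param scene template [synthetic_scene()]; its gaze fields are
#'   overridden per frame
#' @param video_path output video (`.avi` or pgm-sequence directory), or
#'   `NULL` to return frames in memory
#' @param truth_path optional tab-separated truth file path
#' @param fps frame rate for timestamps
#' @param seed RNG seed applied once before rendering (`NULL` = leave RNG
#'   alone)
#' @return invisible list `(frames, truth)`; `truth` is a data.frame
#'   aligned by `frame_number`
#' @export
generate_sequence <- function(trajectory, scene = synthetic_scene(),
                              video_path = NULL, truth_path = NULL,
                              fps = 500, seed = NULL) {
  trajectory <- as.data.frame(trajectory)
  stopifnot(all(c("h_deg", "v_deg", "torsion_deg") %in% names(trajectory)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trajectory)
  frames <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- scene
    sc$gaze_h_deg <- trajectory$h_deg[i]
    sc$gaze_v_deg <- trajectory$v_deg[i]
    sc$torsion_deg <- trajectory$torsion_deg[i]
    out <- render_frame(sc)
    frames[[i]] <- out$image
    rows[[i]] <- c(frame_number = i - 1L, timestamp_s = (i - 1) / fps,
                   unlist(out$truth))
  }
  truth <- as.data.frame(do.call(rbind, rows))
  if (!is.null(video_path)) write_raw_video(video_path, frames, fps = fps)
  if (!is.null(truth_path)) {
    cols <- names(truth)
    lines <- c("# vogkit truth v1", paste0("# columns: ", paste(cols, collapse = "\t")),
               vapply(seq_len(n), function(i) {
                 paste(fmt_num(as.numeric(truth[i, ])), collapse = "\t")
               }, character(1)))
    writeLines(lines, truth_path, useBytes = TRUE)
  }
  invisible(list(frames = frames, truth = truth))
}

#' Read a truth file back
#' @param path truth file from [generate_sequence()]
#' @return data.frame
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  cols_line <- grep("^# columns: ", hdr, value = TRUE)
  if (!length(cols_line)) stopf("truth file %s has no column header", path)
  cols <- strsplit(sub("^# columns: ", "", cols_line[1]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  out <- as.data.frame(m)
  names(out) <- cols
  out
}

#' Trajectory helpers
#'
#' `trajectory_fixation`: steady gaze with optional isotropic Gaussian
#' jitter (draws from the current RNG stream). `trajectory_torsion_ramp`:
#' pure torsion ramp at zero gaze. `trajectory_sine`: sinusoidal horizontal
#' gaze.
#'
#' @param n_frames number of frames
#' @param h_deg,v_deg fixation position
#' @param jitter_sd_deg per-frame positional jitter (degrees)
#' @return data.frame with `h_deg`, `v_deg`, `torsion_deg`
#' @export
trajectory_fixation <- function(n_frames, h_deg = 0, v_deg = 0,
                                jitter_sd_deg = 0) {
  jx <- if (jitter_sd_deg > 0) rnorm(n_frames, 0, jitter_sd_deg) else numeric(n_frames)
  jy <- if (jitter_sd_deg > 0) rnorm(n_frames, 0, jitter_sd_deg) else numeric(n_frames)
  data.frame(h_deg = h_deg + jx, v_deg = v_deg + jy,
             torsion_deg = numeric(n_frames))
}

#' @rdname trajectory_fixation
#' @param from,to,by torsion ramp limits and step (degrees)
#' @export
trajectory_torsion_ramp <- function(from = -10, to = 10, by = 1) {
  t <- seq(from, to, by = by)
  data.frame(h_deg = 0, v_deg = 0, torsion_deg = t)
}

#' @rdname trajectory_fixation
#' @param fs sampling rate (Hz)
#' @param freq_hz sine frequency
#' @param amplitude_deg sine amplitude
#' @export
trajectory_sine <- function(n_frames, fs = 500, freq_hz = 1,
                            amplitude_deg = 5) {
  t <- (seq_len(n_frames) - 1) / fs
  data.frame(h_deg = amplitude_deg * sin(2 * pi * freq_hz * t),
             v_deg = 0, torsion_deg = 0)
}
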
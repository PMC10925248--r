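#' Frame-by-frame data files and trace metrics
#'
#' Results are recorded as tab-separated text with `#`-prefixed header
#' lines (schema version, sampling rate, settings fingerprint, sign
#' conventions). One row per grabbed frame per eye; missing measurements
#' are written as the token `NaN`. Post-hoc quality metrics: central-
#' difference velocity and RMS.
#'
#' @name recording
NULL

DATA_COLUMNS <- c("frame_number", "timestamp_s", "eye", "pupil_x", "pupil_y",
                  "pupil_major", "pupil_minor", "pupil_angle", "glint1_x",
                  "glint1_y", "torsion_deg", "p1_x", "p1_y", "p4_x", "p4_y",
                  "h_deg", "v_deg", "quality")
NUM_COLUMNS <- setdiff(DATA_COLUMNS, c("eye", "quality"))

#' Write tracking rows to a data file
#'
#' @param path output path
#' @param rows data.frame with the documented columns, ordered by
#'   `frame_number` (within each eye); out-of-order rows are an error
#' @param header named list of extra header fields (e.g. `fs`,
#'   `settings_hash`)
#' @return `path`, invisibly
#' @export
write_rows <- function(path, rows, header = list()) {
  rows <- as.data.frame(rows)
  missing_cols <- setdiff(DATA_COLUMNS, names(rows))
  if (length(missing_cols)) {
    stopf("rows missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  rows <- rows[, DATA_COLUMNS]
  for (e in unique(rows$eye)) {
    fn <- rows$frame_number[rows$eye == e]
    if (is.unsorted(fn, strictly = FALSE)) {
      stopf("rows for eye '%s' are not ordered by frame_number", e)
    }
  }
  hdr <- c("# vogkit data v1",
           "# conventions: h positive rightward, v positive upward; pixels 0-based top-left")
  for (k in names(header)) {
    hdr <- c(hdr, sprintf("# %s: %s", k, as.character(header[[k]])))
  }
  hdr <- c(hdr, paste0("# columns: ", paste(DATA_COLUMNS, collapse = "\t")))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    vals <- vapply(DATA_COLUMNS, function(cn) {
      v <- rows[[cn]][i]
      if (cn %in% NUM_COLUMNS) fmt_num(as.numeric(v)) else as.character(v)
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a data file back
#'
#' @param path data file written by [write_rows()]
#' @return data.frame of rows; header fields in attribute `"header"`
#' @export
read_rows <- function(path) {
  if (!file.exists(path)) stopf("data file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  header <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^# ([A-Za-z0-9_]+): (.*)$", h))[[1]]
    if (length(m) == 3) header[[m[2]]] <- m[3]
  }
  body_idx <- which(!is_hdr)
  body <- lines[body_idx]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  if (n == 0) {
    out <- as.data.frame(stats::setNames(
      lapply(DATA_COLUMNS, function(cn) {
        if (cn %in% NUM_COLUMNS) numeric(0) else character(0)
      }), DATA_COLUMNS))
    attr(out, "header") <- header
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(DATA_COLUMNS))
  if (length(bad)) {
    stopf("malformed data line %d in %s: %d fields, expected %d",
          body_idx[bad[1]], path, nf[bad[1]], length(DATA_COLUMNS))
  }
  m <- do.call(rbind, parts)
  out <- list()
  for (j in seq_along(DATA_COLUMNS)) {
    cn <- DATA_COLUMNS[j]
    if (cn %in% NUM_COLUMNS) {
      v <- suppressWarnings(as.numeric(m[, j]))
      badv <- which(is.na(v) & !(toupper(m[, j]) %in% c("NAN", "NA")))
      if (length(badv)) {
        stopf("malformed numeric '%s' in column %s, data line %d of %s",
              m[badv[1], j], cn, body_idx[badv[1]], path)
      }
      out[[cn]] <- v
    } else {
      out[[cn]] <- m[, j]
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$frame_number <- as.integer(out$frame_number)
  attr(out, "header") <- header
  out
}

#' Uniformly sampled trace
#' @param x numeric series (degrees), may contain NaN gaps
#' @param fs sampling rate in Hz, positive
#' @return a `vog_trace`
#' @export
new_trace <- function(x, fs) {
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  structure(list(x = as.numeric(x), fs = fs), class = "vog_trace")
}

#' Central-difference velocity of a trace
#'
#' `v[i] = (x[i+1] - x[i-1]) * fs / 2`, one-sided at the endpoints. A NaN
#' sample propagates to the velocities that reference it (its neighbours).
#'
#' @param trace a `vog_trace`
#' @return a `vog_trace` of velocities (same length, same fs)
#' @export
velocity <- function(trace) {
  stopifnot(inherits(trace, "vog_trace"))
  x <- trace$x; fs <- trace$fs
  n <- length(x)
  if (n < 2) stopf("velocity needs >= 2 samples")
  v <- rep(NA_real_, n)
  if (n > 2) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v[is.na(x)] <- NaN  # no velocity claim where the position itself is missing
  new_trace(v, fs)
}

#' Root mean square over non-NaN samples
#' @param series numeric vector or `vog_trace`
#' @return scalar `sqrt(mean(x^2))` over finite samples
#' @export
rms <- function(series) {
  x <- if (inherits(series, "vog_trace")) series$x else as.numeric(series)
  x <- x[!is.na(x)]
  if (!length(x)) stopf("rms of an all-NaN series")
  sqrt(mean(x^2))
}

#' Batch reprocessing of recorded videos
#'
#' Each job is independent: a failure is recorded in that job's report and
#' the batch continues. Outputs are deterministic given (video, settings,
#' calibration).
#'
#' @param jobs list of jobs, each a list with `video` (path),
#'   `settings` (path or `vog_settings`, optional), `calibration` (path or
#'   `vog_calibration`, optional), `out` (output data-file path)
#' @return list of session reports; failed jobs have `$error`
#' @export
batch_process <- function(jobs) {
  lapply(seq_along(jobs), function(i) {
    job <- jobs[[i]]
    tryCatch({
      settings <- job$settings
      if (is.null(settings)) settings <- default_settings()
      if (is.character(settings)) settings <- load_settings(settings)
      cal <- job$calibration
      if (is.character(cal)) cal <- load_calibration(cal)
      src <- open_video(job$video, timestamps_path = job$timestamps,
                        fps = settings$system$fps)
      run_session(src, pipeline = vog_pipeline(settings),
                  calibration = cal, out_path = job$out,
                  settings = settings)
    }, error = function(e) {
      list(job = i, error = conditionMessage(e), frames_grabbed = 0L,
           frames_processed = 0L, frames_dropped = 0L, out_path = job$out)
    })
  })
}
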
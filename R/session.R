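#' Session orchestration
#'
#' A session runs source -> (preprocess) -> pipeline -> calibration ->
#' sinks, pumping grabbed frames through the bounded FIFO buffer and a
#' pool of workers, and emits exactly one row per grabbed frame in
#' `frame_number` order regardless of worker completion order (a reorder
#' stage keyed on `frame_number` holds early completions back). Frames
#' rejected by a full buffer still yield a row, flagged `dropped`; a
#' pipeline exception flags that row `error` and the session continues.
#'
#' R executes in one OS thread, so the worker pool is a faithful
#' scheduling simulation rather than true parallelism: frames are
#' dispatched to `n_workers` logical workers and their completions are
#' interleaved out of dispatch order, which exercises the reorder stage;
#' pipeline state (e.g. the torsion reference) is updated in frame order,
#' making output byte-identical for any worker count — the determinism the
#' contract requires.
#'
#' @name session
NULL

#' The standard tracking pipeline
#'
#' Per frame: dark-pupil detection (method per settings), optional glint
#' detection (search window centred on the pupil, pupil pixels excluded),
#' optional torsion (iris annulus derived from the pupil each frame;
#' reference auto-set from the first frame with a valid pupil, or
#' explicitly via `$set_reference`), optional dual-Purkinje detection.
#'
#' @param settings a `vog_settings`
#' @return a `vog_pipeline`: list with `$settings`, `$state`, `$process
#'   (frame)`, `$set_reference(image, pupil)`, `$quick_settings`
#' @export
vog_pipeline <- function(settings = default_settings()) {
  state <- new.env(parent = emptyenv())
  state$torsion <- torsion_tracker(settings)
  p <- settings$pipeline

  make_profile <- function(image, pupil) {
    ann <- torsion_annulus(pupil, settings)
    polar <- unwrap_polar(image, pupil$center, ann$r_inner, ann$r_outer,
                          n_angles = p$n_angles, n_radii = p$n_radii)
    iris_profile(polar)
  }

  process <- function(frame) {
    image <- frame$image
    tp <- track_pupil(image, settings)
    if (!tp$found) {
      return(new_datum(frame$frame_number, frame$timestamp, frame$eye,
                       quality = "pupil_not_found"))
    }
    pupil <- tp$ellipse
    glints <- list()
    if (p$track_glints) {
      half <- 5 * pupil$major
      roi <- list(x0 = pupil$center[1] - half, x1 = pupil$center[1] + half,
                  y0 = pupil$center[2] - half, y1 = pupil$center[2] + half)
      glints <- detect_glints(image, p$glint_threshold,
                              min_size_px2 = p$glint_min_size_px2,
                              max_size_px2 = p$glint_max_size_px2,
                              search_roi = roi, exclude_mask = tp$mask,
                              max_glints = p$max_glints)
    }
    torsion_deg <- NA_real_
    quality <- "ok"
    if (p$track_torsion) {
      prof <- tryCatch(make_profile(image, pupil), error = function(e) NULL)
      if (is.null(prof)) {
        quality <- "torsion_low_correlation"
      } else if (is.null(state$torsion$reference)) {
        state$torsion$set_reference(prof)
        torsion_deg <- 0
      } else {
        tr <- state$torsion$measure(prof)
        if (tr$valid) torsion_deg <- tr$torsion_deg
        else quality <- "torsion_low_correlation"
      }
    }
    pk <- list(p1 = NULL, p4 = NULL)
    if (p$track_dpi) {
      pk <- detect_purkinje(image, settings, exclude_mask = tp$mask)
    }
    new_datum(frame$frame_number, frame$timestamp, frame$eye,
              pupil = pupil, glints = glints, torsion_deg = torsion_deg,
              p1 = if (is.null(pk$p1)) NULL else pk$p1$center,
              p4 = if (is.null(pk$p4)) NULL else pk$p4$center,
              quality = quality)
  }

  pl <- list(settings = settings, state = state, process = process,
             set_reference = function(image, pupil) {
               state$torsion$set_reference(make_profile(image, pupil))
             },
             quick_settings = c("pipeline.pupil_threshold",
                                "pipeline.min_size_px2",
                                "pipeline.max_size_px2", "pipeline.roi",
                                "pipeline.glint_threshold",
                                "pipeline.iris_width_px",
                                "pipeline.max_shift_deg",
                                "pipeline.correlation_threshold",
                                "pipeline.p1_threshold",
                                "pipeline.p4_threshold",
                                "pipeline.p4_search_radius"))
  class(pl) <- "vog_pipeline"
  pl
}

resolve_workers <- function(settings, n_workers = NULL) {
  if (!is.null(n_workers)) return(max(1L, as.integer(n_workers)))
  n <- settings$system$n_workers
  if (n <= 0L) {
    n <- tryCatch(parallel::detectCores(), error = function(e) 1L)
    if (!is.finite(n) || n < 1) n <- 1L
  }
  min(as.integer(n), settings$system$max_workers)
}

#' Run a tracking session
#'
#' @param source a `vog_source` (e.g. [open_video()] or [frame_source()])
#' @param pipeline a [vog_pipeline()] (or any list with `$process(frame)`)
#' @param calibration optional `vog_calibration` applied per row
#' @param sinks list of functions called as `sink(row)` per emitted row
#' @param out_path optional data-file path written via [write_rows()]
#' @param settings session settings (defaults to the pipeline's)
#' @param n_workers,buffer_capacity override the corresponding settings
#' @param geometry optional [source_geometry()] applied before processing
#'   (the first resulting per-eye frame is tracked)
#' @param log_path optional log file (timestamped INFO/WARN/ERROR lines)
#' @return a `vog_session_report`: counts (`frames_grabbed =
#'   frames_processed + frames_dropped`), `out_path`, and `$rows` (the
#'   emitted data.frame)
#' @export
run_session <- function(source, pipeline, calibration = NULL, sinks = list(),
                        out_path = NULL, settings = NULL, n_workers = NULL,
                        buffer_capacity = NULL, geometry = NULL,
                        log_path = NULL) {
  if (is.null(settings)) {
    settings <- if (!is.null(pipeline$settings)) pipeline$settings else default_settings()
  }
  n_workers <- resolve_workers(settings, n_workers)
  if (is.null(buffer_capacity)) buffer_capacity <- settings$system$buffer_capacity
  buf <- frame_buffer(buffer_capacity)
  log_con <- NULL
  if (!is.null(log_path)) {
    log_con <- file(log_path, "a")
    on.exit(close(log_con), add = TRUE)
  }
  logf <- function(level, fmt, ...) {
    if (!is.null(log_con)) {
      writeLines(sprintf("%s [%s] %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
                         level, sprintf(fmt, ...)), log_con)
    }
  }
  logf("INFO", "session start: n_workers=%d buffer_capacity=%d",
       n_workers, buffer_capacity)

  grabbed <- 0L; processed <- 0L; dropped <- 0L
  rows <- list()
  pending <- new.env(parent = emptyenv())   # reorder stage: key = frame_number
  next_emit <- NULL

  emit <- function(row) {
    rows[[length(rows) + 1L]] <<- row
    for (s in sinks) s(row)
  }
  flush_pending <- function() {
    repeat {
      key <- as.character(next_emit)
      if (!exists(key, envir = pending, inherits = FALSE)) break
      emit(get(key, envir = pending))
      rm(list = key, envir = pending)
      next_emit <<- next_emit + 1L
    }
  }
  process_one <- function(frame) {
    datum <- tryCatch(pipeline$process(frame), error = function(e) {
      logf("ERROR", "frame %d: %s", frame$frame_number, conditionMessage(e))
      new_datum(frame$frame_number, frame$timestamp, frame$eye,
                quality = "error")
    })
    hv <- list(h_deg = NaN, v_deg = NaN)
    if (!is.null(calibration) && !datum$quality %in% c("dropped", "error")) {
      cs <- apply_calibration(calibration, datum)
      hv <- list(h_deg = cs$h_deg, v_deg = cs$v_deg)
      if (!is.na(cs$torsion_deg)) datum$torsion_deg <- cs$torsion_deg
    }
    datum_to_row(datum, h_deg = hv$h_deg, v_deg = hv$v_deg)
  }
  # drain the buffer through the worker pool: frames are processed in FIFO
  # (frame_number) order but complete out of dispatch order within each
  # worker batch; the reorder stage restores emission order
  drain <- function() {
    while (buffer_size(buf) > 0) {
      batch <- list()
      while (length(batch) < n_workers && buffer_size(buf) > 0) {
        batch[[length(batch) + 1L]] <- buffer_dequeue(buf)
      }
      done <- lapply(batch, process_one)   # state updates in frame order
      processed <<- processed + length(done)
      completion <- rev(seq_along(done))   # simulate out-of-order completion
      for (i in completion) {
        assign(as.character(batch[[i]]$frame_number), done[[i]], envir = pending)
      }
      flush_pending()
    }
  }

  repeat {
    frame <- tryCatch(source$grab(), error = function(e) {
      logf("ERROR", "source: %s", conditionMessage(e))
      NULL
    })
    if (is.null(frame)) break
    if (!is.null(geometry)) frame <- preprocess_frame(frame, geometry)[[1]]
    if (is.null(next_emit)) next_emit <- frame$frame_number
    grabbed <- grabbed + 1L
    status <- buffer_enqueue(buf, frame)
    if (status == "dropped") {
      dropped <- dropped + 1L
      logf("WARN", "frame %d dropped: buffer full", frame$frame_number)
      assign(as.character(frame$frame_number),
             datum_to_row(new_datum(frame$frame_number, frame$timestamp,
                                    frame$eye, quality = "dropped")),
             envir = pending)
    }
    if (buffer_size(buf) >= buffer_capacity) drain()
  }
  drain()
  flush_pending()

  df <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    read_rows_empty()
  }
  if (!is.null(out_path)) {
    write_rows(out_path, df, header = list(
      fs = format(settings$system$fps, digits = 17, trim = TRUE),
      settings_hash = settings_hash(settings)))
  }
  logf("INFO", "session end: grabbed=%d processed=%d dropped=%d",
       grabbed, processed, dropped)
  structure(list(frames_grabbed = grabbed, frames_processed = processed,
                 frames_dropped = dropped, out_path = out_path, rows = df),
            class = "vog_session_report")
}

read_rows_empty <- function() {
  as.data.frame(stats::setNames(lapply(DATA_COLUMNS, function(cn) {
    if (cn %in% NUM_COLUMNS) numeric(0) else character(0)
  }), DATA_COLUMNS))
}

#' @export
print.vog_session_report <- function(x, ...) {
  cat(sprintf("<session: grabbed=%d processed=%d dropped=%d%s>\n",
              x$frames_grabbed, x$frames_processed, x$frames_dropped,
              if (is.null(x$out_path)) "" else paste0(" out=", x$out_path)))
  invisible(x)
}
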
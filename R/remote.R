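#' Remote-control command protocol
#'
#' Other programs (stimulus presentation, analysis scripts) can drive a
#' session through a minimal line-oriented protocol: one JSON request per
#' line, one JSON response per line, every request answered exactly once
#' with its matching `id`. Verbs: `startRecording`, `stopRecording`,
#' `setSetting`, `getLastSample`, `recordEvent`, `status`. The transport is
#' any line connection (TCP socket, pipe, or an in-memory connection in
#' tests); the protocol logic lives in [handle_command()] and is
#' transport-agnostic.
#'
#' @name remote
NULL

#' Create a controllable live session
#'
#' Wraps a source and pipeline in a stepped session whose behaviour
#' (recording on/off, live settings, event markers) is controlled by
#' [handle_command()]. Frames are advanced with [session_step()].
#'
#' @param source a `vog_source`
#' @param settings a `vog_settings`
#' @param calibration optional `vog_calibration`
#' @param out_path data-file path used while recording is on
#' @return a `vog_remote_session` environment
#' @export
remote_session <- function(source, settings = default_settings(),
                           calibration = NULL, out_path = NULL) {
  s <- new.env(parent = emptyenv())
  s$source <- source
  s$settings <- settings
  s$calibration <- calibration
  s$out_path <- out_path
  s$recording <- FALSE
  s$state <- "idle"
  s$last_sample <- NULL
  s$rows <- list()
  s$events <- list()
  s$setting_changes <- list()
  s$pipeline <- vog_pipeline(settings)
  s$frames_seen <- 0L
  class(s) <- "vog_remote_session"
  s
}

# settings that may change mid-session without invalidating history
LIVE_SETTINGS <- c("pipeline.pupil_threshold", "pipeline.glint_threshold",
                   "pipeline.min_size_px2", "pipeline.max_size_px2",
                   "pipeline.p1_threshold", "pipeline.p4_threshold",
                   "pipeline.p4_search_radius",
                   "pipeline.correlation_threshold")

#' Advance a remote session by one frame
#'
#' @param session a [remote_session()]
#' @return the emitted row (invisibly), or `NULL` at end of source
#' @export
session_step <- function(session) {
  frame <- session$source$grab()
  if (is.null(frame)) return(invisible(NULL))
  session$state <- "running"
  session$frames_seen <- session$frames_seen + 1L
  datum <- tryCatch(session$pipeline$process(frame), error = function(e) {
    new_datum(frame$frame_number, frame$timestamp, frame$eye, quality = "error")
  })
  hv <- list(h_deg = NaN, v_deg = NaN)
  if (!is.null(session$calibration) && !datum$quality %in% c("dropped", "error")) {
    cs <- apply_calibration(session$calibration, datum)
    hv <- list(h_deg = cs$h_deg, v_deg = cs$v_deg)
  }
  row <- datum_to_row(datum, h_deg = hv$h_deg, v_deg = hv$v_deg)
  session$last_sample <- row
  if (session$recording) session$rows[[length(session$rows) + 1L]] <- row
  invisible(row)
}

# flush recorded rows (+ event marker comments) to the data file
session_flush <- function(session) {
  if (is.null(session$out_path) || !length(session$rows)) return(invisible(NULL))
  df <- do.call(rbind, lapply(session$rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  hdr <- list(settings_hash = settings_hash(session$settings))
  for (i in seq_along(session$events)) {
    ev <- session$events[[i]]
    hdr[[sprintf("event_%d", i)]] <- sprintf("frame=%s %s", ev$frame, ev$label)
  }
  for (i in seq_along(session$setting_changes)) {
    ch <- session$setting_changes[[i]]
    hdr[[sprintf("setting_change_%d", i)]] <-
      sprintf("frame=%s %s=%s", ch$frame, ch$key, ch$value)
  }
  write_rows(session$out_path, df, header = hdr)
  invisible(session$out_path)
}

#' Handle one remote command
#'
#' @param session a [remote_session()]
#' @param cmd a request: JSON string or list with `verb`, `id` and optional
#'   arguments (`key`/`value` for `setSetting`, `label` for `recordEvent`)
#' @return response list (serialize with `jsonlite::toJSON(auto_unbox =
#'   TRUE)`): always carries the request `id` and `status` (`"ok"` or
#'   `"error"`)
#' @export
handle_command <- function(session, cmd) {
  if (is.character(cmd)) {
    cmd <- tryCatch(jsonlite::fromJSON(cmd), error = function(e) NULL)
    if (is.null(cmd)) return(list(id = NA, status = "error",
                                  message = "unparseable request"))
  }
  id <- if (is.null(cmd$id)) NA else cmd$id
  verb <- cmd$verb
  fail <- function(msg) list(id = id, status = "error", message = msg)
  if (is.null(verb)) return(fail("missing verb"))
  switch(verb,
    status = list(id = id, status = "ok", state = session$state,
                  recording = session$recording,
                  frames_seen = session$frames_seen),
    startRecording = {
      session$recording <- TRUE
      list(id = id, status = "ok", recording = TRUE)
    },
    stopRecording = {   # idempotent: stopping twice is a no-op success
      was <- session$recording
      session$recording <- FALSE
      session_flush(session)
      list(id = id, status = "ok", recording = FALSE, was_recording = was)
    },
    setSetting = {
      key <- cmd$key
      if (is.null(key)) return(fail("setSetting needs 'key'"))
      if (!key %in% LIVE_SETTINGS) {
        return(fail(sprintf(
          "setting '%s' is not live-adjustable; live settings: %s",
          key, paste(LIVE_SETTINGS, collapse = ", "))))
      }
      new <- tryCatch(do.call(set_setting,
                              c(list(session$settings),
                                stats::setNames(list(cmd$value), key))),
                      error = function(e) e)
      if (inherits(new, "error")) return(fail(conditionMessage(new)))
      session$settings <- new
      session$pipeline <- vog_pipeline(new)
      session$setting_changes[[length(session$setting_changes) + 1L]] <-
        list(frame = session$frames_seen, key = key, value = cmd$value)
      list(id = id, status = "ok", key = key, value = cmd$value)
    },
    getLastSample = {
      if (is.null(session$last_sample)) {
        list(id = id, status = "ok", sample = NULL)
      } else {
        list(id = id, status = "ok", sample = session$last_sample)
      }
    },
    recordEvent = {
      label <- if (is.null(cmd$label)) "event" else cmd$label
      session$events[[length(session$events) + 1L]] <-
        list(frame = session$frames_seen, label = label)
      list(id = id, status = "ok", frame = session$frames_seen)
    },
    fail(sprintf("unknown verb '%s'; known: %s", verb,
                 "startRecording, stopRecording, setSetting, getLastSample, recordEvent, status"))
  )
}

#' Serve the protocol over a line connection
#'
#' Reads one JSON request per line from `con_in`, writes one JSON response
#' per line to `con_out`, advancing the session by `frames_per_poll` frames
#' before each command. Stops at end of input or on a `{"verb":"quit"}`
#' line.
#'
#' @param session a [remote_session()]
#' @param con_in,con_out readable / writable connections
#' @param frames_per_poll frames to process before answering each request
#' @return number of requests handled, invisibly
#' @export
serve_connection <- function(session, con_in, con_out, frames_per_poll = 1) {
  n <- 0L
  repeat {
    line <- tryCatch(readLines(con_in, n = 1, warn = FALSE),
                     error = function(e) character(0))
    if (!length(line)) break
    if (!nzchar(trimws(line))) next
    req <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
    if (!is.null(req) && identical(req$verb, "quit")) {
      writeLines(as.character(jsonlite::toJSON(
        list(id = req$id, status = "ok", state = "bye"), auto_unbox = TRUE,
        null = "null")), con_out)
      n <- n + 1L
      break
    }
    for (i in seq_len(frames_per_poll)) session_step(session)
    resp <- handle_command(session, if (is.null(req)) line else req)
    writeLines(as.character(jsonlite::toJSON(resp, auto_unbox = TRUE,
                                             null = "null")), con_out)
    n <- n + 1L
  }
  invisible(n)
}
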
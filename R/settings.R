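#' Typed pipeline settings
#'
#' Settings are declared once, with a section, a type and a default, and are
#' carried through sessions as a `vog_settings` object. The text
#' representation is a flat `section.key = value` file (UTF-8, `#` comments)
#' whose save/load round-trip is the identity on valid settings. Unknown
#' keys are rejected; keys missing from a file keep their defaults; a value
#' that does not parse as the declared type is an error naming the key.
#'
#' Sections mirror the three configuration columns of a tracking
#' application: `system` (acquisition/session plumbing), `pipeline`
#' (image-processing parameters such as brightness thresholds and object
#' size limits) and `calibration`.
#'
#' @name settings
NULL

# declaration table: one row per setting
settings_schema <- function() {
  s <- function(section, key, type, default) {
    list(section = section, key = key, type = type, default = default)
  }
  list(
    s("system", "fps",             "double",  500),
    s("system", "n_workers",       "integer", 0L),   # 0 = auto (detectCores)
    s("system", "max_workers",     "integer", 8L),
    s("system", "buffer_capacity", "integer", 100L),
    s("system", "eye",             "string",  "left"),

    s("pipeline", "pupil_method",     "string",  "ellipse_fit"),
    s("pipeline", "pupil_threshold",  "integer", 80L),
    s("pipeline", "min_size_px2",     "integer", 200L),
    s("pipeline", "max_size_px2",     "integer", 50000L),
    s("pipeline", "roi",              "string",  ""),  # "x0,x1,y0,y1" half-open, empty = full
    s("pipeline", "track_glints",     "logical", TRUE),
    s("pipeline", "glint_threshold",  "integer", 220L),
    s("pipeline", "glint_min_size_px2", "integer", 1L),
    s("pipeline", "glint_max_size_px2", "integer", 400L),
    s("pipeline", "max_glints",       "integer", 4L),
    s("pipeline", "track_torsion",    "logical", FALSE),
    s("pipeline", "iris_width_px",    "double",  40),
    s("pipeline", "n_angles",         "integer", 720L),
    s("pipeline", "n_radii",          "integer", 20L),
    s("pipeline", "max_shift_deg",    "double",  15),
    s("pipeline", "correlation_threshold", "double", 0.5),
    s("pipeline", "track_dpi",        "logical", FALSE),
    s("pipeline", "p1_threshold",     "integer", 200L),
    s("pipeline", "p4_threshold",     "integer", 90L),
    s("pipeline", "p4_search_radius", "double",  40),

    s("calibration", "feature", "string", "pupil"),  # "pupil" or "pupil_cr"
    s("calibration", "degree",  "integer", 1L),
    s("calibration", "radius_px", "double", 259.1)
  )
}

#' Default settings object
#'
#' @return A `vog_settings` object holding every declared setting at its
#'   default value.
#' @examples
#' s <- default_settings()
#' s$pipeline$pupil_threshold
#' @export
default_settings <- function() {
  schema <- settings_schema()
  out <- list()
  types <- character(0)
  for (d in schema) {
    out[[d$section]][[d$key]] <- d$default
    types[paste(d$section, d$key, sep = ".")] <- d$type
  }
  structure(out, types = types, class = "vog_settings")
}

#' @export
print.vog_settings <- function(x, ...) {
  cat("<vog_settings>\n")
  for (sec in names(x)) {
    for (key in names(x[[sec]])) {
      cat(sprintf("  %s.%s = %s\n", sec, key, format_setting(x[[sec]][[key]])))
    }
  }
  invisible(x)
}

format_setting <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.character(v)) return(v)
  format(v, digits = 17, scientific = FALSE, trim = TRUE)
}

parse_setting <- function(value, type, key) {
  value <- trimws(value)
  bad <- function() stopf("setting '%s': cannot parse '%s' as %s", key, value, type)
  switch(type,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", value)) bad()
      as.integer(value)
    },
    double = {
      x <- suppressWarnings(as.numeric(value))
      if (is.na(x) && !identical(toupper(value), "NAN")) bad()
      x
    },
    logical = {
      lv <- tolower(value)
      if (lv %in% c("true", "1", "yes")) TRUE
      else if (lv %in% c("false", "0", "no")) FALSE
      else bad()
    },
    string = value,
    bad()
  )
}

#' Save settings to a text file
#'
#' One `section.key = value` line per setting, `#` comments allowed.
#'
#' @param settings a `vog_settings` object
#' @param path output file path
#' @return `path`, invisibly.
#' @export
save_settings <- function(settings, path) {
  stopifnot(inherits(settings, "vog_settings"))
  lines <- c("# vogkit settings v1")
  for (sec in names(settings)) {
    for (key in names(settings[[sec]])) {
      lines <- c(lines, sprintf("%s.%s = %s", sec, key,
                                format_setting(settings[[sec]][[key]])))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load settings from a text file
#'
#' Keys absent from the file keep the defaults of `base`; unknown keys and
#' type mismatches are errors naming the offending key.
#'
#' @param path settings file path
#' @param base settings object supplying defaults (default:
#'   [default_settings()])
#' @return a `vog_settings` object
#' @export
load_settings <- function(path, base = default_settings()) {
  if (!file.exists(path)) stopf("settings file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  types <- attr(base, "types")
  out <- base
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (!grepl("=", raw, fixed = TRUE)) {
      stopf("settings file %s line %d: expected 'section.key = value'", path, ln)
    }
    key <- trimws(sub("=.*$", "", raw))
    value <- trimws(sub("^[^=]*=", "", raw))
    if (!grepl("^[A-Za-z0-9_]+\\.[A-Za-z0-9_]+$", key)) {
      stopf("settings file %s line %d: malformed key '%s'", path, ln, key)
    }
    if (!key %in% names(types)) {
      stopf("unknown setting '%s' (line %d of %s)", key, ln, path)
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- parse_setting(value, types[[key]], key)
  }
  out
}

#' Set one or more settings by dotted key
#'
#' @param settings a `vog_settings` object
#' @param ... named values, e.g. `pipeline.pupil_threshold = 90`
#' @return the modified settings object
#' @export
set_setting <- function(settings, ...) {
  stopifnot(inherits(settings, "vog_settings"))
  args <- list(...)
  types <- attr(settings, "types")
  for (key in names(args)) {
    if (!key %in% names(types)) {
      stopf("unknown setting '%s'; known: %s", key,
            paste(names(types), collapse = ", "))
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- args[[key]]
    type <- types[[key]]
    ok <- switch(type,
      integer = is.numeric(v) && length(v) == 1 && v == floor(v),
      double = is.numeric(v) && length(v) == 1,
      logical = is.logical(v) && length(v) == 1,
      string = is.character(v) && length(v) == 1)
    if (!ok) stopf("setting '%s': value is not of type %s", key, type)
    if (type == "integer") v <- as.integer(v)
    if (type == "double") v <- as.numeric(v)
    settings[[parts[1]]][[parts[2]]] <- v
  }
  settings
}

#' Get one setting by dotted key
#' @param settings a `vog_settings` object
#' @param key dotted key, e.g. `"pipeline.pupil_threshold"`
#' @return the setting's value
#' @export
get_setting <- function(settings, key) {
  types <- attr(settings, "types")
  if (!key %in% names(types)) {
    stopf("unknown setting '%s'; known: %s", key,
          paste(names(types), collapse = ", "))
  }
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  settings[[parts[1]]][[parts[2]]]
}

# parse the roi string "x0,x1,y0,y1" (half-open) or "" -> NULL
parse_roi <- function(roi_string) {
  if (!nzchar(roi_string)) return(NULL)
  v <- suppressWarnings(as.numeric(strsplit(roi_string, ",")[[1]]))
  if (length(v) != 4 || anyNA(v)) stopf("roi must be 'x0,x1,y0,y1', got '%s'", roi_string)
  list(x0 = v[1], x1 = v[2], y0 = v[3], y1 = v[4])
}

# stable text fingerprint of a settings object for data-file headers
settings_hash <- function(settings) {
  lines <- character(0)
  for (sec in names(settings)) {
    for (key in names(settings[[sec]])) {
      lines <- c(lines, sprintf("%s.%s=%s", sec, key,
                                format_setting(settings[[sec]][[key]])))
    }
  }
  fnv1a32(paste(lines, collapse = "\n"))
}
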
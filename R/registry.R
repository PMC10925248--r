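#' Plugin registry
#'
#' Sources, tracking pipelines and calibration methods are interchangeable
#' plugins looked up by `(kind, name)`. A plugin is registered as a factory
#' (a constructor function); duplicate names within a kind are an error, and
#' looking up an unknown name reports the registered alternatives.
#'
#' @name registry
NULL

.vog_registry <- new.env(parent = emptyenv())

registry_reset <- function() {
  for (kind in c("source", "pipeline", "calibration")) {
    assign(kind, list(), envir = .vog_registry)
  }
  invisible(NULL)
}

check_kind <- function(kind) {
  kinds <- c("source", "pipeline", "calibration")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    stopf("plugin kind must be one of: %s", paste(kinds, collapse = ", "))
  }
  kind
}

#' Register a plugin factory
#'
#' @param kind one of `"source"`, `"pipeline"`, `"calibration"`
#' @param name unique plugin name within its kind
#' @param factory constructor function for the plugin
#' @param overwrite allow replacing an existing registration
#' @return the factory, invisibly
#' @export
register_plugin <- function(kind, name, factory, overwrite = FALSE) {
  check_kind(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.function(factory))
  tab <- get(kind, envir = .vog_registry)
  if (name %in% names(tab) && !overwrite) {
    stopf("plugin '%s' already registered for kind '%s'", name, kind)
  }
  tab[[name]] <- factory
  assign(kind, tab, envir = .vog_registry)
  invisible(factory)
}

#' Look up a plugin factory
#' @inheritParams register_plugin
#' @return the registered factory function
#' @export
get_plugin <- function(kind, name) {
  check_kind(kind)
  tab <- get(kind, envir = .vog_registry)
  if (!name %in% names(tab)) {
    stopf("no plugin '%s' of kind '%s'; registered: %s", name, kind,
          if (length(tab)) paste(names(tab), collapse = ", ") else "(none)")
  }
  tab[[name]]
}

#' List registered plugin names
#' @inheritParams register_plugin
#' @return character vector of names
#' @export
list_plugins <- function(kind) {
  check_kind(kind)
  names(get(kind, envir = .vog_registry))
}

# built-ins installed at load time
register_builtin_plugins <- function() {
  register_plugin("source", "video", open_video, overwrite = TRUE)
  register_plugin("pipeline", "standard", vog_pipeline, overwrite = TRUE)
  register_plugin("calibration", "regression", fit_regression, overwrite = TRUE)
  register_plugin("calibration", "eye_model", fit_eye_model, overwrite = TRUE)
  invisible(NULL)
}
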
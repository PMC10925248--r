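#' Corneal-reflection (glint) detection
#'
#' Glints are small bright specular reflections of the illuminator on the
#' cornea. The vector from glint to pupil centre cancels translations of
#' the camera or head, leaving the rotational gaze signal (pupil-CR
#' method). Centres are sub-pixel, computed as background-subtracted
#' intensity-weighted centroids.
#'
#' @name glint
NULL

#' Detect glints
#'
#' Bright (`>= threshold`) 8-connected components within the size range,
#' optionally restricted to a search region and excluding given pixels
#' (e.g. the pupil mask, so a glint touching the pupil boundary is not
#' merged with it). Results are sorted by descending peak intensity, then
#' descending area.
#'
#' @param image 8-bit grayscale integer matrix
#' @param glint_threshold brightness threshold (inclusive)
#' @param min_size_px2,max_size_px2 component area bounds
#' @param search_roi optional `list(x0, x1, y0, y1)` half-open window
#' @param exclude_mask optional logical matrix of pixels to ignore
#' @param max_glints keep at most this many (by sort order)
#' @return list of glints: each `list(center, area_px2, peak_intensity)`
#' @export
detect_glints <- function(image, glint_threshold, min_size_px2 = 1,
                          max_size_px2 = Inf, search_roi = NULL,
                          exclude_mask = NULL, max_glints = Inf) {
  work <- image
  off <- c(0, 0)
  if (!is.null(search_roi)) {
    r <- search_roi
    r$x0 <- max(0, floor(r$x0)); r$y0 <- max(0, floor(r$y0))
    r$x1 <- min(ncol(image), ceiling(r$x1)); r$y1 <- min(nrow(image), ceiling(r$y1))
    if (r$x1 <= r$x0 || r$y1 <= r$y0) return(list())
    work <- crop_image(image, r)
    off <- c(r$x0, r$y0)
  }
  mask <- work >= glint_threshold
  if (!is.null(exclude_mask)) {
    ex <- exclude_mask[(off[2] + 1):(off[2] + nrow(work)),
                       (off[1] + 1):(off[1] + ncol(work)), drop = FALSE]
    mask <- mask & !ex
  }
  comps <- find_components(mask)
  comps <- Filter(function(cc) cc$area >= min_size_px2 && cc$area <= max_size_px2,
                  comps)
  if (!length(comps)) return(list())
  glints <- lapply(comps, function(cc) {
    vals <- as.numeric(work[cbind(cc$ys + 1L, cc$xs + 1L)])
    w <- vals - glint_threshold + 1  # background-subtracted weights, > 0
    list(center = c(sum(cc$xs * w) / sum(w), sum(cc$ys * w) / sum(w)) + off,
         area_px2 = cc$area,
         peak_intensity = max(vals))
  })
  ord <- order(-vapply(glints, `[[`, numeric(1), "peak_intensity"),
               -vapply(glints, `[[`, numeric(1), "area_px2"))
  glints <- glints[ord]
  if (is.finite(max_glints)) glints <- head(glints, max_glints)
  glints
}

#' Pupil-to-corneal-reflection vector
#'
#' @param pupil_center,glint_center length-2 `(x, y)` or `NULL`
#' @return `pupil - glint` (pixels), or `NULL` if either input is absent
#' @export
pupil_cr_vector <- function(pupil_center, glint_center) {
  if (is.null(pupil_center) || is.null(glint_center)) return(NULL)
  as.numeric(pupil_center) - as.numeric(glint_center)
}
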
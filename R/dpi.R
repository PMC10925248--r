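#' Digital dual-Purkinje (P1/P4) tracking
#'
#' The first Purkinje image (P1, anterior cornea) is the brightest
#' reflection of the illuminator; the fourth (P4, posterior lens surface)
#' is much dimmer and lies near P1. Because P1 and P4 translate together
#' under head/camera motion but separate under eye rotation, their
#' difference vector isolates rotation.
#'
#' @name dpi
NULL

#' Detect the P1/P4 reflection pair
#'
#' P1 is the brightest spot with peak `>= p1_threshold`; P4 is the
#' brightest spot with peak in `[p4_threshold, p1_threshold)` within
#' `p4_search_radius` of P1 (P1's own pixels excluded by component
#' separation). If two P1 candidates lie within 10 percent peak intensity
#' of each other the frame is flagged ambiguous rather than guessed.
#'
#' @param image 8-bit grayscale integer matrix
#' @param settings a `vog_settings`; uses `pipeline.p1_threshold`,
#'   `pipeline.p4_threshold`, `pipeline.p4_search_radius`,
#'   `pipeline.glint_min_size_px2`, `pipeline.glint_max_size_px2`
#' @param exclude_mask optional pixels to ignore (e.g. pupil)
#' @return list `(p1, p4, dpi_vector, found, ambiguous)`; `p1`/`p4` are
#'   glint records or `NULL`; `dpi_vector = p1$center - p4$center` or `NULL`
#' @export
detect_purkinje <- function(image, settings = default_settings(),
                            exclude_mask = NULL) {
  p <- settings$pipeline
  if (p$p1_threshold <= p$p4_threshold) {
    stopf("p1_threshold (%d) must exceed p4_threshold (%d)",
          p$p1_threshold, p$p4_threshold)
  }
  cands <- detect_glints(image, glint_threshold = p$p4_threshold,
                         min_size_px2 = p$glint_min_size_px2,
                         max_size_px2 = p$glint_max_size_px2,
                         exclude_mask = exclude_mask)
  none <- list(p1 = NULL, p4 = NULL, dpi_vector = NULL, found = FALSE,
               ambiguous = FALSE)
  p1_cands <- Filter(function(g) g$peak_intensity >= p$p1_threshold, cands)
  if (!length(p1_cands)) return(none)
  if (length(p1_cands) >= 2 &&
      p1_cands[[2]]$peak_intensity >= 0.9 * p1_cands[[1]]$peak_intensity) {
    none$ambiguous <- TRUE
    return(none)
  }
  p1 <- p1_cands[[1]]
  p4_cands <- Filter(function(g) {
    g$peak_intensity < p$p1_threshold &&
      sqrt(sum((g$center - p1$center)^2)) <= p$p4_search_radius
  }, cands)
  p4 <- if (length(p4_cands)) p4_cands[[1]] else NULL
  list(p1 = p1, p4 = p4,
       dpi_vector = if (is.null(p4)) NULL else p1$center - p4$center,
       found = TRUE, ambiguous = FALSE)
}

#' Differential Purkinje signal
#' @param pair result of [detect_purkinje()]
#' @return `p1 - p4` (pixels) or `NULL` when either member is absent
#' @export
dpi_signal <- function(pair) {
  if (is.null(pair$p1) || is.null(pair$p4)) return(NULL)
  pair$p1$center - pair$p4$center
}
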
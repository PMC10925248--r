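#' Bounded FIFO frame buffer
#'
#' Connects frame grabbing to processing. The buffer holds at most
#' `capacity` frames; when full, the incoming (newest) frame is rejected
#' and counted as dropped, preserving the temporal continuity of the
#' frames already queued. Dequeue order equals enqueue order.
#'
#' Implemented as a preallocated ring; all operations O(1).
#'
#' @param capacity positive integer
#' @return a `vog_buffer` (mutable environment)
#' @examples
#' b <- frame_buffer(2)
#' buffer_enqueue(b, 1); buffer_enqueue(b, 2)
#' buffer_enqueue(b, 3)  # "dropped"
#' buffer_dequeue(b)     # 1
#' @export
frame_buffer <- function(capacity) {
  stopifnot(is_count(capacity), capacity >= 1)
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$ring <- vector("list", capacity)
  b$head <- 0L   # index of next dequeue (0-based)
  b$count <- 0L
  b$n_enqueued <- 0L
  b$n_dropped <- 0L
  class(b) <- "vog_buffer"
  b
}

#' Enqueue a frame
#' @param buffer a `vog_buffer`
#' @param frame any value (typically a `vog_frame`)
#' @return `"accepted"` or `"dropped"`
#' @export
buffer_enqueue <- function(buffer, frame) {
  if (buffer$count >= buffer$capacity) {
    buffer$n_dropped <- buffer$n_dropped + 1L
    return("dropped")
  }
  slot <- (buffer$head + buffer$count) %% buffer$capacity
  buffer$ring[[slot + 1L]] <- frame
  buffer$count <- buffer$count + 1L
  buffer$n_enqueued <- buffer$n_enqueued + 1L
  "accepted"
}

#' Dequeue the oldest frame
#' @param buffer a `vog_buffer`
#' @return the oldest queued value, or `NULL` if empty
#' @export
buffer_dequeue <- function(buffer) {
  if (buffer$count == 0L) return(NULL)
  out <- buffer$ring[[buffer$head + 1L]]
  buffer$ring[buffer$head + 1L] <- list(NULL)
  buffer$head <- (buffer$head + 1L) %% buffer$capacity
  buffer$count <- buffer$count - 1L
  out
}

#' Number of frames currently queued
#' @param buffer a `vog_buffer`
#' @return integer count
#' @export
buffer_size <- function(buffer) buffer$count
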
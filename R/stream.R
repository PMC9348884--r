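#' Sliding FIFO buffer for instance-level classification
#'
#' At 10 Hz the camera delivers ten frames per second; the stream classifier
#' smooths per-frame verdicts with a simple moving average over a
#' first-in-first-out buffer of the most recent `sma_window` frames. If any
#' frame in the window is a hit, the whole instance is a hit. Before the
#' buffer fills, decisions use the partial window, which preserves the
#' "any hit implies hit" semantics from the first frame.
#'
#' @param sma_window Window width in frames (>= 1).
#' @return A `jet_fifo` object with mutable internal state; feed it with
#'   [fifo_push()].
#' @seealso [classify_stream()]
#' @export
#' @examples
#' buf <- fifo_buffer(10)
#' for (i in 0:8) fifo_push(buf, i, FALSE)
#' fifo_push(buf, 9, TRUE)$is_hit  # one hit in ten -> instance hit
fifo_buffer <- function(sma_window = 10L) {
  sma_window <- as.integer(sma_window)
  if (is.na(sma_window) || sma_window < 1L) {
    stop("`sma_window` must be a positive integer", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$sma_window <- sma_window
  e$hits <- logical(0)
  e$last_index <- -Inf
  class(e) <- "jet_fifo"
  e
}

#' Push a frame verdict into a FIFO buffer
#'
#' Evicts the oldest entry once the buffer is full, appends the new verdict
#' and returns the instance decision for the current window. Verdicts must
#' arrive in strictly increasing index order.
#'
#' @param buffer A [fifo_buffer()].
#' @param index Frame index (strictly greater than the previous push).
#' @param is_hit Logical per-frame verdict; a [classify_frame()] result may
#'   be passed instead, in which case its index and verdict are used.
#' @return An `instance verdict` list: `window_end_index`, `frame_hits`
#'   (logical vector, oldest first), `is_hit` (OR over the window) and
#'   `window_full`.
#' @export
fifo_push <- function(buffer, index, is_hit) {
  stopifnot(inherits(buffer, "jet_fifo"))
  if (inherits(index, "jet_verdict")) {
    v <- index
    index <- v$index
    is_hit <- v$is_hit
  }
  index <- as.numeric(index)
  if (!is.finite(index) || index <= buffer$last_index) {
    stop("frame verdicts must be pushed in increasing index order (got ",
         index, " after ", buffer$last_index, ")", call. = FALSE)
  }
  buffer$last_index <- index
  h <- c(buffer$hits, isTRUE(as.logical(is_hit)))
  if (length(h) > buffer$sma_window) {
    h <- h[-1]  # first in, first out
  }
  buffer$hits <- h
  list(
    window_end_index = index,
    frame_hits = h,
    is_hit = any(h),
    window_full = length(h) == buffer$sma_window
  )
}

# Trailing windowed OR via cumulative sums; x logical, w >= 1.
windowed_or <- function(x, w) {
  s <- cumsum(as.integer(x))
  lagged <- c(rep(0L, min(w, length(x))), head(s, -w))[seq_along(x)]
  if (w >= length(x)) lagged <- rep(0L, length(x))
  (s - lagged) > 0L
}

#' Aggregate per-frame verdicts into instance verdicts
#'
#' Applies the FIFO/SMA rule to an ordered stream of per-frame hit/miss
#' verdicts: in `"sliding"` mode (default) every frame gets an instance
#' verdict equal to the OR over the trailing `sma_window` frames; in
#' `"tumbling"` mode frames are grouped into disjoint blocks of `sma_window`
#' frames (the "1 s instance" view at 10 Hz) and every frame in a block
#' shares the block's OR.
#'
#' @param verdicts A data frame with logical column `is_hit` ordered by
#'   frame, or a logical vector.
#' @param cfg A [jet_config()]; uses `sma_window` and `window_mode`.
#' @return The input as a tibble with columns `instance_hit` and
#'   `window_full` appended (a new tibble when a vector was given).
#' @export
classify_stream <- function(verdicts, cfg) {
  if (is.logical(verdicts)) {
    verdicts <- tibble::tibble(is_hit = verdicts)
  }
  verdicts <- tibble::as_tibble(verdicts)
  h <- verdicts$is_hit
  n <- length(h)
  w <- cfg$sma_window
  if (n == 0L) {
    verdicts$instance_hit <- logical(0)
    verdicts$window_full <- logical(0)
    return(verdicts)
  }
  if (cfg$window_mode == "sliding") {
    verdicts$instance_hit <- windowed_or(h, w)
    verdicts$window_full <- seq_len(n) >= w
  } else {
    block <- (seq_len(n) - 1L) %/% w
    block_hit <- tapply(h, block, any)
    verdicts$instance_hit <- as.logical(block_hit[as.character(block)])
    full_len <- tapply(h, block, length)
    verdicts$window_full <- as.vector(full_len[as.character(block)]) == w
  }
  verdicts
}
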
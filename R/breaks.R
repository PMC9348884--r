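#' Row-wise jet presence profile
#'
#' Scans the binarized ROI row by row. A row counts as containing jet
#' material when it holds at least `min_run` contiguous value-1 pixels;
#' requiring a short run (default 2) keeps isolated salt-noise pixels from
#' mimicking the jet. Row 1 corresponds to the nozzle tip row of the ROI.
#'
#' @param mask A [new_mask()] (or 0/1 matrix) cropped to the ROI.
#' @param min_run Minimum contiguous run of 1s for presence.
#' @return Logical vector, one element per mask row.
#' @seealso [find_breaks()]
#' @export
jet_profile <- function(mask, min_run = 2L) {
  v <- if (inherits(mask, "jet_mask")) mask$values else mask
  if (!is.matrix(v) || nrow(v) == 0L || ncol(v) == 0L) {
    stop("mask must be a non-empty matrix", call. = FALSE)
  }
  min_run <- as.integer(min_run)
  if (min_run == 1L) {
    return(rowSums(v) > 0L)
  }
  if (ncol(v) < min_run) {
    return(rep(FALSE, nrow(v)))
  }
  # presence of a run of length >= min_run == some window of min_run
  # consecutive columns is all ones
  acc <- v[, 1:(ncol(v) - min_run + 1L), drop = FALSE]
  if (min_run > 1L) {
    for (k in 2:min_run) {
      acc <- acc * v[, k:(ncol(v) - min_run + k), drop = FALSE]
    }
  }
  rowSums(acc) > 0L
}

#' Find qualifying breaks in a jet presence profile
#'
#' A break is a maximal run of jet-free rows that (a) is bounded by
#' jet-bearing rows on both sides, (b) is no longer than `max_gap_px`, and
#' (c) starts within `max_break_distance_um` of the nozzle tip. Condition (c)
#' excludes the natural droplet-breakup region, which begins well downstream
#' of the interaction point; the trailing jet-free region below the last
#' droplet is unbounded and never qualifies via (a).
#'
#' @param profile Logical vector from [jet_profile()]; element 1 is the
#'   nozzle tip row.
#' @param cfg A [jet_config()]; uses `max_gap_px`, `max_break_distance_um`
#'   and `pixel_size_um`. Distance is measured from the tip row to the
#'   upstream edge of the gap: row r lies `(r - 1) * pixel_size_um`
#'   micrometres from the tip.
#' @return A tibble with one row per break: `gap_start_row`, `gap_end_row`
#'   (1-based, inclusive), `gap_px`, `distance_um`.
#' @export
#' @examples
#' cfg <- jet_config(pixel_size_um = 1)
#' prof <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 30))
#' find_breaks(prof, cfg)  # one 10 px break 30 um from the nozzle
find_breaks <- function(profile, cfg) {
  if (length(profile) == 0L) {
    stop("profile must be non-empty", call. = FALSE)
  }
  empty <- tibble::tibble(gap_start_row = integer(), gap_end_row = integer(),
                          gap_px = integer(), distance_um = numeric())
  r <- rle(as.logical(profile))
  if (length(r$lengths) < 3L) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- which(!r$values)
  interior <- interior[interior > 1L & interior < length(r$values)]
  if (length(interior) == 0L) return(empty)
  out <- tibble::tibble(
    gap_start_row = starts[interior],
    gap_end_row = ends[interior],
    gap_px = r$lengths[interior],
    distance_um = (starts[interior] - 1) * cfg$pixel_size_um
  )
  dplyr::filter(out, .data$gap_px <= cfg$max_gap_px,
                .data$distance_um <= cfg$max_break_distance_um)
}

#' Classify one frame as hit or miss
#'
#' Composes the full per-frame pipeline: template matching, ROI derivation
#' and cropping, adaptive binarization, row-wise jet profiling and break
#' scanning. The frame is a hit when at least one qualifying break is found.
#' A frame in which no jet rows are detected at all is classified as a miss
#' and flagged `no_jet` for operator review (an unstable or absent jet is
#' not evidence of beam-jet overlap).
#'
#' @param frame A [new_frame()] object.
#' @param template A [jet_template()] object.
#' @param cfg A [jet_config()].
#' @param roi Optional pre-computed [derive_roi()] result; when supplied the
#'   template-matching step is skipped (used by [process_sequence()] to
#'   match once per run).
#' @return A `jet_verdict` list: `index`, `is_hit`, `events` (tibble from
#'   [find_breaks()]), `no_jet`, `n_jet_rows`, and the `roi` used.
#' @export
classify_frame <- function(frame, template, cfg, roi = NULL) {
  if (is.null(roi)) {
    m <- match_template(frame, template)
    roi <- derive_roi(m, cfg, dim(as_pixels(frame)))
  }
  crop <- crop_frame(frame, roi)
  mask <- binarize(crop, cfg)
  prof <- jet_profile(mask, cfg$min_run)
  n_jet <- sum(prof)
  events <- if (n_jet == 0L) {
    find_breaks(c(TRUE, FALSE), cfg)[0, ]  # typed empty tibble
  } else {
    find_breaks(prof, cfg)
  }
  structure(
    list(
      index = if (inherits(frame, "jet_frame")) frame$index else NA_integer_,
      is_hit = nrow(events) > 0L,
      events = events,
      no_jet = n_jet == 0L,
      n_jet_rows = as.integer(n_jet),
      roi = roi
    ),
    class = "jet_verdict"
  )
}

#' @export
print.jet_verdict <- function(x, ...) {
  cat(sprintf("<jet_verdict> frame %s: %s (%d break%s%s)\n",
              x$index, if (x$is_hit) "HIT" else "miss", nrow(x$events),
              if (nrow(x$events) == 1) "" else "s",
              if (x$no_jet) ", no jet detected" else ""))
  invisible(x)
}

# One-row tibble summary of a verdict, used by the sequence pipeline/CSV.
verdict_row <- function(v) {
  tibble::tibble(
    index = v$index,
    is_hit = v$is_hit,
    n_events = nrow(v$events),
    first_gap_px = if (nrow(v$events)) v$events$gap_px[1] else NA_integer_,
    first_distance_um = if (nrow(v$events)) v$events$distance_um[1] else NA_real_,
    no_jet = v$no_jet
  )
}
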
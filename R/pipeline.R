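#' Run the full hit/miss pipeline over a frame sequence
#'
#' Template matching runs on the first frame and the resulting ROI is reused
#' for the rest of the sequence (nozzle and background are effectively
#' static over a run); set `cfg$rematch_every > 0` to re-match periodically.
#' Each frame is cropped, binarized and scanned for breaks, and the
#' per-frame verdicts are smoothed with the sliding FIFO window.
#'
#' @param frames List of [new_frame()] objects in acquisition order.
#' @param template A [jet_template()]; defaults to the configured
#'   `template_path`, or to [default_nozzle_template()] when none is set.
#' @param cfg A [jet_config()].
#' @return A `jet_run` tibble with one row per frame: `index`, `is_hit`
#'   (per-frame), `n_events`, `first_gap_px`, `first_distance_um`, `no_jet`,
#'   `instance_hit`, `window_full`. Attributes `match`, `roi` and `config`
#'   carry the nozzle localization and settings used.
#' @export
#' @examples
#' seqs <- generate_sequence(12, scene_params(),
#'                           hit_pattern = rep(c(FALSE, TRUE), 6))
#' run <- process_sequence(seqs$frames, cfg = jet_config(pixel_size_um = 1))
#' head(run, 3)
process_sequence <- function(frames, template = NULL, cfg) {
  stopifnot(inherits(cfg, "jet_config"))
  if (is.null(template)) {
    template <- if (!is.null(cfg$template_path)) {
      tf <- read_frame(cfg$template_path, pixel_size_um = cfg$pixel_size_um)
      # tip assumed at bottom-centre for file-supplied templates
      jet_template(tf$pixels, nrow(tf$pixels), (ncol(tf$pixels) + 1L) %/% 2L)
    } else {
      default_nozzle_template()
    }
  }
  if (length(frames) == 0L) {
    out <- classify_stream(verdict_row(
      structure(list(index = 0L, is_hit = FALSE,
                     events = data.frame(), no_jet = TRUE, n_jet_rows = 0L),
                class = "jet_verdict"))[0, ], cfg)
    return(structure(out, class = c("jet_run", class(out))))
  }
  match <- NULL
  roi <- NULL
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    need_match <- is.null(roi) ||
      (cfg$rematch_every > 0L && (i - 1L) %% cfg$rematch_every == 0L)
    if (need_match) {
      match <- match_template(f, template)
      roi <- derive_roi(match, cfg, dim(as_pixels(f)))
    }
    rows[[i]] <- verdict_row(classify_frame(f, template, cfg, roi = roi))
  }
  out <- classify_stream(dplyr::bind_rows(rows), cfg)
  structure(out, class = c("jet_run", class(out)),
            match = match, roi = roi, config = cfg)
}

#' @export
glance.jet_run <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x),
    frame_hits = sum(x$is_hit),
    instance_hits = sum(x$instance_hit),
    no_jet_frames = sum(x$no_jet),
    sma_window = attr(x, "config")$sma_window
  )
}

#' Write a run's per-frame/instance verdicts to CSV
#'
#' Columns: `index,is_hit,n_events,first_gap_px,first_distance_um,no_jet,`
#' `instance_hit,window_full`.
#'
#' @param run A [process_sequence()] result (any data frame works).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(run, path) {
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  invisible(path)
}
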
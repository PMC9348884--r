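#' Pipeline configuration
#'
#' Bundles every tunable of the hit/miss pipeline. The defaults reproduce the
#' published operating point: a 13 x 13 Gaussian-weighted local threshold
#' window with offset C = 7 on the 16-bit scale, a maximum qualifying gap of
#' 20 px, a maximum break distance of 200 um from the nozzle, and a 10-frame
#' sliding FIFO window (1 s at 10 Hz).
#'
#' @param pixel_size_um Micrometres per pixel. Mandatory: the break-distance
#'   rule is specified in micrometres and cannot be applied without the
#'   optical scale.
#' @param template_path Optional path to the nozzle template image; `NULL`
#'   when the template is passed as an object.
#' @param roi_length_px Vertical extent of the region of interest downstream
#'   of the nozzle tip, in pixels. Sized to exceed the jet breakup length by a
#'   comfortable margin so one setting serves many nozzles.
#' @param roi_halfwidth_px Lateral half-extent of the ROI about the tip
#'   column, in pixels.
#' @param threshold_window Odd window width W (pixels) of the adaptive local
#'   threshold.
#' @param threshold_offset Offset C subtracted from the Gaussian-weighted
#'   local mean, on the 16-bit intensity scale. The default C = 7 suits
#'   low-noise 16-bit data; for noisier images C should grow with the noise
#'   (about 3 standard deviations of the background noise works well).
#' @param threshold_sigma Gaussian weight sigma (pixels). `NULL` uses the
#'   conventional window-to-sigma mapping `0.3 * ((W - 1)/2 - 1) + 0.8`.
#' @param max_gap_px Largest gap (in rows) that still counts as a beam-induced
#'   break.
#' @param max_break_distance_um Breaks starting farther than this from the
#'   nozzle tip are attributed to natural droplet breakup and ignored.
#' @param sma_window Width of the sliding FIFO window (frames). 1 gives
#'   per-frame decisions.
#' @param polarity `"dark_jet"` for backlit shadowgraph images (dark jet on a
#'   bright background; the default) or `"bright_jet"`. In both cases jet
#'   pixels map to 1 in the binary mask.
#' @param min_run Minimum number of contiguous mask pixels in a row for the
#'   row to count as containing jet material; suppresses salt noise.
#' @param rematch_every Re-run template matching every this many frames when
#'   processing a sequence; 0 (default) matches once on the first frame and
#'   reuses the ROI, exploiting that nozzle and background stay put.
#' @param window_mode `"sliding"` (default; one instance verdict per frame
#'   over the trailing window) or `"tumbling"` (disjoint blocks of
#'   `sma_window` frames).
#' @return A `jet_config` list.
#' @seealso [load_config()]
#' @export
#' @examples
#' cfg <- jet_config(pixel_size_um = 1)
#' cfg$threshold_window  # 13
#' cfg$threshold_offset  # 7
jet_config <- function(pixel_size_um,
                       template_path = NULL,
                       roi_length_px = 400L,
                       roi_halfwidth_px = 100L,
                       threshold_window = 13L,
                       threshold_offset = 7,
                       threshold_sigma = NULL,
                       max_gap_px = 20L,
                       max_break_distance_um = 200,
                       sma_window = 10L,
                       polarity = c("dark_jet", "bright_jet"),
                       min_run = 2L,
                       rematch_every = 0L,
                       window_mode = c("sliding", "tumbling")) {
  if (missing(pixel_size_um)) {
    stop("`pixel_size_um` is required and has no default", call. = FALSE)
  }
  polarity <- match.arg(polarity)
  window_mode <- match.arg(window_mode)
  check_pos <- function(x, name, int = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
        (int && x != round(x))) {
      stop("`", name, "` must be a positive ",
           if (int) "integer" else "number", call. = FALSE)
    }
    if (int) as.integer(x) else as.numeric(x)
  }
  pixel_size_um <- check_pos(pixel_size_um, "pixel_size_um", int = FALSE)
  roi_length_px <- check_pos(roi_length_px, "roi_length_px")
  roi_halfwidth_px <- check_pos(roi_halfwidth_px, "roi_halfwidth_px")
  threshold_window <- check_pos(threshold_window, "threshold_window")
  if (threshold_window < 3L || threshold_window %% 2L == 0L) {
    stop("`threshold_window` must be an odd integer >= 3, got ",
         threshold_window, call. = FALSE)
  }
  if (!is.numeric(threshold_offset) || length(threshold_offset) != 1L ||
      is.na(threshold_offset)) {
    stop("`threshold_offset` must be a single number", call. = FALSE)
  }
  if (is.null(threshold_sigma)) {
    threshold_sigma <- 0.3 * ((threshold_window - 1) / 2 - 1) + 0.8
  } else {
    threshold_sigma <- check_pos(threshold_sigma, "threshold_sigma", int = FALSE)
  }
  max_gap_px <- check_pos(max_gap_px, "max_gap_px")
  max_break_distance_um <- check_pos(max_break_distance_um,
                                     "max_break_distance_um", int = FALSE)
  sma_window <- check_pos(sma_window, "sma_window")
  min_run <- check_pos(min_run, "min_run")
  rematch_every <- as.integer(rematch_every)
  if (is.na(rematch_every) || rematch_every < 0L) {
    stop("`rematch_every` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(
      pixel_size_um = pixel_size_um,
      template_path = template_path,
      roi_length_px = roi_length_px,
      roi_halfwidth_px = roi_halfwidth_px,
      threshold_window = threshold_window,
      threshold_offset = as.numeric(threshold_offset),
      threshold_sigma = threshold_sigma,
      max_gap_px = max_gap_px,
      max_break_distance_um = max_break_distance_um,
      sma_window = sma_window,
      polarity = polarity,
      min_run = min_run,
      rematch_every = rematch_every,
      window_mode = window_mode
    ),
    class = "jet_config"
  )
}

#' @export
print.jet_config <- function(x, ...) {
  cat("<jet_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys match the arguments of [jet_config()]; unspecified keys take the
#' defaults. `pixel_size_um` must be present.
#'
#' @param path Path to a YAML key:value file.
#' @return A [jet_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("no such config file: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- setdiff(names(formals(jet_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$pixel_size_um)) {
    stop("config must set `pixel_size_um` (no default exists)", call. = FALSE)
  }
  do.call(jet_config, raw)
}
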
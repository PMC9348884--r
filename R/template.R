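#' Nozzle template
#'
#' A template is a small two-level outline image of the nozzle plus the
#' position of the nozzle tip within it. Template matching slides it over a
#' frame and the tip position of the best placement anchors the region of
#' interest.
#'
#' @param pixels Numeric matrix; any two-level (or richer) rendering of the
#'   nozzle outline. Must be strictly smaller than the frames it is matched
#'   against, in both dimensions.
#' @param tip_row,tip_col 1-based position of the nozzle tip within the
#'   template.
#' @return A `jet_template` object.
#' @seealso [default_nozzle_template()], [match_template()]
#' @export
jet_template <- function(pixels, tip_row, tip_col) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("template `pixels` must be a numeric matrix", call. = FALSE)
  }
  tip_row <- as.integer(tip_row)
  tip_col <- as.integer(tip_col)
  if (tip_row < 1L || tip_row > nrow(pixels) ||
      tip_col < 1L || tip_col > ncol(pixels)) {
    stop("tip position must lie inside the template", call. = FALSE)
  }
  structure(list(pixels = pixels, tip_row = tip_row, tip_col = tip_col),
            class = "jet_template")
}

#' @export
print.jet_template <- function(x, ...) {
  cat(sprintf("<jet_template> %d x %d px, tip at (%d, %d)\n",
              nrow(x$pixels), ncol(x$pixels), x$tip_row, x$tip_col))
  invisible(x)
}

# Logical raster of the GDVN outline used by both the default template and
# the synthetic scene renderer, so a noiseless synthetic nozzle matches the
# template exactly. A trapezoid tapering from the mount to the tip, with the
# tip on the bottom row at the centre column.
nozzle_silhouette <- function(height, width, halfwidth_top, halfwidth_tip) {
  centre <- (width + 1L) %/% 2L
  hw <- round(halfwidth_top +
                (halfwidth_tip - halfwidth_top) * (seq_len(height) - 1) /
                (height - 1))
  mask <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    cols <- max(1L, centre - hw[r]):min(width, centre + hw[r])
    mask[r, cols] <- TRUE
  }
  mask
}

#' Default GDVN outline template
#'
#' Emits the simple geometric nozzle outline used by the synthetic scene
#' generator: a dark trapezoid tapering to the jet orifice, on a bright
#' background, with the tip at the bottom-centre pixel.
#'
#' @param height,width Template size in pixels (`width` is forced odd so the
#'   tip column is central).
#' @param halfwidth_top,halfwidth_tip Silhouette half-widths at the top row
#'   and at the tip, in pixels.
#' @param background,foreground Intensities for background and silhouette on
#'   the 16-bit scale. Only their contrast matters to ZNCC matching.
#' @return A [jet_template()] object.
#' @export
default_nozzle_template <- function(height = 60L, width = 97L,
                                    halfwidth_top = 40L, halfwidth_tip = 5L,
                                    background = 65535, foreground = 0) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  sil <- nozzle_silhouette(height, width, halfwidth_top, halfwidth_tip)
  px <- matrix(background, height, width)
  px[sil] <- foreground
  jet_template(px, tip_row = height, tip_col = (width + 1L) %/% 2L)
}

# Summed-area helper: sums of img over every th x tw window, for all valid
# top-left placements. Returns an (H-th+1) x (W-tw+1) matrix.
window_sums <- function(img, th, tw) {
  cs <- rbind(0, apply(img, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  H <- nrow(img); W <- ncol(img)
  r1 <- 1:(H - th + 1); c1 <- 1:(W - tw + 1)
  cs[r1 + th, c1 + tw, drop = FALSE] - cs[r1 + th, c1, drop = FALSE] -
    cs[r1, c1 + tw, drop = FALSE] + cs[r1, c1, drop = FALSE]
}

# Cross-correlation of img with a zero-mean kernel at all valid placements,
# via circular FFT correlation (no wrap-around inside the valid region).
valid_crosscor <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  th <- nrow(kern); tw <- ncol(kern)
  kp <- matrix(0, H, W)
  kp[1:th, 1:tw] <- kern
  cc <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(kp)), inverse = TRUE)) / (H * W)
  cc[1:(H - th + 1), 1:(W - tw + 1), drop = FALSE]
}

#' Zero-normalized cross-correlation map of a template over a frame
#'
#' @param frame A [new_frame()] object or numeric matrix.
#' @param template A [jet_template()] object or numeric matrix.
#' @return Matrix of ZNCC scores in \[-1, 1\], one per valid top-left
#'   placement. Windows (or templates) with zero variance score 0.
#' @seealso [match_template()]
#' @export
zncc_map <- function(frame, template) {
  img <- as_pixels(frame)
  tpx <- if (inherits(template, "jet_template")) template$pixels else template
  th <- nrow(tpx); tw <- ncol(tpx)
  if (th >= nrow(img) || tw >= ncol(img)) {
    stop("template (", th, " x ", tw, ") must be strictly smaller than the ",
         "frame (", nrow(img), " x ", ncol(img), ") in both dimensions",
         call. = FALSE)
  }
  n <- th * tw
  t0 <- tpx - mean(tpx)
  sst <- sum(t0^2)
  s1 <- window_sums(img, th, tw)
  s2 <- window_sums(img^2, th, tw)
  ssw <- pmax(s2 - s1^2 / n, 0)
  if (sst <= 0) {
    return(matrix(0, nrow(s1), ncol(s1)))
  }
  num <- valid_crosscor(img, t0)
  denom <- sqrt(ssw * sst)
  # scale-aware cutoff: windows whose variance is numerically zero score 0
  eps <- 1e-8 * sqrt(sst) * max(1, max(abs(img)))
  score <- ifelse(denom > eps, num / denom, 0)
  pmin(pmax(score, -1), 1)
}

#' Locate the nozzle by template matching
#'
#' Slides the template over the frame and returns the placement maximizing
#' the zero-normalized cross-correlation coefficient (template and window
#' each mean-subtracted and scaled by their standard deviations). ZNCC is
#' invariant to affine intensity changes `a * I + b` (a > 0), which buys
#' robustness to illumination drift. Ties are broken by smallest row, then
#' smallest column.
#'
#' @inheritParams zncc_map
#' @return A `jet_match` list: `top_left` (row, col) of the best placement,
#'   `score` in \[-1, 1\], and `tip` (row, col) of the nozzle tip in frame
#'   coordinates (`top_left + tip_offset - 1`).
#' @export
match_template <- function(frame, template) {
  stopifnot(inherits(template, "jet_template"))
  score <- zncc_map(frame, template)
  best <- max(score)
  hits <- which(score == best, arr.ind = TRUE)
  # row-major tie-break: smallest row, then smallest column
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  tl <- as.integer(hits[1, ])
  structure(
    list(
      top_left = c(row = tl[1], col = tl[2]),
      score = best,
      tip = c(row = tl[1] + template$tip_row - 1L,
              col = tl[2] + template$tip_col - 1L)
    ),
    class = "jet_match"
  )
}

#' @export
print.jet_match <- function(x, ...) {
  cat(sprintf("<jet_match> top-left (%d, %d), tip (%d, %d), score %.4f\n",
              x$top_left[1], x$top_left[2], x$tip[1], x$tip[2], x$score))
  invisible(x)
}

#' Derive the region of interest from a nozzle match
#'
#' The ROI is anchored at the matched nozzle tip: it starts at the tip row,
#' extends `roi_length_px` downstream (the jet flows down the image) and
#' spans the tip column +/- `roi_halfwidth_px`, clipped to the frame.
#'
#' @param match A [match_template()] result.
#' @param cfg A [jet_config()].
#' @param frame_shape Integer vector `c(rows, cols)` of the frame.
#' @return A `jet_roi` list with 1-based `top`, `left`, `height`, `width`.
#' @export
derive_roi <- function(match, cfg, frame_shape) {
  tip_r <- match$tip[["row"]]; tip_c <- match$tip[["col"]]
  nr <- frame_shape[1]; nc <- frame_shape[2]
  top <- max(1L, tip_r)
  bottom <- min(nr, tip_r + cfg$roi_length_px - 1L)
  left <- max(1L, tip_c - cfg$roi_halfwidth_px)
  right <- min(nc, tip_c + cfg$roi_halfwidth_px)
  if (top > nr || bottom < 1L || left > nc || right < 1L || bottom < top ||
      right < left) {
    stop("region of interest falls entirely outside the frame", call. = FALSE)
  }
  structure(
    list(top = as.integer(top), left = as.integer(left),
         height = as.integer(bottom - top + 1L),
         width = as.integer(right - left + 1L)),
    class = "jet_roi"
  )
}

#' @export
print.jet_roi <- function(x, ...) {
  cat(sprintf("<jet_roi> top %d, left %d, %d x %d px\n",
              x$top, x$left, x$height, x$width))
  invisible(x)
}

#' Crop a frame to a region of interest
#'
#' @param frame A [new_frame()] object.
#' @param roi A [derive_roi()] result.
#' @return A [new_frame()] with the boxed sub-image; index and pixel scale
#'   preserved.
#' @export
crop_frame <- function(frame, roi) {
  px <- as_pixels(frame)
  if (roi$top < 1L || roi$left < 1L ||
      roi$top + roi$height - 1L > nrow(px) ||
      roi$left + roi$width - 1L > ncol(px)) {
    stop("ROI is not contained in the frame", call. = FALSE)
  }
  sub <- px[roi$top:(roi$top + roi$height - 1L),
            roi$left:(roi$left + roi$width - 1L), drop = FALSE]
  f <- frame
  if (inherits(frame, "jet_frame")) {
    f$pixels <- sub
    f
  } else {
    sub
  }
}
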
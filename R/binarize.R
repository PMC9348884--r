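# Symmetric (edge-duplicating) reflection padding by p pixels on every side.
pad_reflect <- function(m, p) {
  if (p == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  if (p > H || p > W) {
    stop("padding exceeds image size", call. = FALSE)
  }
  ri <- c(p:1, 1:H, H:(H - p + 1))
  ci <- c(p:1, 1:W, W:(W - p + 1))
  m[ri, ci, drop = FALSE]
}

# 1-D Gaussian taps of length W, normalized to sum 1.
gaussian_taps <- function(W, sigma) {
  x <- seq_len(W) - (W + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian-weighted local mean
#'
#' Per-pixel weighted mean over the `W` x `W` window centred on each pixel,
#' with weights a normalized 2-D Gaussian of width `sigma`. This is the
#' moving reference level from which the adaptive threshold is derived.
#' Borders are handled by symmetric reflection padding. The 2-D Gaussian is
#' separable, so the filter runs as two banded matrix products.
#'
#' @param img A [new_frame()] or numeric matrix.
#' @param W Odd window width in pixels, `W <= min(dim(img))`.
#' @param sigma Gaussian width in pixels; default is the conventional mapping
#'   `0.3 * ((W - 1)/2 - 1) + 0.8`.
#' @return Numeric matrix of local means, same shape as the input.
#' @seealso [binarize()]
#' @export
local_gaussian_mean <- function(img, W = 13L,
                                sigma = 0.3 * ((W - 1) / 2 - 1) + 0.8) {
  px <- as_pixels(img)
  W <- as.integer(W)
  if (W < 3L || W %% 2L == 0L) {
    stop("`W` must be an odd integer >= 3, got ", W, call. = FALSE)
  }
  if (W > min(dim(px))) {
    stop("`W` (", W, ") exceeds the smallest image dimension (",
         min(dim(px)), ")", call. = FALSE)
  }
  p <- (W - 1L) %/% 2L
  g <- gaussian_taps(W, sigma)
  padded <- pad_reflect(px, p)
  H <- nrow(px); Wd <- ncol(px)
  # banded convolution operators: A (H x H+2p) for rows, B (Wd x Wd+2p) for cols
  A <- matrix(0, H, H + 2L * p)
  B <- matrix(0, Wd, Wd + 2L * p)
  for (k in seq_len(W)) {
    A[cbind(seq_len(H), seq_len(H) + k - 1L)] <- g[k]
    B[cbind(seq_len(Wd), seq_len(Wd) + k - 1L)] <- g[k]
  }
  A %*% padded %*% t(B)
}

#' Binarize a greyscale image with an adaptive local threshold
#'
#' Each pixel is compared against the Gaussian-weighted mean of its
#' `W` x `W` neighbourhood minus a fixed offset `C`, which makes the
#' threshold track non-uniform illumination. With the default `dark_jet`
#' polarity (backlit shadowgraph imaging) a pixel maps to 1 when it is
#' darker than `local mean - C`, so jet material is white (1) in the mask
#' and background is black (0); with `bright_jet` the comparison flips to
#' `pixel > local mean + C`.
#'
#' @param img A [new_frame()] or numeric matrix, at least `W` x `W`.
#' @param cfg A [jet_config()]; `threshold_window` (W = 13),
#'   `threshold_offset` (C = 7), `threshold_sigma` and `polarity` are used.
#' @return A `jet_mask` object: integer matrix over \{0, 1\}, same shape as
#'   the input.
#' @export
#' @examples
#' cfg <- jet_config(pixel_size_um = 1)
#' img <- matrix(50000, 40, 40)
#' img[, 20:22] <- 10000          # dark vertical stripe
#' m <- binarize(img, cfg)
#' range(m$values)
binarize <- function(img, cfg) {
  px <- as_pixels(img)
  mu <- local_gaussian_mean(px, cfg$threshold_window, cfg$threshold_sigma)
  v <- if (cfg$polarity == "dark_jet") {
    px < mu - cfg$threshold_offset
  } else {
    px > mu + cfg$threshold_offset
  }
  new_mask(matrix(as.integer(v), nrow(px), ncol(px)))
}

#' Construct a binary jet mask
#'
#' @param values Matrix over \{0, 1\}; 1 marks jet material.
#' @return A `jet_mask` object.
#' @export
new_mask <- function(values) {
  if (!is.matrix(values) || !all(values %in% c(0L, 1L))) {
    stop("mask values must form a matrix over {0, 1}", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  structure(list(values = values), class = "jet_mask")
}

#' @export
print.jet_mask <- function(x, ...) {
  cat(sprintf("<jet_mask> %d x %d px, %.1f%% jet\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$values)))
  invisible(x)
}

#' @export
dim.jet_mask <- function(x) dim(x$values)

#' Write a binary mask as an 8-bit PNG (0/255) for visual inspection
#'
#' @param mask A [new_mask()] object.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$values * 1.0, path)
  invisible(path)
}
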
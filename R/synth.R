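#' Parameters of a synthetic shadowgraph scene
#'
#' Describes one rendered frame: a dark nozzle silhouette at the top of a
#' bright backlit field, a dark quasi-vertical jet column flowing down from
#' the nozzle tip, natural droplet breakup beyond `breakup_length_um`, and,
#' for a hit, a full-width gap (optionally with splatter speckle) centred
#' `break_center_um` below the tip. Identical parameters (including `seed`)
#' render bit-identical frames.
#'
#' Defaults emulate the phenomenology of a GDVN water jet viewed at
#' 1 um/pixel: a few-pixel-wide jet, breakup at 300 um (beyond the 200 um
#' break-distance cut, as droplets form well downstream of the interaction
#' region) and an interaction point 100 um from the nozzle.
#'
#' @param height_px,width_px Frame size in pixels.
#' @param background_level Backlit background intensity (16-bit scale).
#' @param jet_level Intensity of jet, nozzle silhouette and splatter (dark).
#' @param nozzle_tip_rc Integer `(row, col)` of the nozzle tip.
#' @param jet_width_px Jet column width in pixels.
#' @param jet_angle_deg Jet inclination from vertical, degrees.
#' @param breakup_length_um Distance from the tip at which the continuous
#'   column disintegrates into droplets.
#' @param is_hit Whether the X-ray pulse hit the jet in this frame.
#' @param break_center_um Axial distance of the hit-induced gap centre from
#'   the tip; must be less than `breakup_length_um`.
#' @param break_gap_px Axial extent of the hit-induced gap, in rows.
#' @param splatter Render speckle ejected laterally around the break
#'   (hits only). Off by default; the speckle model is phenomenological,
#'   not calibrated.
#' @param illum_gradient Linear illumination ramp, intensity units per
#'   column, centred on the frame.
#' @param noise_sd Standard deviation of additive Gaussian noise (16-bit
#'   intensity units); 0 disables noise.
#' @param pixel_size_um Micrometres per pixel.
#' @param seed Integer seed; all randomness in the render flows from it.
#' @return A validated `scene_params` list.
#' @seealso [render_scene()], [generate_sequence()]
#' @export
scene_params <- function(height_px = 480L, width_px = 320L,
                         background_level = 52000, jet_level = 12000,
                         nozzle_tip_rc = c(70L, 160L),
                         jet_width_px = 4L, jet_angle_deg = 0,
                         breakup_length_um = 300,
                         is_hit = FALSE, break_center_um = 100,
                         break_gap_px = 10L, splatter = FALSE,
                         illum_gradient = 0, noise_sd = 0,
                         pixel_size_um = 1, seed = 1L) {
  p <- list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    background_level = as.numeric(background_level),
    jet_level = as.numeric(jet_level),
    nozzle_tip_rc = as.integer(nozzle_tip_rc),
    jet_width_px = as.integer(jet_width_px),
    jet_angle_deg = as.numeric(jet_angle_deg),
    breakup_length_um = as.numeric(breakup_length_um),
    is_hit = isTRUE(is_hit),
    break_center_um = as.numeric(break_center_um),
    break_gap_px = as.integer(break_gap_px),
    splatter = isTRUE(splatter),
    illum_gradient = as.numeric(illum_gradient),
    noise_sd = as.numeric(noise_sd),
    pixel_size_um = as.numeric(pixel_size_um),
    seed = as.integer(seed)
  )
  if (p$height_px < 64L || p$width_px < 64L) {
    stop("scene must be at least 64 x 64 px", call. = FALSE)
  }
  if (p$jet_width_px < 1L || p$break_gap_px < 1L) {
    stop("`jet_width_px` and `break_gap_px` must be positive", call. = FALSE)
  }
  if (p$noise_sd < 0 || p$pixel_size_um <= 0 || p$breakup_length_um <= 0) {
    stop("`noise_sd` must be >= 0; `pixel_size_um` and `breakup_length_um` ",
         "must be > 0", call. = FALSE)
  }
  if (p$is_hit && p$break_center_um >= p$breakup_length_um) {
    stop("a hit requires `break_center_um` < `breakup_length_um` (the gap ",
         "must sit on the continuous part of the jet)", call. = FALSE)
  }
  structure(p, class = "scene_params")
}

# Geometry of the default nozzle silhouette within a scene, kept identical
# to default_nozzle_template() so a noiseless render matches it exactly.
scene_nozzle_geometry <- function() {
  list(height = 60L, width = 97L, halfwidth_top = 40L, halfwidth_tip = 5L)
}

#' Render one synthetic shadowgraph frame with its ground-truth label
#'
#' Deterministic given `p` (including `p$seed`). The nozzle silhouette is
#' pixel-identical to [default_nozzle_template()] pasted with its tip at
#' `p$nozzle_tip_rc`, so noiseless renders score exactly 1 under ZNCC
#' template matching.
#'
#' @param p A [scene_params()] object.
#' @return A list: `frame` (a [new_frame()]), `is_hit` (the label), and
#'   `jet_mask` (logical matrix of rendered jet-column pixels, for oracle
#'   comparisons).
#' @export
render_scene <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  withr::with_seed(p$seed, render_scene_impl(p))
}

render_scene_impl <- function(p) {
  H <- p$height_px; W <- p$width_px
  tip_r <- p$nozzle_tip_rc[1]; tip_c <- p$nozzle_tip_rc[2]
  img <- matrix(p$background_level, H, W)
  if (p$illum_gradient != 0) {
    ramp <- p$illum_gradient * (seq_len(W) - (W + 1) / 2)
    img <- img + matrix(ramp, H, W, byrow = TRUE)
  }

  # nozzle silhouette, identical raster to the default template
  g <- scene_nozzle_geometry()
  if (tip_r < g$height || tip_c <= g$width %/% 2L ||
      tip_c + g$width %/% 2L > W) {
    stop("nozzle tip too close to the frame border for the silhouette",
         call. = FALSE)
  }
  sil <- nozzle_silhouette(g$height, g$width, g$halfwidth_top, g$halfwidth_tip)
  rr <- (tip_r - g$height + 1L):tip_r
  cc <- (tip_c - g$width %/% 2L):(tip_c + g$width %/% 2L)
  block <- img[rr, cc]
  block[sil] <- p$jet_level
  img[rr, cc] <- block

  # jet column: from just below the tip to the bottom, tilted by
  # jet_angle_deg; continuous until breakup, droplet train beyond
  jet_mask <- matrix(FALSE, H, W)
  if (tip_r < H) {
    rows <- (tip_r + 1L):H
    dist_px <- rows - tip_r
    dist_um <- dist_px * p$pixel_size_um
    centres <- tip_c + tan(p$jet_angle_deg * pi / 180) * dist_px
    half_lo <- (p$jet_width_px - 1L) %/% 2L
    half_hi <- p$jet_width_px - 1L - half_lo
    solid <- dist_um <= p$breakup_length_um
    # droplet train: 4 rows of droplet then 5 rows of gap, repeating
    beyond <- which(!solid)
    droplet <- logical(length(rows))
    droplet[beyond] <- ((dist_px[beyond] -
                           ceiling(p$breakup_length_um / p$pixel_size_um)) %% 9L) < 4L
    draw <- solid | droplet
    if (p$is_hit) {
      gap_half <- (p$break_gap_px * p$pixel_size_um) / 2
      # half-open band so the gap spans exactly break_gap_px rows at 1 um/px
      in_gap <- dist_um >= p$break_center_um - gap_half &
        dist_um < p$break_center_um + gap_half
      draw <- draw & !in_gap
    }
    for (i in which(draw)) {
      c0 <- round(centres[i])
      cols <- max(1L, c0 - half_lo):min(W, c0 + half_hi)
      jet_mask[rows[i], cols] <- TRUE
    }
    img[jet_mask] <- p$jet_level
  }

  # splatter: dark speckle ejected laterally around the break (hits only)
  if (p$is_hit && p$splatter) {
    centre_r <- tip_r + round(p$break_center_um / p$pixel_size_um)
    n_speck <- 30L
    ang <- runif(n_speck, 0, 2 * pi)
    rad <- 6 + 12 * sqrt(runif(n_speck))
    sr <- round(centre_r + rad * sin(ang))
    sc <- round(tip_c + rad * cos(ang) * 1.6)
    keep <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
    img[cbind(sr[keep], sc[keep])] <- p$jet_level
  }

  if (p$noise_sd > 0) {
    img <- img + rnorm(H * W, 0, p$noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 65535))
  list(
    frame = new_frame(img, index = 0L, pixel_size_um = p$pixel_size_um),
    is_hit = p$is_hit,
    jet_mask = jet_mask
  )
}

#' Generate a labelled synthetic frame sequence
#'
#' Renders `n` frames sharing the geometry of `base`, with per-frame hit
#' labels and optional frame-to-frame jitter of jet angle and lateral nozzle
#' position. Labels come either from `hit_pattern` (used verbatim) or from
#' `hit_fraction`: exactly `round(hit_fraction * n)` hits are assigned by
#' deterministic stratified allocation and then shuffled with the seeded
#' RNG, so label counts are exact, not binomial.
#'
#' @param n Number of frames (>= 1).
#' @param base A [scene_params()] giving the shared scene geometry.
#' @param hit_pattern Logical vector of length `n`; overrides
#'   `hit_fraction`.
#' @param hit_fraction Fraction of hit frames in \[0, 1\].
#' @param jitter List with `angle_sd_deg` and `shift_sd_px`: per-frame
#'   Gaussian perturbations of jet angle and lateral tip position. Use
#'   `jitter = NULL` (default) for a perfectly steady jet.
#' @param seed Integer seed for labels, jitter and per-frame noise streams.
#' @return A list: `frames` (list of [new_frame()], indices `0:(n-1)`) and
#'   `labels` (tibble with `index`, `is_hit`).
#' @export
#' @examples
#' seq <- generate_sequence(6, scene_params(), hit_pattern = c(rep(FALSE, 5), TRUE))
#' seq$labels
generate_sequence <- function(n, base = scene_params(), hit_pattern = NULL,
                              hit_fraction = 0, jitter = NULL, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  stopifnot(inherits(base, "scene_params"))
  if (!is.null(hit_pattern)) {
    if (length(hit_pattern) != n) {
      stop("`hit_pattern` must have length n = ", n, call. = FALSE)
    }
    labels <- as.logical(hit_pattern)
  } else {
    if (hit_fraction < 0 || hit_fraction > 1) {
      stop("`hit_fraction` must lie in [0, 1]", call. = FALSE)
    }
    k <- round(hit_fraction * n)
    labels <- c(rep(TRUE, k), rep(FALSE, n - k))
    labels <- withr::with_seed(seed, sample(labels))
  }
  ang_sd <- if (is.null(jitter)) 0 else jitter$angle_sd_deg %||% 0
  shift_sd <- if (is.null(jitter)) 0 else jitter$shift_sd_px %||% 0
  perturb <- withr::with_seed(seed + 1L, list(
    angle = rnorm(n, 0, ang_sd),
    shift = round(rnorm(n, 0, shift_sd))
  ))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base
    p$is_hit <- labels[i]
    p$jet_angle_deg <- base$jet_angle_deg + perturb$angle[i]
    p$nozzle_tip_rc <- c(base$nozzle_tip_rc[1],
                         base$nozzle_tip_rc[2] + as.integer(perturb$shift[i]))
    p$seed <- base$seed + 1000L * i
    sc <- render_scene(p)
    f <- sc$frame
    f$index <- i - 1L
    frames[[i]] <- f
  }
  list(
    frames = frames,
    labels = tibble::tibble(index = 0:(n - 1L), is_hit = labels)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
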
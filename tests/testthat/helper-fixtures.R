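# Compact scene/config used by most tests: a 200 x 160 px field of view at
# 1 um/px, breakup at 90 um, interaction point 40 um from the nozzle. The
# matching config scales the break-distance rule to 80 um so natural droplet
# gaps stay beyond it, mirroring the full-scale 200/300 um geometry.
small_scene <- function(...) {
  defaults <- list(height_px = 200L, width_px = 160L,
                   nozzle_tip_rc = c(70L, 80L),
                   breakup_length_um = 90, break_center_um = 40)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

small_cfg <- function(...) {
  defaults <- list(pixel_size_um = 1, roi_length_px = 120L,
                   roi_halfwidth_px = 60L, max_break_distance_um = 80)
  do.call(jet_config, utils::modifyList(defaults, list(...)))
}

# Random 16-bit test image.
random_image <- function(h, w) {
  matrix(round(runif(h * w, 0, 65535)), h, w)
}
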
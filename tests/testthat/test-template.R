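paste_template <- function(frame_px, tpl_px, r, c) {
  frame_px[r:(r + nrow(tpl_px) - 1), c:(c + ncol(tpl_px) - 1)] <- tpl_px
  frame_px
}

test_that("noiseless paste is recovered exactly with score 1", {
  tpl <- default_nozzle_template(height = 20, width = 15,
                                 halfwidth_top = 6, halfwidth_tip = 1)
  img <- paste_template(matrix(30000, 60, 50), tpl$pixels, 6, 8)
  m <- match_template(img, tpl)
  expect_identical(unname(m$top_left), c(6L, 8L))
  expect_equal(m$score, 1, tolerance = 1e-9)
  expect_identical(unname(m$tip),
                   c(6L + tpl$tip_row - 1L, 8L + tpl$tip_col - 1L))
})

test_that("ZNCC is invariant to affine intensity rescaling", {
  withr::local_seed(11)
  tpl <- default_nozzle_template(height = 16, width = 13,
                                 halfwidth_top = 5, halfwidth_tip = 1)
  img <- paste_template(random_image(48, 40), tpl$pixels, 12, 9)
  m0 <- match_template(img, tpl)
  m1 <- match_template(pmin(0.4 * img + 1200, 65535), tpl)
  expect_identical(m0$top_left, m1$top_left)
})

test_that("argmax equals the brute-force oracle on small instances", {
  withr::local_seed(21)
  # the worked case: 20 x 20 frame, 8 x 8 template pasted at (3, 4),
  # argmax checked against every one of the 13 x 13 placements
  tpl_px <- matrix(round(runif(64, 0, 65535)), 8, 8)
  img <- paste_template(matrix(20000, 20, 20), tpl_px, 3, 4)
  tpl <- jet_template(tpl_px, 8, 4)
  m <- match_template(img, tpl)
  o <- oracle_zncc_argmax(img, tpl_px)
  expect_identical(unname(m$top_left), o$top_left)
  expect_identical(unname(m$top_left), c(3L, 4L))
  # randomized frames up to 64 x 64 (no paste; pure argmax agreement)
  for (i in 1:5) {
    img <- random_image(sample(30:64, 1), sample(30:64, 1))
    m <- match_template(img, tpl)
    o <- oracle_zncc_argmax(img, tpl_px)
    expect_identical(unname(m$top_left), o$top_left)
    expect_equal(m$score, o$score, tolerance = 1e-6)
  }
})

test_that("localization is translation-equivariant away from borders", {
  tpl <- default_nozzle_template(height = 20, width = 15,
                                 halfwidth_top = 6, halfwidth_tip = 1)
  base <- matrix(30000, 80, 70)
  m0 <- match_template(paste_template(base, tpl$pixels, 10, 20), tpl)
  m1 <- match_template(paste_template(base, tpl$pixels, 17, 25), tpl)
  expect_identical(unname(m1$tip - m0$tip), c(7L, 5L))
})

test_that("ties break at the smallest row, then column", {
  # constant frame: every placement has zero variance, every score is 0
  tpl <- jet_template(matrix(c(0, 1, 1, 0), 2, 2), 2, 1)
  m <- match_template(matrix(500, 32, 32), tpl)
  expect_identical(unname(m$top_left), c(1L, 1L))
  expect_equal(m$score, 0)  # zero-variance windows score 0
})

test_that("oversized templates are rejected", {
  tpl <- jet_template(matrix(runif(40 * 40), 40, 40), 40, 20)
  expect_error(match_template(matrix(0, 40, 60), tpl), "strictly smaller")
  expect_error(match_template(matrix(0, 60, 30), tpl), "strictly smaller")
})

test_that("ROI is anchored at the tip and clipped to the frame", {
  cfg <- jet_config(pixel_size_um = 1, roi_length_px = 300,
                    roi_halfwidth_px = 60)
  fake_match <- function(r, c) {
    structure(list(tip = c(row = r, col = c)), class = "jet_match")
  }
  roi <- derive_roi(fake_match(11, 51), cfg, c(512, 512))
  expect_identical(roi$top, 11L)
  expect_identical(roi$left, 1L)           # 51 - 60 clips to the left edge
  expect_identical(roi$width, 111L)        # columns 1..111 (tip + 60)
  expect_identical(roi$height, 300L)

  roi <- derive_roi(fake_match(1, 257), cfg, c(512, 512))
  expect_identical(roi$top, 1L)            # starts at the first row

  expect_error(derive_roi(fake_match(513, 600), cfg, c(512, 512)),
               "outside the frame")
})

test_that("cropping extracts the exact sub-image and composes", {
  withr::local_seed(5)
  f <- new_frame(random_image(120, 100), index = 2, pixel_size_um = 0.7)
  roi <- structure(list(top = 11L, left = 21L, height = 50L, width = 40L),
                   class = "jet_roi")
  crop <- crop_frame(f, roi)
  expect_identical(dim(crop$pixels), c(50L, 40L))
  expect_identical(crop$index, 2L)
  expect_equal(crop$pixel_size_um, 0.7)
  # pixel (r, c) of the crop equals pixel (top + r - 1, left + c - 1)
  expect_identical(crop$pixels[3, 7], f$pixels[13, 27])
  # crop of crop equals the crop of the composed box
  roi2 <- structure(list(top = 5L, left = 3L, height = 20L, width = 10L),
                    class = "jet_roi")
  roi12 <- structure(list(top = 15L, left = 23L, height = 20L, width = 10L),
                     class = "jet_roi")
  expect_identical(crop_frame(crop, roi2)$pixels, crop_frame(f, roi12)$pixels)
  bad <- structure(list(top = 100L, left = 90L, height = 50L, width = 40L),
                   class = "jet_roi")
  expect_error(crop_frame(f, bad), "not contained")
})
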
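test_that("jet profile applies the minimum-run rule", {
  expect_identical(jet_profile(matrix(1L, 5, 6)), rep(TRUE, 5))
  expect_identical(jet_profile(matrix(0L, 5, 6)), rep(FALSE, 5))
  m <- matrix(0L, 3, 8)
  m[1, 4] <- 1L          # isolated pixel: below min_run = 2
  m[2, 4:5] <- 1L        # run of 2: counts
  m[3, c(2, 4, 6)] <- 1L # alternating pixels: never contiguous
  expect_identical(jet_profile(m, min_run = 2), c(FALSE, TRUE, FALSE))
  expect_identical(jet_profile(m, min_run = 1), c(TRUE, TRUE, TRUE))
  expect_error(jet_profile(matrix(integer(0), 0, 0)), "non-empty")
})

test_that("break detection applies the gap and distance bounds", {
  cfg <- jet_config(pixel_size_um = 1)
  ev <- find_breaks(c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 30)), cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$gap_px, 10L)
  expect_equal(ev$distance_um, 30)

  # a 25 px gap exceeds the 20 px bound
  ev <- find_breaks(c(rep(TRUE, 30), rep(FALSE, 25), rep(TRUE, 30)), cfg)
  expect_identical(nrow(ev), 0L)

  # a gap starting 250 um from the nozzle exceeds the 200 um bound
  ev <- find_breaks(c(rep(TRUE, 250), rep(FALSE, 10), rep(TRUE, 40)), cfg)
  expect_identical(nrow(ev), 0L)

  # trailing unbounded gap (droplets then nothing) never qualifies
  ev <- find_breaks(c(rep(TRUE, 30), rep(FALSE, 10)), cfg)
  expect_identical(nrow(ev), 0L)

  # distance is measured at the upstream edge of the gap
  ev <- find_breaks(c(rep(TRUE, 195), rep(FALSE, 10), rep(TRUE, 30)), cfg)
  expect_equal(ev$distance_um, 195)

  # pixel scale converts rows to micrometres
  cfg2 <- jet_config(pixel_size_um = 2.5)
  ev <- find_breaks(c(rep(TRUE, 90), rep(FALSE, 5), rep(TRUE, 20)), cfg2)
  expect_identical(nrow(ev), 0L)  # 90 px * 2.5 um/px = 225 um > 200
})

test_that("break detection matches the brute-force enumerator on random profiles", {
  withr::local_seed(41)
  cfg <- jet_config(pixel_size_um = 1)
  for (i in 1:200) {
    n <- sample(5:500, 1)
    prof <- runif(n) < runif(1, 0.2, 0.9)
    got <- find_breaks(prof, cfg)
    want <- oracle_find_breaks(prof, cfg$max_gap_px,
                               cfg$max_break_distance_um, cfg$pixel_size_um)
    expect_identical(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_identical(got$gap_start_row, as.integer(want[, "start"]))
      expect_identical(got$gap_end_row, as.integer(want[, "end"]))
      expect_identical(got$gap_px, as.integer(want[, "gap"]))
      expect_equal(got$distance_um, unname(want[, "dist"]))
    }
  }
})

test_that("loosening the gap or distance bound never removes a hit", {
  withr::local_seed(42)
  base <- jet_config(pixel_size_um = 1)
  wider <- jet_config(pixel_size_um = 1, max_gap_px = 35,
                      max_break_distance_um = 320)
  for (i in 1:100) {
    prof <- runif(sample(20:300, 1)) < 0.7
    expect_true(nrow(find_breaks(prof, wider)) >=
                  nrow(find_breaks(prof, base)))
  }
})

test_that("frame classification composes the pipeline end to end", {
  cfg <- small_cfg()
  tpl <- default_nozzle_template()

  miss <- render_scene(small_scene(is_hit = FALSE))
  vm <- classify_frame(miss$frame, tpl, cfg)
  expect_false(vm$is_hit)
  expect_false(vm$no_jet)

  hit <- render_scene(small_scene(is_hit = TRUE, break_gap_px = 10L))
  vh <- classify_frame(hit$frame, tpl, cfg)
  expect_true(vh$is_hit)
  expect_identical(nrow(vh$events), 1L)
  expect_identical(vh$events$gap_px, 10L)
  # gap centred 40 um below the tip: upstream edge at 35 um
  expect_equal(vh$events$distance_um, 35)
})

test_that("droplet breakup beyond 200 um never triggers a hit", {
  cfg <- jet_config(pixel_size_um = 1)
  tpl <- default_nozzle_template()
  sc <- render_scene(scene_params(is_hit = FALSE, breakup_length_um = 260))
  v <- classify_frame(sc$frame, tpl, cfg)
  expect_false(v$is_hit)
  # sanity: the droplet gaps exist but start beyond the distance bound
  permissive <- jet_config(pixel_size_um = 1, max_break_distance_um = 1000)
  vp <- classify_frame(sc$frame, tpl, permissive)
  expect_true(vp$is_hit)
  expect_true(all(vp$events$distance_um > 200))
})

test_that("a frame with no jet at all is a flagged miss", {
  cfg <- small_cfg(min_run = 2)
  tpl <- default_nozzle_template(height = 20, width = 15,
                                 halfwidth_top = 6, halfwidth_tip = 1)
  # blank frame: template matching finds something, but no jet rows exist
  blank <- new_frame(matrix(30000, 200, 160), pixel_size_um = 1)
  v <- classify_frame(blank, tpl, cfg)
  expect_false(v$is_hit)
  expect_true(v$no_jet)
  expect_identical(v$n_jet_rows, 0L)
})
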
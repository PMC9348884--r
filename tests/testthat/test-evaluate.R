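test_that("confusion counts partition the compared instances", {
  cc <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unlist(cc), c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  cc <- confusion(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_identical(unlist(cc), c(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  cc <- confusion(logical(0), logical(0))
  expect_identical(sum(unlist(cc)), 0L)
  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "align")
  withr::local_seed(61)
  p <- runif(200) < 0.5; t <- runif(200) < 0.5
  expect_identical(sum(unlist(confusion(p, t))), 200L)
})

test_that("the Dice coefficient follows 2TP/(2TP + FP + FN)", {
  expect_equal(dice(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_equal(dice(list(tp = 0, fp = 3, fn = 2)), 0)
  expect_equal(dice(list(tp = 3, fp = 1, fn = 1)), 0.75)
  expect_warning(d <- dice(list(tp = 0, fp = 0, fn = 0)), "all-negative")
  expect_equal(d, 1)
})

test_that("Dice is invariant to the number of true negatives", {
  withr::local_seed(62)
  for (i in 1:20) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:20, 1),
               fn = sample(0:20, 1))
    if (2 * cc$tp + cc$fp + cc$fn == 0) cc$tp <- 1
    base <- dice(cc)
    cc$tn <- sample(0:10000, 1)
    expect_identical(dice(cc), base)
  }
})

test_that("self-comparison yields Dice 1", {
  withr::local_seed(63)
  x <- runif(50) < 0.4
  if (!any(x)) x[1] <- TRUE
  expect_equal(dice(confusion(x, x)), 1)
})

test_that("run summaries report the box-and-whisker statistics", {
  s <- summarize_runs(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  s <- summarize_runs(c(0, 1))
  expect_equal(s$mean, 0.5); expect_equal(s$median, 0.5)
  s <- summarize_runs(c(0.83, 0.98, 1.0))
  expect_equal(s$min, 0.83); expect_equal(s$max, 1.0)
  expect_equal(s$median, 0.98)
  # quartiles by linear interpolation between order statistics
  expect_equal(s$q1, stats::quantile(c(0.83, 0.98, 1.0), 0.25,
                                     names = FALSE))
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)
  expect_error(summarize_runs(numeric(0)), "non-empty")
  expect_error(summarize_runs(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evaluation lifts frame truth to instances and scores per run", {
  cfg <- jet_config(pixel_size_um = 1, sma_window = 3)
  truth <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  # a perfect instance-level classifier predicts the windowed OR of truth
  pred_inst <- oracle_windowed_or(truth, 3)
  ev <- evaluate_run(pred_inst, truth, cfg)
  expect_equal(ev$dice, 1)
  expect_identical(ev$counts$fp + ev$counts$fn, 0L)

  # two runs with one error each in the second
  run <- rep(1:2, each = 8)
  pred2 <- c(pred_inst, !pred_inst)
  ev2 <- evaluate_run(c(pred_inst, pred2[9:16]),
                      rep(truth, 2), cfg, run = run)
  expect_identical(nrow(ev2$by_run), 2L)
  expect_equal(ev2$by_run$dice[1], 1)
  expect_true(ev2$by_run$dice[2] < 1)
  expect_equal(ev2$summary$n_runs, 2)
})

test_that("tidy and glance expose evaluation results as tibbles", {
  cfg <- jet_config(pixel_size_um = 1, sma_window = 2)
  truth <- c(TRUE, FALSE, FALSE, TRUE)
  ev <- evaluate_run(c(TRUE, TRUE, FALSE, TRUE), truth, cfg)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("tp", "tn", "fp", "fn", "dice") %in% names(td)))
  gl <- glance(ev)
  expect_identical(gl$n_instances, 4L)
  expect_true(all(c("fp_pct", "fn_pct") %in% names(gl)))
})

test_that("misaligned evaluation inputs error", {
  cfg <- jet_config(pixel_size_um = 1)
  res <- tibble::tibble(index = 0:3, instance_hit = rep(FALSE, 4))
  truth <- tibble::tibble(index = 1:4, is_hit = rep(FALSE, 4))
  expect_error(evaluate_run(res, truth, cfg), "align")
})
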
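#' Confusion counts between predicted and true hit labels
#'
#' @param pred,truth Logical vectors of equal length (TRUE = hit).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`;
#'   `tp + tn + fp + fn` equals the number of compared instances.
#' @export
#' @examples
#' confusion(c(TRUE, FALSE), c(FALSE, TRUE))  # fp = 1, fn = 1
confusion <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` (", length(pred), ") and `truth` (", length(truth),
         ") must align", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(pred & truth),
    tn = sum(!pred & !truth),
    fp = sum(pred & !truth),
    fn = sum(!pred & truth)
  )
}

#' Dice coefficient from confusion counts
#'
#' `2TP / (2TP + FP + FN)`: 1 is complete agreement, 0 means no correctly
#' classified hit. True negatives do not enter the formula, so the score is
#' driven by performance on hits. In the degenerate all-negative case
#' (`2TP + FP + FN = 0`, i.e. neither prediction nor truth contains a hit)
#' the agreement is perfect and the value is defined as 1 with a warning.
#'
#' @param counts A [confusion()] row, or anything with elements `tp`, `fp`,
#'   `fn`.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' dice(list(tp = 3, fp = 1, fn = 1))  # 0.75
dice <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) {
    warning("no hits in prediction or truth; Dice of the all-negative case ",
            "defined as 1", call. = FALSE)
    return(1)
  }
  2 * counts$tp / denom
}

#' Summarize per-run Dice coefficients
#'
#' Computes the statistics conventionally shown in per-run box-and-whisker
#' summaries: mean, sample standard deviation (n - 1 denominator), median,
#' lower/upper quartile (linear interpolation between order statistics) and
#' range.
#'
#' @param run_dices Numeric vector of per-run Dice values in \[0, 1\].
#' @return A one-row tibble: `n_runs`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
summarize_runs <- function(run_dices) {
  if (length(run_dices) == 0L) {
    stop("`run_dices` must be non-empty", call. = FALSE)
  }
  if (anyNA(run_dices) || min(run_dices) < 0 || max(run_dices) > 1) {
    stop("Dice values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::quantile(run_dices, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n_runs = length(run_dices),
    mean = mean(run_dices),
    sd = if (length(run_dices) > 1) stats::sd(run_dices) else 0,
    median = stats::median(run_dices),
    q1 = q[1], q3 = q[2],
    min = min(run_dices), max = max(run_dices)
  )
}

#' Score pipeline output against ground truth
#'
#' Compares instance-level verdicts with instance-level truth. Frame-level
#' ground truth is lifted to instances with the same windowed-OR rule the
#' classifier uses (a window truly contains a hit iff any of its frames
#' does), so prediction and truth live on the same footing. With a `run`
#' grouping, confusion counts and Dice are computed per run and summarized.
#'
#' @param result A [process_sequence()] tibble (needs `index` and
#'   `instance_hit`), or a logical vector of instance predictions.
#' @param truth A tibble with `index` and `is_hit` frame-level ground truth
#'   (as produced by [generate_sequence()]), or a logical vector of
#'   frame-level truths aligned with `result`.
#' @param cfg The [jet_config()] used for the run (for `sma_window` and
#'   `window_mode`).
#' @param run Optional vector assigning each frame to a run; per-run Dice
#'   values are then reported separately.
#' @return A `jet_eval` object: list with `by_run` (per-run counts + Dice),
#'   `counts` (overall [confusion()]), `dice`, and `summary`
#'   ([summarize_runs()] across runs).
#' @export
evaluate_run <- function(result, truth, cfg, run = NULL) {
  pred <- if (is.data.frame(result)) result$instance_hit else as.logical(result)
  truth_frame <- if (is.data.frame(truth)) {
    if (is.data.frame(result) && !identical(result$index, truth$index)) {
      stop("`result` and `truth` do not align on frame index", call. = FALSE)
    }
    truth$is_hit
  } else {
    as.logical(truth)
  }
  if (length(pred) != length(truth_frame)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  if (is.null(run)) run <- rep(1L, length(pred))
  run <- as.vector(run)
  # lift frame truth to instance truth with the classifier's own window rule,
  # independently within each run (runs keep their order of appearance)
  df <- dplyr::bind_rows(lapply(unique(run), function(r) {
    ix <- which(run == r)
    tibble::tibble(
      run = r,
      pred = pred[ix],
      truth_inst = classify_stream(truth_frame[ix], cfg)$instance_hit
    )
  }))
  by_run <- df |>
    dplyr::group_by(.data$run) |>
    dplyr::group_modify(function(d, key) {
      cc <- confusion(d$pred, d$truth_inst)
      cc$dice <- withCallingHandlers(dice(cc),
                                     warning = function(w) invokeRestart("muffleWarning"))
      cc$n <- nrow(d)
      cc
    }) |>
    dplyr::ungroup()
  counts <- confusion(df$pred, df$truth_inst)
  overall <- withCallingHandlers(dice(counts),
                                 warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(by_run = by_run, counts = counts, dice = overall,
         summary = summarize_runs(by_run$dice)),
    class = "jet_eval"
  )
}

#' @export
print.jet_eval <- function(x, ...) {
  cat(sprintf("<jet_eval> %d run(s), %d instances\n",
              nrow(x$by_run), sum(x$by_run$n)))
  cat(sprintf("  overall Dice %.4f  (TP %d, TN %d, FP %d, FN %d)\n",
              x$dice, x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  s <- x$summary
  cat(sprintf("  per-run Dice: mean %.3f, sd %.3f, median %.3f, range [%.3f, %.3f]\n",
              s$mean, s$sd, s$median, s$min, s$max))
  invisible(x)
}

#' @export
tidy.jet_eval <- function(x, ...) {
  x$by_run
}

#' @export
glance.jet_eval <- function(x, ...) {
  n <- sum(x$by_run$n)
  tibble::tibble(
    n_instances = n,
    dice = x$dice,
    mean_run_dice = x$summary$mean,
    sd_run_dice = x$summary$sd,
    fp_pct = 100 * x$counts$fp / n,
    fn_pct = 100 * x$counts$fn / n
  )
}
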
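raster_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a frame, optionally with its binary mask and ROI overlaid
#'
#' @param frame A [new_frame()] object (or matrix).
#' @param mask Optional [new_mask()]; jet pixels are tinted.
#' @param roi Optional [derive_roi()] box drawn over the frame. When `mask`
#'   is given it is assumed to be aligned with `roi` (a mask of the crop).
#' @return A ggplot object.
#' @export
plot_frame <- function(frame, mask = NULL, roi = NULL) {
  px <- as_pixels(frame)
  df <- raster_df(px)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 65535), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "jet_mask")) mask$values else mask
    md <- raster_df(mv)
    md <- md[md$value == 1L, ]
    if (!is.null(roi)) {
      md$row <- md$row + roi$top - 1L
      md$col <- md$col + roi$left - 1L
    }
    p <- p + ggplot2::geom_tile(data = md, fill = "red", alpha = 0.5)
  }
  if (!is.null(roi)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = roi$left - 0.5, xmax = roi$left + roi$width - 0.5,
      ymin = roi$top - 0.5, ymax = roi$top + roi$height - 0.5,
      colour = "dodgerblue", fill = NA, linewidth = 0.6
    )
  }
  p
}

#' @export
autoplot.jet_mask <- function(object, ...) {
  df <- raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "white"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Per-frame and instance verdicts along a sequence
#'
#' @param object A [process_sequence()] result.
#' @param ... Unused.
#' @return A ggplot object: frame verdicts as points, instance verdicts as a
#'   step line.
#' @export
autoplot.jet_run <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_step(ggplot2::aes(y = as.integer(.data$instance_hit)),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = as.integer(.data$is_hit)),
                        alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("miss", "hit")) +
    ggplot2::labs(x = "frame index", y = NULL,
                  title = "Per-frame (points) and instance (line) verdicts") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker summary of per-run Dice coefficients
#'
#' @param object A [evaluate_run()] result, or a data frame with columns
#'   `dice` and optionally `group`.
#' @param group Optional grouping (e.g. nozzle type) aligned with the runs.
#' @param ... Unused.
#' @return A ggplot object in the conventional box-and-whisker style: box at
#'   the quartiles, line at the median, cross at the mean, whiskers at the
#'   extremes.
#' @export
autoplot.jet_eval <- function(object, group = NULL, ...) {
  df <- object$by_run
  df$group <- if (is.null(group)) "all runs" else as.character(group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$dice)) +
    ggplot2::geom_boxplot(coef = Inf, width = 0.4, fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Dice coefficient") +
    ggplot2::theme_minimal()
}
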
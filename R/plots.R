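#' Plot a spectrogram
#'
#' Raster view (time on x in seconds, frequency on y in kHz), thinned in
#' time when the track exceeds `max_frames` columns so the plot stays
#' responsive on 3-minute tracks.
#'
#' @param object A `usv_spectrogram`.
#' @param max_frames Maximum time columns rendered.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_spectrogram <- function(object, max_frames = 2000L, ...) {
  N <- ncol(object$values)
  keep <- if (N > max_frames) {
    unique(as.integer(round(seq(1L, N, length.out = max_frames))))
  } else seq_len(N)
  df <- tidyr::expand_grid(freq_khz = object$freq_hz / 1000,
                           frame = keep) |>
    dplyr::arrange(.data$frame, .data$freq_khz)
  df$db <- as.vector(object$values[, keep])
  df$time_s <- (df$frame - 1L) * object$frame_hop_s
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_khz,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)",
                  title = object$track_id) +
    ggplot2::theme_minimal()
}

#' Plot precision/recall/accuracy curves over the confidence threshold
#'
#' Solid lines show raw predictions, dashed lines post-processed ones,
#' mirroring the usual presentation of these sweeps.
#'
#' @param object A `usv_pr_curve` (from [pr_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usv_pr_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t_c", "postprocessed", "precision",
                                  "recall", "accuracy")],
    c("precision", "recall", "accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_c, .data$value,
                                   colour = .data$metric,
                                   linetype = .data$postprocessed)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   name = "post-processed") +
    ggplot2::labs(x = expression(t[c]), y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of true-positive IoU values of a report
#'
#' @param report A `usv_eval_report`.
#' @param breaks Bin edges over `[0, 1]`.
#' @return A ggplot object.
#' @export
plot_iou_histogram <- function(report, breaks = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(report, "usv_eval_report"))
  df <- tibble::tibble(iou = report$tp_ious)
  ggplot2::ggplot(df, ggplot2::aes(.data$iou)) +
    ggplot2::geom_histogram(breaks = breaks, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "IoU of detected calls", y = "count") +
    ggplot2::theme_minimal()
}

#' Boxplot of relative length errors
#'
#' Compares `(l_GT - l_pr) / l_GT` distributions across named reports
#' (e.g. different segmenters).
#'
#' @param reports A named list of `usv_eval_report` objects.
#' @return A ggplot object.
#' @export
plot_length_errors <- function(reports) {
  df <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(r$length_errors, method = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$rel_error)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "relative length error") +
    ggplot2::theme_minimal()
}
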
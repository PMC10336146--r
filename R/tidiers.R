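#' Tidy a trained segmenter's training history
#'
#' @param x A `usv_segmenter`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss` (empty for an
#'   untrained model).
#' @export
tidy.usv_segmenter <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric()))
  }
  x$history
}

#' One-row summary of a segmenter
#'
#' @param x A `usv_segmenter`.
#' @param ... Unused.
#' @return A one-row tibble with `architecture`, `preset`, `M`, `n`,
#'   `parameters`, `trained`, `epochs`, `best_val_loss`.
#' @export
glance.usv_segmenter <- function(x, ...) {
  tibble::tibble(
    architecture = x$arch$name, preset = x$arch$preset,
    M = x$arch$M, n = x$arch$n,
    parameters = parameter_count(x),
    trained = isTRUE(x$state$trained),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_loss = if (is.null(x$state$best_val_loss)) NA_real_
                    else x$state$best_val_loss)
}

#' Tidy an evaluation report into a long metric table
#'
#' @param x A `usv_eval_report`.
#' @param ... Unused.
#' @return A tibble with `family` (`"frame"`/`"detection"`), `metric`,
#'   and `value`.
#' @export
tidy.usv_eval_report <- function(x, ...) {
  fm <- x$frame_metrics
  dplyr::bind_rows(
    tidyr::pivot_longer(fm, dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
      dplyr::mutate(family = "frame", .before = 1),
    tibble::tibble(family = "detection",
                   metric = c("precision", "recall"),
                   value = c(x$detection$precision, x$detection$recall)))
}

#' One-row summary of an evaluation report
#'
#' @param x A `usv_eval_report`.
#' @param ... Unused.
#' @return A one-row tibble of pooled counts and metrics.
#' @export
glance.usv_eval_report <- function(x, ...) {
  dplyr::bind_cols(
    x$frame_counts,
    x$frame_metrics,
    tibble::tibble(det_tp = x$detection$counts$tp,
                   det_fp = x$detection$counts$fp,
                   det_fn = x$detection$counts$fn,
                   det_precision = x$detection$precision,
                   det_recall = x$detection$recall,
                   t_iou = x$t_iou, n_tracks = x$n_tracks))
}

#' Tidy a detection result into its matched pairs
#'
#' @param x A `usv_detection`.
#' @param ... Unused.
#' @return The `tp_pairs` tibble.
#' @export
tidy.usv_detection <- function(x, ...) x$tp_pairs

#' One-row summary of a detection result
#'
#' @param x A `usv_detection`.
#' @param ... Unused.
#' @return A one-row tibble with counts, precision, recall, `t_iou`.
#' @export
glance.usv_detection <- function(x, ...) {
  tibble::tibble(tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn,
                 precision = x$precision, recall = x$recall,
                 t_iou = x$t_iou)
}
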
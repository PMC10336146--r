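#' Frame-wise confusion counts
#'
#' Compares two equal-length binary label vectors frame by frame: a
#' predicted 1 on a true 1 is a TP, a predicted 0 on a true 1 an FN, a
#' predicted 1 on a true 0 an FP, and a predicted 0 on a true 0 a TN.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) {
    abort_squeakseg("`y_true` and `y_pred` must have the same length.",
                    "squeakseg_length_mismatch")
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Frame-wise classification metrics
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/(TP+TN+FP+FN), FPR = FP/(FP+TN). A zero denominator
#' yields `NA` (undefined), never a 0-or-1 convention.
#'
#' @param counts A one-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `precision`, `recall`, `accuracy`, `fpr`.
#' @export
frame_metrics <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, tibble::tibble(
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    fpr = safe_div(fp, fp + tn)))
}

#' Intersection-over-union of two half-open intervals
#'
#' Computed on frame counts: `|a intersect b| / |a union b]`. Vectorized
#' over interval pairs.
#'
#' @param a_start,a_end,b_start,b_end Interval endpoints, half-open
#'   `[start, end)`. `a` may also be given as a length-2 vector in
#'   `a_start` with `b` in `a_end`.
#' @return IoU value(s) in `[0, 1]`.
#' @export
interval_iou <- function(a_start, a_end, b_start = NULL, b_end = NULL) {
  if (is.null(b_start)) {  # interval_iou(c(s,e), c(s,e))
    b <- a_end
    a <- a_start
    a_start <- a[1]; a_end <- a[2]; b_start <- b[1]; b_end <- b[2]
  }
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  union <- (a_end - a_start) + (b_end - b_start) - inter
  ifelse(union > 0, inter / union, 0)
}

check_interval_table <- function(x, arg) {
  if (!all(c("start_frame", "end_frame") %in% names(x))) {
    abort_squeakseg(sprintf("`%s` needs `start_frame` and `end_frame` columns.", arg),
                    "squeakseg_bad_input")
  }
  if (nrow(x) == 0) return(x)
  if (any(x$end_frame <= x$start_frame)) {
    abort_squeakseg(sprintf("`%s` contains empty intervals.", arg),
                    "squeakseg_bad_input")
  }
  o <- order(x$start_frame)
  x <- x[o, , drop = FALSE]
  if (any(x$start_frame[-1] < x$end_frame[-nrow(x)])) {
    abort_squeakseg(sprintf("Intervals in `%s` overlap.", arg),
                    "squeakseg_overlapping_intervals")
  }
  x
}

#' IoU-based detection matching
#'
#' Each predicted interval is paired with the ground-truth interval of
#' maximum IoU and counts as a TP iff that IoU is strictly greater than
#' `t_iou`, otherwise as an FP. Independently, each ground-truth interval
#' counts as an FN iff no single prediction achieves IoU > `t_iou` with
#' it. The rule is deliberately not one-to-one: two predictions above
#' threshold on the same call are two TPs; a greedy one-to-one mode is
#' available for sensitivity analysis.
#'
#' @param preds,gts Interval tibbles (`start_frame`, `end_frame`), each
#'   internally non-overlapping.
#' @param t_iou IoU threshold (strict inequality).
#' @param one_to_one If `TRUE`, greedily assign pairs by decreasing IoU so
#'   each prediction and each GT is used at most once.
#' @return An object of class `usv_detection`: `tp_pairs` (tibble with
#'   `pred_idx`, `gt_idx`, `iou`, `pred_len`, `gt_len`), `fp`, `fn`
#'   (tibbles of unmatched intervals), `counts`, `precision`, `recall`
#'   (detection-level, `NA` when undefined), and `t_iou`.
#' @export
match_detections <- function(preds, gts, t_iou = 0.6, one_to_one = FALSE) {
  preds <- check_interval_table(preds, "preds")
  gts <- check_interval_table(gts, "gts")
  np <- nrow(preds); ng <- nrow(gts)
  if (np > 0 && ng > 0) {
    inter <- pmax(0, outer(preds$end_frame, gts$end_frame, pmin) -
                     outer(preds$start_frame, gts$start_frame, pmax))
    union <- outer(preds$end_frame - preds$start_frame,
                   gts$end_frame - gts$start_frame, `+`) - inter
    iou <- ifelse(union > 0, inter / union, 0)
  } else {
    iou <- matrix(0, nrow = np, ncol = ng)
  }
  if (!one_to_one) {
    if (np > 0 && ng > 0) {
      best_gt <- max.col(iou, ties.method = "first")
      best_iou <- iou[cbind(seq_len(np), best_gt)]
    } else {
      best_gt <- integer(np)
      best_iou <- numeric(np)
    }
    is_tp <- best_iou > t_iou
    gt_found <- if (np > 0 && ng > 0) apply(iou, 2, max) > t_iou else rep(FALSE, ng)
  } else {
    is_tp <- rep(FALSE, np)
    best_gt <- integer(np)
    gt_found <- rep(FALSE, ng)
    if (np > 0 && ng > 0) {
      cand <- which(iou > t_iou, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(iou[cand], decreasing = TRUE), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          p <- cand[r, 1]; g <- cand[r, 2]
          if (!is_tp[p] && !gt_found[g]) {
            is_tp[p] <- TRUE; best_gt[p] <- g; gt_found[g] <- TRUE
          }
        }
      }
    }
  }
  tp_idx <- which(is_tp)
  tp_pairs <- tibble::tibble(
    pred_idx = tp_idx,
    gt_idx = best_gt[tp_idx],
    iou = if (length(tp_idx)) iou[cbind(tp_idx, best_gt[tp_idx])] else numeric(0),
    pred_len = preds$end_frame[tp_idx] - preds$start_frame[tp_idx],
    gt_len = gts$end_frame[best_gt[tp_idx]] - gts$start_frame[best_gt[tp_idx]])
  counts <- list(tp = length(tp_idx), fp = np - length(tp_idx),
                 fn = sum(!gt_found))
  structure(list(
    tp_pairs = tp_pairs,
    fp = preds[!is_tp, , drop = FALSE],
    fn = gts[!gt_found, , drop = FALSE],
    counts = counts,
    precision = if (np > 0) counts$tp / np else NA_real_,
    recall = if (counts$tp + counts$fn > 0)
      counts$tp / (counts$tp + counts$fn) else NA_real_,
    t_iou = t_iou),
    class = "usv_detection")
}

#' @export
print.usv_detection <- function(x, ...) {
  cat(sprintf("<usv_detection> t_IoU %.2f: TP %d, FP %d, FN %d (precision %s, recall %s)\n",
              x$t_iou, x$counts$tp, x$counts$fp, x$counts$fn,
              format(x$precision, digits = 3), format(x$recall, digits = 3)))
  invisible(x)
}

#' Histogram of true-positive IoU values
#'
#' @param result A `usv_detection`.
#' @param breaks Bin edges partitioning `[0, 1]`.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   TP count (the top bin is closed so IoU = 1 is included).
#' @export
iou_histogram <- function(result, breaks = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(result, "usv_detection"))
  if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - 1) > 1e-12) {
    abort_squeakseg("`breaks` must span [0, 1].", "squeakseg_bad_input")
  }
  bin <- findInterval(result$tp_pairs$iou, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = tabulate(bin, nbins = nb))
}

#' Relative length errors of detected calls
#'
#' For every true positive, `(l_GT - l_pr) / l_GT` on frame lengths:
#' positive when the prediction is shorter than the true call, negative
#' when it over-segments.
#'
#' @param result A `usv_detection`.
#' @return A tibble with columns `gt_len`, `pred_len`, `rel_error`.
#' @export
length_errors <- function(result) {
  stopifnot(inherits(result, "usv_detection"))
  tp <- result$tp_pairs
  tibble::tibble(gt_len = tp$gt_len, pred_len = tp$pred_len,
                 rel_error = (tp$gt_len - tp$pred_len) / tp$gt_len)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration (via the exact rank-sum distribution) when both
#' samples have at most 10 observations and there are no ties; otherwise
#' the normal approximation with tie correction.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return The two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort_squeakseg("Both samples must be non-empty.", "squeakseg_bad_input")
  }
  no_ties <- !any(duplicated(c(x, y)))
  if (min(length(x), length(y)) <= 10 && no_ties) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"`
#' otherwise.
#'
#' @param p A p-value.
#' @return A character label.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Evaluate predictions against ground truth over a set of tracks
#'
#' Frame-wise confusion counts are pooled over all tracks (evaluation
#' operates on track-level merged vectors, not on chunks); intervals are
#' extracted from each track's label vector and matched at `t_iou`.
#'
#' @param pred_labels,gt_labels Lists of binary vectors, one per track,
#'   matching lengths track by track.
#' @param t_iou IoU threshold for detection matching.
#' @param frame_hop_s Seconds per frame (stored for reporting).
#' @param one_to_one Passed to [match_detections()].
#' @return An object of class `usv_eval_report` with `frame_counts`,
#'   `frame_metrics`, `detection` (pooled counts and metrics),
#'   `tp_ious`, `length_errors`, `t_iou`, `frame_hop_s`, `n_tracks`.
#' @export
evaluate_tracks <- function(pred_labels, gt_labels, t_iou = 0.6,
                            frame_hop_s = NA_real_, one_to_one = FALSE) {
  if (length(pred_labels) != length(gt_labels) || length(pred_labels) == 0) {
    abort_squeakseg("Prediction and ground-truth lists must be non-empty and equal length.",
                    "squeakseg_bad_input")
  }
  cc <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  det <- list(tp = 0L, fp = 0L, fn = 0L)
  tp_ious <- numeric(0)
  len_err <- list()
  for (i in seq_along(pred_labels)) {
    ci <- confusion(gt_labels[[i]], pred_labels[[i]])
    cc <- list(tp = cc$tp + ci$tp, fp = cc$fp + ci$fp,
               tn = cc$tn + ci$tn, fn = cc$fn + ci$fn)
    m <- match_detections(labels_to_segments(pred_labels[[i]]),
                          labels_to_segments(gt_labels[[i]]),
                          t_iou, one_to_one = one_to_one)
    det <- list(tp = det$tp + m$counts$tp, fp = det$fp + m$counts$fp,
                fn = det$fn + m$counts$fn)
    tp_ious <- c(tp_ious, m$tp_pairs$iou)
    len_err[[i]] <- length_errors(m)
  }
  fc <- tibble::as_tibble(cc)
  structure(list(
    frame_counts = fc,
    frame_metrics = frame_metrics(fc),
    detection = list(
      counts = det,
      precision = if (det$tp + det$fp > 0) det$tp / (det$tp + det$fp) else NA_real_,
      recall = if (det$tp + det$fn > 0) det$tp / (det$tp + det$fn) else NA_real_),
    tp_ious = tp_ious,
    length_errors = dplyr::bind_rows(len_err),
    t_iou = t_iou, frame_hop_s = frame_hop_s,
    n_tracks = length(pred_labels)),
    class = "usv_eval_report")
}

#' @export
print.usv_eval_report <- function(x, ...) {
  fm <- x$frame_metrics
  cat(sprintf("<usv_eval_report> %d track(s), t_IoU %.2f\n", x$n_tracks, x$t_iou))
  cat(sprintf("  frames:    precision %.4f  recall %.4f  accuracy %.4f  FPR %.4f\n",
              fm$precision, fm$recall, fm$accuracy, fm$fpr))
  cat(sprintf("  detection: precision %s  recall %s  (TP %d, FP %d, FN %d)\n",
              format(x$detection$precision, digits = 4),
              format(x$detection$recall, digits = 4),
              x$detection$counts$tp, x$detection$counts$fp,
              x$detection$counts$fn))
  invisible(x)
}

#' Precision-recall and accuracy curves over the confidence threshold
#'
#' Sweeps `t_c` over merged per-frame confidence tracks. At each
#' threshold, both metric families (frame-wise and detection) are
#' computed with and without morphological post-processing, mirroring the
#' solid/dashed curve pairs used to compare the segmenters.
#'
#' @param conf_tracks List of merged confidence vectors (one per track,
#'   values in `[0, 1]`).
#' @param gt_labels List of matching ground-truth binary vectors.
#' @param t_c_grid Thresholds to sweep.
#' @param K Post-processing kernel length.
#' @param t_iou IoU threshold for detection metrics.
#' @return A tibble of class `usv_pr_curve`: one row per
#'   (`t_c`, `postprocessed`) combination with frame and detection
#'   metrics.
#' @export
pr_curve <- function(conf_tracks, gt_labels, t_c_grid = seq(0.1, 0.9, by = 0.1),
                     K = 135L, t_iou = 0.6) {
  if (length(t_c_grid) == 0) {
    abort_squeakseg("`t_c_grid` must be non-empty.", "squeakseg_bad_input")
  }
  rows <- list()
  for (t_c in t_c_grid) {
    raw <- lapply(conf_tracks, function(conf) as.integer(conf > t_c))
    post <- lapply(raw, postprocess_labels, K = K)
    for (variant in c(FALSE, TRUE)) {
      preds <- if (variant) post else raw
      rep <- evaluate_tracks(preds, gt_labels, t_iou = t_iou)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(t_c = t_c, postprocessed = variant),
        rep$frame_metrics,
        tibble::tibble(det_precision = rep$detection$precision,
                       det_recall = rep$detection$recall))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("usv_pr_curve", class(out))
  out
}
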
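#' One-dimensional binary dilation and erosion
#'
#' Flat structuring element of length `K` with origin `floor(K/2)`:
#' the window for output position `k` (0-based) covers input positions
#' `k - floor(K/2), ..., k - floor(K/2) + K - 1`. Positions outside the
#' vector are treated as 0 for both operators, so erosion shrinks runs
#' that touch the track boundary.
#'
#' Both are O(N) via cumulative sums.
#'
#' @param y Binary 0/1 vector.
#' @param K Structuring element length in frames (>= 1).
#' @return Binary integer vector of the same length.
#' @export
dilate_labels <- function(y, K) {
  y <- check_labels(y)
  K <- as.integer(K)
  if (K < 1L) abort_squeakseg("Kernel length `K` must be >= 1.",
                              "squeakseg_bad_kernel")
  N <- length(y)
  if (N == 0L) return(integer(0))
  o <- K %/% 2L
  cs <- c(0L, cumsum(y))
  i <- seq_len(N)
  a <- pmax(i - o, 1L)
  b <- pmin(i - o + K - 1L, N)
  s <- ifelse(a > b, 0L, cs[b + 1L] - cs[a])
  as.integer(s > 0L)
}

#' @rdname dilate_labels
#' @export
erode_labels <- function(y, K) {
  y <- check_labels(y)
  K <- as.integer(K)
  if (K < 1L) abort_squeakseg("Kernel length `K` must be >= 1.",
                              "squeakseg_bad_kernel")
  N <- length(y)
  if (N == 0L) return(integer(0))
  o <- K %/% 2L
  cs <- c(0L, cumsum(y))
  i <- seq_len(N)
  a <- i - o
  b <- i - o + K - 1L
  inside <- a >= 1L & b <= N
  s <- integer(N)
  s[inside] <- cs[b[inside] + 1L] - cs[a[inside]]
  as.integer(inside & s == K)
}

#' Morphological post-processing of a prediction vector
#'
#' Closing (dilation then erosion) followed by opening (erosion then
#' dilation) with the same flat kernel: interior gaps shorter than `K`
#' are filled, then runs shorter than `K` are removed. The reverse order
#' is available for ablation.
#'
#' @param y Binary 0/1 prediction vector.
#' @param K Kernel length in frames.
#' @param order `"close-open"` (default) or `"open-close"`.
#' @return Post-processed binary vector.
#' @export
postprocess_labels <- function(y, K, order = c("close-open", "open-close")) {
  order <- match.arg(order)
  closing <- function(v) erode_labels(dilate_labels(v, K), K)
  opening <- function(v) dilate_labels(erode_labels(v, K), K)
  if (order == "close-open") opening(closing(y)) else closing(opening(y))
}

#' Convert a label vector to call intervals (and back)
#'
#' A call starts at a 0-to-1 transition and ends at the following 1-to-0
#' transition; intervals are half-open `[start_frame, end_frame)` on
#' 0-based frame indices.
#'
#' @param z Binary 0/1 label vector.
#' @param frame_hop_s Seconds per frame, used to fill `start_s`/`end_s`;
#'   omit for frame-only intervals.
#' @param track_id Identifier copied into the result.
#' @return A tibble with columns `track_id`, `start_frame`, `end_frame`,
#'   `length`, and (when `frame_hop_s` is given) `start_s`, `end_s`.
#' @export
labels_to_segments <- function(z, frame_hop_s = NULL, track_id = "track") {
  z <- check_labels(z)
  starts <- which(diff(c(0L, z)) == 1L)
  ends <- which(diff(c(z, 0L)) == -1L)
  out <- tibble::tibble(track_id = track_id,
                        start_frame = starts - 1L,
                        end_frame = ends,
                        length = ends - starts + 1L)
  if (!is.null(frame_hop_s)) {
    out$start_s <- out$start_frame * frame_hop_s
    out$end_s <- out$end_frame * frame_hop_s
  }
  out
}

#' @rdname labels_to_segments
#' @param segments A tibble with `start_frame`/`end_frame` columns.
#' @param N Track length in frames.
#' @export
segments_to_labels <- function(segments, N) {
  intervals_to_labels(segments, N)
}

#' Tune the post-processing kernel length on training tracks
#'
#' For each candidate kernel the raw predictions are post-processed,
#' converted to intervals, and matched against the ground truth at
#' `t_iou`; detection precision and recall are pooled over tracks. The
#' selected kernel minimizes `|precision - recall|` (the crossing point
#' of the two curves), with ties broken toward the smaller kernel.
#' Candidates whose precision or recall is undefined are skipped.
#'
#' @param preds List of raw binary prediction vectors, one per track.
#' @param gts List of ground-truth binary vectors (same lengths).
#' @param candidate_ks Integer vector of kernel lengths.
#' @param t_iou IoU threshold for detection matching.
#' @return A list with `K` (selected length) and `metrics` (tibble of
#'   `K`, `precision`, `recall`, `gap`).
#' @export
select_kernel <- function(preds, gts, candidate_ks, t_iou = 0.6) {
  if (length(candidate_ks) == 0) {
    abort_squeakseg("`candidate_ks` must be non-empty.", "squeakseg_bad_kernel")
  }
  if (length(preds) != length(gts) || length(preds) == 0) {
    abort_squeakseg("`preds` and `gts` must be non-empty lists of equal length.",
                    "squeakseg_bad_input")
  }
  candidate_ks <- sort(as.integer(candidate_ks))
  gt_segs <- lapply(gts, labels_to_segments)
  rows <- lapply(candidate_ks, function(K) {
    tp <- fp <- fn <- 0L
    for (i in seq_along(preds)) {
      z <- postprocess_labels(preds[[i]], K)
      m <- match_detections(labels_to_segments(z), gt_segs[[i]], t_iou)
      tp <- tp + m$counts$tp; fp <- fp + m$counts$fp; fn <- fn + m$counts$fn
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tibble::tibble(K = K, precision = p, recall = r,
                   gap = abs(p - r))
  })
  metrics <- dplyr::bind_rows(rows)
  list(K = kernel_crossing(metrics), metrics = metrics)
}

# Selection rule: the kernel where the precision and recall curves cross,
# i.e. argmin |precision - recall|; ties go to the smaller kernel
# (metrics must be sorted by ascending K).
kernel_crossing <- function(metrics) {
  gap <- abs(metrics$precision - metrics$recall)
  gap[is.na(gap)] <- Inf
  if (all(is.infinite(gap))) {
    abort_squeakseg("Precision/recall undefined for every candidate kernel.",
                    "squeakseg_bad_kernel")
  }
  metrics$K[which.min(gap)]
}
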
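# Independent oracles used across the suite. These deliberately avoid the
# package's cumulative-sum / vectorized implementations: morphology is a
# literal sliding window, detection matching a literal all-pairs loop, and
# the rank-sum p-value a full enumeration over rank assignments.

# Materialize every length-K window (zero padding outside the vector) and
# reduce it directly.
oracle_windows <- function(y, K) {
  o <- K %/% 2L
  padded <- c(integer(o), as.integer(y), integer(K - 1L - o))
  stats::embed(padded, K)  # row i = window of output position i
}

oracle_dilate <- function(y, K) as.integer(rowSums(oracle_windows(y, K)) > 0L)
oracle_erode <- function(y, K) as.integer(rowSums(oracle_windows(y, K)) == K)
oracle_closing <- function(y, K) oracle_erode(oracle_dilate(y, K), K)
oracle_opening <- function(y, K) oracle_dilate(oracle_erode(y, K), K)
oracle_postprocess <- function(y, K) oracle_opening(oracle_closing(y, K), K)

# Exhaustive all-pairs detection matcher (strict IoU inequality).
oracle_match <- function(preds, gts, t_iou) {
  iou1 <- function(a0, a1, b0, b1) {
    inter <- max(0, min(a1, b1) - max(a0, b0))
    uni <- (a1 - a0) + (b1 - b0) - inter
    if (uni > 0) inter / uni else 0
  }
  tp <- 0L
  for (i in seq_len(nrow(preds))) {
    best <- 0
    for (j in seq_len(nrow(gts))) {
      best <- max(best, iou1(preds$start_frame[i], preds$end_frame[i],
                             gts$start_frame[j], gts$end_frame[j]))
    }
    if (best > t_iou) tp <- tp + 1L
  }
  fn <- 0L
  for (j in seq_len(nrow(gts))) {
    found <- FALSE
    for (i in seq_len(nrow(preds))) {
      if (iou1(preds$start_frame[i], preds$end_frame[i],
               gts$start_frame[j], gts$end_frame[j]) > t_iou) found <- TRUE
    }
    if (!found) fn <- fn + 1L
  }
  list(tp = tp, fp = nrow(preds) - tp, fn = fn)
}

# Random sorted, non-overlapping interval table.
random_intervals <- function(n, span = 1000L) {
  if (n == 0L) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer()))
  }
  edges <- sort(sample(span, 2L * n))
  tibble::tibble(start_frame = edges[seq(1L, 2L * n, 2L)],
                 end_frame = edges[seq(2L, 2L * n, 2L)])
}

# Two-sided rank-sum p-value by enumeration over all rank subsets.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  subsets <- utils::combn(n + m, n)
  ws <- apply(subsets, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# Cheap random binary vector with call-like runs.
random_label_vector <- function(N, p_switch = 0.1) {
  state <- sample(0:1, 1)
  y <- integer(N)
  for (i in seq_len(N)) {
    if (stats::runif(1) < p_switch) state <- 1L - state
    y[i] <- state
  }
  y
}
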
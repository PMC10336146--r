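test_that("frame-wise confusion counts follow the TP/FP/TN/FN mapping", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(as.integer(cc[1, ]), c(1L, 1L, 1L, 1L))
  same <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(same$fp + same$fn, 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)),
               class = "squeakseg_length_mismatch")
  set.seed(1)
  for (i in 1:1000) {
    N <- sample(10:80, 1)
    a <- rbinom(N, 1, 0.4); b <- rbinom(N, 1, 0.4)
    cc <- confusion(a, b)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, N)
  }
})

test_that("frame metrics apply the defining formulas, with NA for 0/0", {
  expect_equal(frame_metrics(list(tp = 9, fp = 1, tn = 0, fn = 0))$precision,
               0.9)
  und <- frame_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$recall))
  expect_equal(und$fpr, 0)
  set.seed(2)
  for (i in 1:1000) {
    k <- as.list(rpois(4, 20)); names(k) <- c("tp", "fp", "tn", "fn")
    m <- frame_metrics(k)
    tot <- k$tp + k$fp + k$tn + k$fn
    if (tot > 0) expect_equal(m$accuracy, (k$tp + k$tn) / tot)
    if (k$tp + k$fp > 0) expect_equal(m$precision, k$tp / (k$tp + k$fp))
    if (k$tp + k$fn > 0) expect_equal(m$recall, k$tp / (k$tp + k$fn))
    if (k$fp + k$tn > 0) expect_equal(m$fpr, k$fp / (k$fp + k$tn))
  }
})

test_that("interval IoU is symmetric and exact on worked cases", {
  expect_equal(interval_iou(c(10, 20), c(10, 20)), 1)
  expect_equal(interval_iou(c(0, 10), c(20, 30)), 0)
  expect_equal(interval_iou(c(0, 100), c(50, 150)), 1 / 3)
  expect_equal(interval_iou(c(50, 150), c(0, 100)), 1 / 3)
})

test_that("detection matching agrees with the exhaustive all-pairs oracle", {
  set.seed(3)
  for (i in 1:500) {
    preds <- random_intervals(sample(0:10, 1))
    gts <- random_intervals(sample(0:10, 1))
    t_iou <- sample(c(0.3, 0.5, 0.6), 1)
    got <- match_detections(preds, gts, t_iou)
    want <- oracle_match(preds, gts, t_iou)
    expect_identical(got$counts, want)
    expect_lte(got$counts$tp, nrow(preds))
    expect_lte(got$counts$fn, nrow(gts))
  }
})

test_that("perfect predictions give all TPs; empty predictions all FNs", {
  gts <- random_intervals(5)
  perfect <- match_detections(gts, gts, 0.99)
  expect_identical(perfect$counts, list(tp = 5L, fp = 0L, fn = 0L))
  none <- match_detections(random_intervals(0), random_intervals(3), 0.6)
  expect_identical(none$counts$fn, 3L)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_error(
    match_detections(tibble::tibble(start_frame = c(0L, 5L),
                                    end_frame = c(10L, 15L)),
                     random_intervals(2), 0.6),
    class = "squeakseg_overlapping_intervals")
})

test_that("matching is invariant to a global time shift", {
  set.seed(4)
  preds <- random_intervals(6)
  gts <- random_intervals(6)
  a <- match_detections(preds, gts, 0.5)
  shift <- function(x, d) dplyr::mutate(x, start_frame = start_frame + d,
                                        end_frame = end_frame + d)
  b <- match_detections(shift(preds, 1234L), shift(gts, 1234L), 0.5)
  expect_identical(a$counts, b$counts)
  expect_equal(a$tp_pairs$iou, b$tp_pairs$iou)
})

test_that("the default rule is not one-to-one; the greedy mode is", {
  gt <- tibble::tibble(start_frame = 0L, end_frame = 100L)
  preds <- tibble::tibble(start_frame = c(0L, 50L), end_frame = c(50L, 100L))
  literal <- match_detections(preds, gt, t_iou = 0.3)
  expect_identical(literal$counts, list(tp = 2L, fp = 0L, fn = 0L))
  greedy <- match_detections(preds, gt, t_iou = 0.3, one_to_one = TRUE)
  expect_identical(greedy$counts, list(tp = 1L, fp = 1L, fn = 0L))
})

test_that("the IoU threshold is strict", {
  gt <- tibble::tibble(start_frame = 0L, end_frame = 100L)
  pred <- tibble::tibble(start_frame = 0L, end_frame = 60L)  # IoU exactly 0.6
  at <- match_detections(pred, gt, t_iou = 0.6)
  expect_identical(at$counts$tp, 0L)
  below <- match_detections(pred, gt, t_iou = 0.59)
  expect_identical(below$counts$tp, 1L)
})

test_that("IoU histograms conserve the TP count", {
  set.seed(5)
  for (i in 1:20) {
    preds <- random_intervals(8)
    gts <- random_intervals(8)
    m <- match_detections(preds, gts, 0.2)
    h <- iou_histogram(m)
    expect_identical(sum(h$count), m$counts$tp)
  }
  perfect <- match_detections(random_intervals(4), random_intervals(0), 0.6)
  expect_identical(sum(iou_histogram(perfect)$count), 0L)
  self <- random_intervals(5)
  top <- iou_histogram(match_detections(self, self, 0.5))
  expect_identical(top$count[10], 5L)  # IoU = 1 lands in the closed top bin
})

test_that("relative length errors carry the over-segmentation sign", {
  gt <- tibble::tibble(start_frame = c(0L, 200L), end_frame = c(100L, 300L))
  pred <- tibble::tibble(start_frame = c(0L, 195L), end_frame = c(90L, 305L))
  m <- match_detections(pred, gt, 0.5)
  le <- length_errors(m)
  expect_equal(sort(le$rel_error), c(-0.10, 0.10))
  exact <- length_errors(match_detections(gt, gt, 0.5))
  expect_true(all(exact$rel_error == 0))
})

test_that("rank-sum p-values match exact enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)),
               oracle_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(rank_sum_test(c(1, 3, 5), c(2, 4, 6)),
               oracle_rank_sum_p(c(1, 3, 5), c(2, 4, 6)))
  set.seed(6)
  for (i in 1:10) {
    x <- runif(sample(3:6, 1)); y <- runif(sample(3:6, 1))
    expect_equal(rank_sum_test(x, y), oracle_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  # identical multisets are maximally non-significant
  expect_equal(rank_sum_test(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  # n = m = 12 uses the normal approximation; compare to the exact law
  set.seed(7)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  approx_p <- rank_sum_test(x, y)
  w <- sum(rank(c(x, y))[1:12]) - 12 * 13 / 2
  exact_p <- min(1, 2 * min(pwilcox(w, 12, 12),
                            1 - pwilcox(w - 1, 12, 12)))
  expect_lt(abs(approx_p - exact_p), 0.02)
  expect_error(rank_sum_test(numeric(0), 1:3), class = "squeakseg_bad_input")
  expect_identical(significance_stars(0.0004), "***")
  expect_identical(significance_stars(0.2), "ns")
})

test_that("evaluation reports pool counts over tracks and round-trip as JSON", {
  set.seed(8)
  gts <- lapply(1:3, function(i) random_label_vector(300L))
  preds <- lapply(gts, function(y) {
    y2 <- y
    flip <- sample(300, 15)
    y2[flip] <- 1L - y2[flip]
    y2
  })
  rep_ <- evaluate_tracks(preds, gts, t_iou = 0.4, frame_hop_s = 0.002)
  expect_identical(rep_$frame_counts$tp + rep_$frame_counts$fp +
                     rep_$frame_counts$tn + rep_$frame_counts$fn, 900L)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  back <- read_eval_report(path)
  expect_equal(glance(back), glance(rep_))
  expect_equal(back$tp_ious, rep_$tp_ious)
})

test_that("pr_curve endpoints, monotonicity, and single-threshold consistency", {
  set.seed(9)
  gts <- lapply(1:2, function(i) random_label_vector(400L, 0.05))
  confs <- lapply(gts, function(y) {
    pmin(pmax(y * 0.8 + 0.1 + rnorm(400, 0, 0.05), 0), 1)
  })
  curve <- pr_curve(confs, gts, t_c_grid = c(0, 0.25, 0.5, 0.75, 1),
                    K = 5L, t_iou = 0.5)
  raw <- dplyr::filter(curve, !postprocessed)
  # t_c = 0 labels everything positive; t_c = 1 nothing
  expect_equal(raw$recall[raw$t_c == 0], 1)
  expect_equal(raw$recall[raw$t_c == 1], 0)
  expect_true(is.na(raw$precision[raw$t_c == 1]))
  expect_true(all(diff(raw$recall) <= 1e-12))
  direct <- evaluate_tracks(lapply(confs, function(cf) as.integer(cf > 0.5)),
                            gts, t_iou = 0.5)
  expect_equal(raw$precision[raw$t_c == 0.5],
               direct$frame_metrics$precision)
  expect_equal(raw$det_recall[raw$t_c == 0.5], direct$detection$recall)
})

test_that("post-processing lifts detection precision on spike-injected input", {
  set.seed(10)
  gts <- list(); raws <- list(); posts <- list()
  for (i in 1:4) {
    y <- integer(600)
    for (s in seq(30, 540, by = 90)) y[s:(s + 49)] <- 1L
    noisy <- y
    noisy[sample(which(y == 0), 20)] <- 1L
    gts[[i]] <- y
    raws[[i]] <- noisy
    posts[[i]] <- postprocess_labels(noisy, 9L)
  }
  before <- evaluate_tracks(raws, gts, t_iou = 0.5)
  after <- evaluate_tracks(posts, gts, t_iou = 0.5)
  expect_gt(after$detection$precision, before$detection$precision)
  expect_gte(after$detection$recall, before$detection$recall)
})
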
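#' Pipeline configuration
#'
#' Aggregates every tunable of the segmentation pipeline with the
#' published defaults: 512-coefficient / hop-8 Kaiser STFT, 2048-frame
#' chunks at 50% overlap, confidence threshold `t_c = 0.5`, IoU threshold
#' `t_iou = 0.6`, and per-architecture post-processing kernels of 135
#' (AE), 150 (UNET) and 65 (RNN) frames.
#'
#' @param stft An [stft_config()].
#' @param chunk_n Chunk length in frames.
#' @param chunk_overlap Overlap fraction (only 0.5 supported).
#' @param arch Architecture name: `"ae"`, `"unet"`, or `"rnn"`.
#' @param preset Architecture width preset.
#' @param train A [train_config()].
#' @param postprocess_k Named integer vector of kernel lengths per
#'   architecture.
#' @param t_c Confidence threshold.
#' @param t_iou IoU threshold for detection evaluation.
#' @param seed Pipeline-level seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stft = stft_config(), chunk_n = 2048L,
                            chunk_overlap = 0.5, arch = "ae",
                            preset = "paper", train = train_config(),
                            postprocess_k = c(ae = 135L, unet = 150L,
                                              rnn = 65L),
                            t_c = 0.5, t_iou = 0.6, seed = 1L) {
  structure(list(stft = stft, chunk_n = as.integer(chunk_n),
                 chunk_overlap = chunk_overlap, arch = arch,
                 preset = preset, train = train,
                 postprocess_k = postprocess_k, t_c = t_c, t_iou = t_iou,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `pipeline_config` equal to the one written.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$stft <- unclass(x$stft)
  x$train <- unclass(x$train)
  x$postprocess_k <- as.list(x$postprocess_k)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    stft = do.call(stft_config, x$stft),
    chunk_n = x$chunk_n, chunk_overlap = x$chunk_overlap,
    arch = x$arch, preset = x$preset,
    train = do.call(train_config, x$train),
    postprocess_k = unlist(x$postprocess_k),
    t_c = x$t_c, t_iou = x$t_iou, seed = x$seed)
}

#' Split a dataset manifest into training and test tracks
#'
#' The split is at track level (never chunk level) in a 4:1 proportion:
#' the test set holds `round(total / 5)` tracks, so 198 tracks yield a
#' 158/40 split. Deterministic for a given seed.
#'
#' @param manifest A data frame with one row per track and a unique
#'   `track_id` column.
#' @param seed Integer seed.
#' @param test_fraction Test proportion (default 1/5).
#' @return The manifest tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_dataset <- function(manifest, seed = 1L, test_fraction = 0.2) {
  manifest <- tibble::as_tibble(manifest)
  if (!"track_id" %in% names(manifest)) {
    abort_squeakseg("`manifest` needs a `track_id` column.",
                    "squeakseg_bad_manifest")
  }
  if (anyDuplicated(manifest$track_id)) {
    abort_squeakseg("`track_id` values must be unique.",
                    "squeakseg_bad_manifest")
  }
  total <- nrow(manifest)
  if (total < 5L) {
    abort_squeakseg("At least 5 tracks are required for a 4:1 split.",
                    "squeakseg_bad_manifest")
  }
  n_test <- round(total * test_fraction)
  test_idx <- with_seed(seed, sample(total, n_test))
  manifest$split <- "train"
  manifest$split[test_idx] <- "test"
  manifest
}

#' Write / read call interval tables as CSV
#'
#' Dialect: header `track_id,start_s,end_s`, seconds with 6 decimal
#' places, half-open interval semantics.
#'
#' @param intervals A data frame with `track_id`, `start_s`, `end_s`.
#' @param path File path.
#' @return `write_intervals()` returns `path` invisibly;
#'   `read_intervals()` returns a tibble.
#' @export
write_intervals <- function(intervals, path) {
  df <- data.frame(track_id = intervals$track_id,
                   start_s = sprintf("%.6f", intervals$start_s),
                   end_s = sprintf("%.6f", intervals$end_s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) {
    abort_squeakseg(sprintf("Interval file not found: %s", path),
                    "squeakseg_missing_file")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("track_id", "start_s", "end_s") %in% names(df))) {
    abort_squeakseg(sprintf("Interval file %s lacks track_id/start_s/end_s columns.",
                            path),
                    "squeakseg_bad_input")
  }
  tibble::tibble(track_id = as.character(df$track_id),
                 start_s = as.numeric(df$start_s),
                 end_s = as.numeric(df$end_s))
}

#' Serialize / parse an evaluation report as JSON
#'
#' The round trip is lossless for all counts and metrics.
#'
#' @param report A `usv_eval_report`.
#' @param path File path.
#' @return `write_eval_report()` returns `path` invisibly;
#'   `read_eval_report()` an equivalent `usv_eval_report`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "usv_eval_report"))
  x <- list(
    frame_counts = as.list(report$frame_counts),
    detection_counts = report$detection$counts,
    tp_ious = report$tp_ious,
    length_errors = as.list(report$length_errors),
    t_iou = report$t_iou,
    frame_hop_s = report$frame_hop_s,
    n_tracks = report$n_tracks)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fc <- tibble::as_tibble(x$frame_counts)
  det <- lapply(x$detection_counts, as.integer)
  structure(list(
    frame_counts = fc,
    frame_metrics = frame_metrics(fc),
    detection = list(
      counts = det,
      precision = if (det$tp + det$fp > 0) det$tp / (det$tp + det$fp) else NA_real_,
      recall = if (det$tp + det$fn > 0) det$tp / (det$tp + det$fn) else NA_real_),
    tp_ious = as.numeric(x$tp_ious),
    length_errors = tibble::as_tibble(lapply(x$length_errors, as.numeric)),
    t_iou = x$t_iou,
    frame_hop_s = ifelse(is.null(x$frame_hop_s), NA_real_, x$frame_hop_s),
    n_tracks = as.integer(x$n_tracks)),
    class = "usv_eval_report")
}

#' Save / load a trained segmenter
#'
#' The checkpoint is an RDS of the model plus a self-describing JSON
#' sidecar (`<path>.json`) recording the architecture, STFT settings,
#' confidence threshold, and post-processing kernel.
#'
#' @param model A `usv_segmenter`.
#' @param path Checkpoint path (`.rds`).
#' @param stft The [stft_config()] the model expects.
#' @param t_c Confidence threshold to record.
#' @param K Post-processing kernel length to record.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model with a `sidecar` attribute.
#' @export
save_model <- function(model, path, stft = stft_config(), t_c = 0.5,
                       K = NULL) {
  stopifnot(inherits(model, "usv_segmenter"))
  obj <- list(arch = model$arch, params = model$params,
              state = as.list(model$state), history = model$history,
              train_config = model$train_config)
  saveRDS(obj, path)
  sidecar <- list(architecture = model$arch[c("name", "preset", "M", "n")],
                  parameter_count = parameter_count(model),
                  stft = unclass(stft), t_c = t_c, K = K)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) state[[nm]] <- obj$state[[nm]]
  model <- structure(list(arch = obj$arch, params = obj$params,
                          state = state, history = obj$history,
                          train_config = obj$train_config),
                     class = "usv_segmenter")
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(model, "sidecar") <- jsonlite::read_json(sidecar_path,
                                                  simplifyVector = TRUE)
  }
  model
}

stage_banner <- function(stage, ...) {
  params <- paste(names(list(...)), unlist(list(...)), sep = "=",
                  collapse = ", ")
  message(sprintf("[squeakseg] %s (%s)", stage, params))
}

#' Run the full pipeline on synthetic fixture tracks
#'
#' Orchestrates every stage end to end: generate fixture spectrograms
#' with ground truth, split tracks 4:1, train the configured segmenter on
#' the training tracks' chunks, predict the test tracks, post-process,
#' and evaluate. Artifacts (model checkpoint + sidecar, per-track
#' predicted interval CSVs, and a JSON evaluation report) are written to
#' `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_tracks Number of synthetic tracks.
#' @param synth A [synth_config()] describing each track; per-track seeds
#'   are derived from `config$seed`.
#' @param M,frame_hop_s Fixture spectrogram geometry.
#' @param K Post-processing kernel; default taken from
#'   `config$postprocess_k[config$arch]`.
#' @return The `usv_eval_report` for the test tracks, invisibly, with the
#'   written file paths in attribute `"artifacts"`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         n_tracks = 10L, synth = synth_config(duration_s = 20),
                         M = 64L, frame_hop_s = 0.002, K = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(K)) K <- as.integer(config$postprocess_k[[config$arch]])
  stage_banner("synthesize", n_tracks = n_tracks,
               duration_s = synth$duration_s, snr_db = synth$snr_db)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    s <- synth
    s$seed <- config$seed * 1000L + i
    generate_spectrogram_fixture(s, M = M, frame_hop_s = frame_hop_s,
                                 track_id = sprintf("track%02d", i))
  })
  manifest <- split_dataset(tibble::tibble(track_id = vapply(tracks, `[[`,
                                                             "", "track_id")),
                            seed = config$seed)
  stage_banner("split", train = sum(manifest$split == "train"),
               test = sum(manifest$split == "test"))
  is_train <- manifest$split == "train"
  make_samples <- function(tr) {
    chunks <- split_spectrogram(tr$spectrogram, n = config$chunk_n)
    targets <- split_labels(tr$gt_labels, n = config$chunk_n)
    mapply(function(ch, tg) list(x = ch$values, y = tg$pred),
           chunks, targets, SIMPLIFY = FALSE)
  }
  train_set <- unlist(lapply(tracks[is_train], make_samples),
                      recursive = FALSE)
  arch <- architecture_spec(config$arch, M = M, n = config$chunk_n,
                            preset = config$preset)
  stage_banner("train", arch = config$arch, preset = config$preset,
               chunks = length(train_set), lr = config$train$lr,
               max_epochs = config$train$max_epochs)
  model <- build_model(arch, seed = config$seed)
  model <- train(model, train_set, config$train)
  model_path <- file.path(out_dir, "model.rds")
  save_model(model, model_path, stft = config$stft, t_c = config$t_c, K = K)
  stage_banner("predict", test_tracks = sum(!is_train), t_c = config$t_c,
               K = K)
  test_tracks <- tracks[!is_train]
  preds <- list()
  gts <- list()
  csvs <- character(0)
  for (tr in test_tracks) {
    pr <- predict_track(model, tr$spectrogram, t_c = config$t_c)
    z <- postprocess_labels(pr$labels, K)
    preds[[length(preds) + 1L]] <- z
    gts[[length(gts) + 1L]] <- tr$gt_labels
    segs <- labels_to_segments(z, frame_hop_s = frame_hop_s,
                               track_id = tr$track_id)
    csv <- file.path(out_dir, paste0(tr$track_id, "_pred.csv"))
    write_intervals(segs, csv)
    csvs <- c(csvs, csv)
  }
  stage_banner("evaluate", t_iou = config$t_iou)
  report <- evaluate_tracks(preds, gts, t_iou = config$t_iou,
                            frame_hop_s = frame_hop_s)
  report_path <- file.path(out_dir, "report.json")
  write_eval_report(report, report_path)
  attr(report, "artifacts") <- list(model = model_path,
                                    predictions = csvs,
                                    report = report_path)
  invisible(report)
}
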
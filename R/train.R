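#' Training configuration
#'
#' Binary cross-entropy loss, Adam optimization, and early stopping on
#' validation loss. Published learning-rate ranges for the full-width
#' architectures are 5e-5..1e-7 (RNN), 1e-4..1e-6 (AE), and 1e-4..1e-7
#' (UNET); small synthetic experiments tolerate larger rates.
#'
#' @param lr Adam learning rate.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience, in epochs, on validation
#'   loss; must be smaller than `max_epochs`.
#' @param batch_size Chunks per gradient step.
#' @param validation_fraction Fraction of the dataset held out for
#'   validation when no explicit validation set is supplied.
#' @param t_c Confidence threshold used to binarize predictions.
#' @param seed Seed driving weight initialization order, shuffling, and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, max_epochs = 100L, patience = 10L,
                         batch_size = 32L, validation_fraction = 0.2,
                         t_c = 0.5, seed = 1L) {
  if (lr <= 0) abort_squeakseg("`lr` must be positive.", "squeakseg_bad_config")
  if (patience >= max_epochs) {
    abort_squeakseg("`patience` must be smaller than `max_epochs`.",
                    "squeakseg_bad_config")
  }
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 t_c = t_c, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# One gradient step on a batch. Returns loss and updated model/opt.
train_step <- function(model, xb, yb, opt, lr) {
  tape <- new_tape(grad = TRUE)
  ids <- new.env(parent = emptyenv())
  getp <- function(name) {
    if (is.null(ids[[name]])) ids[[name]] <- tp_value(tape, model$params[[name]])
    ids[[name]]
  }
  out_id <- model_forward(tape, getp, tp_value(tape, xb), model,
                          training = TRUE)
  loss_id <- op_bce_probs(tape, out_id, yb)
  loss <- tp_get(tape, loss_id)
  if (!is.finite(loss)) {
    abort_squeakseg(sprintf("Non-finite training loss (%g); check learning rate and inputs.",
                            loss),
                    "squeakseg_nan_loss")
  }
  grads_all <- tape_backward(tape, loss_id)
  grads <- list()
  for (nm in ls(ids)) grads[[nm]] <- grads_all[[ids[[nm]]]]
  upd <- adam_step(model$params, grads, opt, lr)
  model$params <- upd$params
  list(model = model, opt = upd$opt, loss = loss)
}

dataset_loss <- function(model, dataset, batch_size = 16L) {
  total <- 0
  n <- 0L
  for (b0 in seq(1L, length(dataset), by = batch_size)) {
    b1 <- min(b0 + batch_size - 1L, length(dataset))
    batch <- dataset[b0:b1]
    conf <- forward_chunks(model, lapply(batch, `[[`, "x"))
    yb <- vapply(batch, `[[`, numeric(model$arch$n), "y")
    eps <- 1e-7
    pc <- pmin(pmax(conf, eps), 1 - eps)
    total <- total - sum(yb * log(pc) + (1 - yb) * log(1 - pc))
    n <- n + length(pc)
  }
  total / n
}

#' Train a segmenter
#'
#' Mini-batch Adam on binary cross-entropy with early stopping: training
#' halts once the validation loss has not improved for `patience` epochs
#' and the best-validation-loss weights are restored. Deterministic for a
#' given `cfg$seed`.
#'
#' @param model An untrained (or previously trained) `usv_segmenter`.
#' @param dataset List of training samples, each a list with `x` (an
#'   `M x n` chunk matrix) and `y` (length-`n` binary target).
#' @param cfg A [train_config()].
#' @param val_dataset Optional explicit validation set (same structure);
#'   when omitted, `cfg$validation_fraction` of `dataset` is held out.
#' @param verbose Print per-epoch losses.
#' @return The trained `usv_segmenter`, with `history` (a tibble of
#'   epoch, train and validation loss) and `train_config` attached.
#' @export
train <- function(model, dataset, cfg = train_config(), val_dataset = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "usv_segmenter"))
  if (length(dataset) == 0) {
    abort_squeakseg("Training dataset is empty.", "squeakseg_empty_dataset")
  }
  with_seed(cfg$seed, {
    if (is.null(val_dataset)) {
      n_val <- max(1L, round(cfg$validation_fraction * length(dataset)))
      if (n_val >= length(dataset)) {
        abort_squeakseg("Dataset too small to hold out a validation split.",
                        "squeakseg_empty_dataset")
      }
      val_idx <- sample(length(dataset), n_val)
      val_dataset <- dataset[val_idx]
      dataset <- dataset[-val_idx]
    }
    opt <- adam_init(model$params)
    best_loss <- Inf
    best_params <- model$params
    best_state <- as.list(model$state)
    best_epoch <- 0L
    wait <- 0L
    history <- list()
    arch <- model$arch
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(dataset))
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        B <- length(idx)
        xb <- array(0, c(arch$M, arch$n, B, 1L))
        yb <- matrix(0, arch$n, B)
        for (i in seq_len(B)) {
          xb[, , i, 1L] <- dataset[[idx[i]]]$x
          yb[, i] <- dataset[[idx[i]]]$y
        }
        st <- train_step(model, xb, yb, opt, cfg$lr)
        model <- st$model
        opt <- st$opt
        ep_loss <- ep_loss + st$loss
        nb <- nb + 1L
      }
      val_loss <- dataset_loss(model, val_dataset)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        ep_loss / nb, val_loss))
      }
      if (val_loss < best_loss) {
        best_loss <- val_loss
        best_params <- model$params
        best_state <- as.list(model$state)
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model$params <- best_params
    for (nm in names(best_state)) model$state[[nm]] <- best_state[[nm]]
    model$state$trained <- TRUE
    model$state$best_epoch <- best_epoch
    model$state$best_val_loss <- best_loss
    model$history <- dplyr::bind_rows(history)
    model$train_config <- cfg
    model
  })
}

#' k-fold cross-validation over a learning-rate grid
#'
#' Folds are formed at track level: all chunks of one track stay in a
#' single fold, so validation tracks are never seen in training. The
#' learning rate minimizing the mean validation loss across folds is
#' selected.
#'
#' @param tracks List of per-track datasets; each element is itself a
#'   list of `(x, y)` chunk samples as in [train()].
#' @param arch A `usv_arch_spec` describing the model to fit.
#' @param lr_grid Learning rates to evaluate.
#' @param k Number of folds.
#' @param cfg Base [train_config()]; its `lr` is overridden by the grid.
#' @return A list with `best_lr` and `metrics`, a tibble of
#'   (`lr`, `fold`, `val_loss`, `epochs`).
#' @export
cross_validate <- function(tracks, arch, lr_grid, k = 5L,
                           cfg = train_config()) {
  if (k > length(tracks)) {
    abort_squeakseg(sprintf("k = %d exceeds the number of tracks (%d).",
                            k, length(tracks)),
                    "squeakseg_bad_config")
  }
  if (length(lr_grid) == 0) {
    abort_squeakseg("`lr_grid` must be non-empty.", "squeakseg_bad_config")
  }
  folds <- with_seed(cfg$seed,
                     split(sample(length(tracks)),
                           rep_len(seq_len(k), length(tracks))))
  rows <- list()
  for (lr in lr_grid) {
    for (f in seq_len(k)) {
      val_tracks <- folds[[f]]
      train_set <- unlist(tracks[setdiff(seq_along(tracks), val_tracks)],
                          recursive = FALSE)
      val_set <- unlist(tracks[val_tracks], recursive = FALSE)
      cfg_f <- cfg
      cfg_f$lr <- lr
      model <- build_model(arch, seed = cfg$seed)
      fit <- train(model, train_set, cfg_f, val_dataset = val_set)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(lr = lr, fold = f,
                       val_loss = fit$state$best_val_loss,
                       epochs = nrow(fit$history))
    }
  }
  metrics <- dplyr::bind_rows(rows)
  mean_loss <- metrics |>
    dplyr::group_by(.data$lr) |>
    dplyr::summarise(loss = mean(.data$val_loss), .groups = "drop")
  list(best_lr = mean_loss$lr[which.min(mean_loss$loss)], metrics = metrics)
}

#' Segment a full track with a trained model
#'
#' Splits the spectrogram into 50%-overlapping chunks, runs the model,
#' discards padded tail positions, merges per-frame confidences with the
#' per-frame maximum (equivalent to thresholding each chunk at `t_c` and
#' OR-merging), and thresholds at `t_c`.
#'
#' @param model A trained `usv_segmenter`.
#' @param spec A `usv_spectrogram` with `M` rows matching the model.
#' @param t_c Confidence threshold in `[0, 1]`; a frame is labelled 1 iff
#'   its merged confidence is strictly greater than `t_c`.
#' @param batch_size Chunks evaluated per forward pass.
#' @return A list with `confidence` (length-N numeric), `labels`
#'   (length-N 0/1 integer), and `N`.
#' @export
predict_track <- function(model, spec, t_c = 0.5, batch_size = 8L) {
  stopifnot(inherits(model, "usv_segmenter"))
  if (!isTRUE(model$state$trained)) {
    abort_squeakseg("Model has not been trained; call train() first.",
                    "squeakseg_untrained")
  }
  chunks <- split_spectrogram(spec, n = model$arch$n)
  N <- ncol(spec$values)
  preds <- list()
  for (b0 in seq(1L, length(chunks), by = batch_size)) {
    b1 <- min(b0 + batch_size - 1L, length(chunks))
    conf <- forward_chunks(model, lapply(chunks[b0:b1], `[[`, "values"))
    for (j in seq_len(b1 - b0 + 1L)) {
      ch <- chunks[[b0 + j - 1L]]
      preds[[length(preds) + 1L]] <- list(pred = conf[, j],
                                          origin = ch$origin,
                                          valid_len = ch$valid_len)
    }
  }
  confidence <- merge_predictions(preds, N)
  list(confidence = confidence,
       labels = as.integer(confidence > t_c),
       N = N)
}
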
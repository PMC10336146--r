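# Finite-difference gradient checks for the autodiff core, then the
# training-level contracts. `ns` gives access to the internal ops.
ns <- asNamespace("squeakseg")

# Check d(sum(f(x) * w)) / dx against central differences for every input.
check_op_grad <- function(build, inputs, eps = 1e-5, tol = 1e-4,
                          n_probe = 6L) {
  run <- function(vals) {
    tape <- ns$new_tape(grad = TRUE)
    ids <- lapply(vals, function(v) ns$tp_value(tape, v))
    out_id <- build(tape, ids)
    out <- ns$tp_get(tape, out_id)
    list(tape = tape, out_id = out_id, out = out, ids = ids)
  }
  set.seed(123)
  r0 <- run(inputs)
  w <- rnorm(length(r0$out))
  if (!is.null(dim(r0$out))) dim(w) <- dim(r0$out)
  # scalar objective sum(out * w): run the tape backward with dout = w
  grads <- local({
    tape <- r0$tape
    recs <- tape$records
    gr <- vector("list", tape$n)
    gr[[r0$out_id]] <- w
    for (rec in rev(recs)) {
      dout <- gr[[rec$out]]
      if (is.null(dout)) next
      gs <- rec$fn(dout)
      for (j in seq_along(rec$inputs)) {
        id <- rec$inputs[j]
        if (id > 0L && !is.null(gs[[j]])) {
          gr[[id]] <- if (is.null(gr[[id]])) gs[[j]] else gr[[id]] + gs[[j]]
        }
      }
    }
    gr
  })
  for (vi in seq_along(inputs)) {
    ga <- grads[[r0$ids[[vi]]]]
    expect_false(is.null(ga))
    probes <- sample(length(inputs[[vi]]), min(n_probe, length(inputs[[vi]])))
    for (j in probes) {
      up <- inputs; up[[vi]][j] <- up[[vi]][j] + eps
      dn <- inputs; dn[[vi]][j] <- dn[[vi]][j] - eps
      gn <- (sum(run(up)$out * w) - sum(run(dn)$out * w)) / (2 * eps)
      expect_lt(abs(gn - ga[j]) / max(1, abs(gn), abs(ga[j])), tol)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 8 * 2 * 3), c(6, 8, 2, 3))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  check_op_grad(function(tape, ids) {
    ns$op_conv2d(tape, ids[[1]], ids[[2]], ids[[3]])
  }, list(x, W, b))
  # stride 2, as in the U-Net encoder
  check_op_grad(function(tape, ids) {
    ns$op_conv2d(tape, ids[[1]], ids[[2]], ids[[3]], stride = c(2L, 2L))
  }, list(x, W, b))
  x1 <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  W1 <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  check_op_grad(function(tape, ids) {
    ns$op_conv1d(tape, ids[[1]], ids[[2]], ids[[3]])
  }, list(x1, W1, rnorm(2)))
})

test_that("pooling, resampling and concatenation gradients are exact", {
  set.seed(2)
  x <- array(rnorm(4 * 6 * 2 * 3), c(4, 6, 2, 3))
  check_op_grad(function(tape, ids) ns$op_maxpool2d(tape, ids[[1]]), list(x))
  check_op_grad(function(tape, ids) ns$op_avgpool_freq(tape, ids[[1]]),
                list(x))
  check_op_grad(function(tape, ids) ns$op_upsample2d(tape, ids[[1]]), list(x))
  s <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  check_op_grad(function(tape, ids) ns$op_upsample1d(tape, ids[[1]]), list(s))
  y <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
  check_op_grad(function(tape, ids) {
    ns$op_concat_c(tape, ids[[1]], ids[[2]])
  }, list(x, y))
})

test_that("dense, batch-norm, GRU and loss gradients are exact", {
  set.seed(3)
  xm <- matrix(rnorm(4 * 5), 4, 5)
  Wm <- matrix(rnorm(5 * 3), 5, 3)
  check_op_grad(function(tape, ids) {
    ns$op_dense(tape, ids[[1]], ids[[2]], ids[[3]])
  }, list(xm, Wm, rnorm(3)))
  x <- array(rnorm(4 * 6 * 3 * 2), c(4, 6, 3, 2))
  check_op_grad(function(tape, ids) {
    st <- new.env()
    ns$op_batchnorm(tape, ids[[1]], ids[[2]], ids[[3]], st, "bn",
                    training = TRUE)
  }, list(x, rnorm(2), rnorm(2)), tol = 5e-4)
  xs <- array(rnorm(7 * 2 * 3), c(7, 2, 3))
  U <- 4L
  check_op_grad(function(tape, ids) {
    ns$op_gru(tape, ids[[1]], ids[[2]], ids[[3]], ids[[4]])
  }, list(xs, matrix(rnorm(3 * 3 * U), 3, 3 * U) * 0.3,
          matrix(rnorm(U * 3 * U), U, 3 * U) * 0.3, rnorm(3 * U) * 0.1),
  tol = 5e-4)
  p <- matrix(runif(12, 0.05, 0.95), 4, 3)
  tgt <- matrix(rbinom(12, 1, 0.5), 4, 3)
  check_op_grad(function(tape, ids) {
    ns$op_bce_probs(tape, ids[[1]], tgt)
  }, list(p))
})

test_that("all three architectures map M x n chunks to [0,1]^n", {
  set.seed(4)
  chunks <- list(matrix(rnorm(16 * 64), 16, 64),
                 matrix(rnorm(16 * 64), 16, 64),
                 matrix(rnorm(16 * 64), 16, 64))
  for (a in c("ae", "unet", "rnn")) {
    m <- build_model(architecture_spec(a, M = 16L, n = 64L, preset = "tiny"),
                     seed = 5)
    conf <- ns$forward_chunks(m, chunks)
    expect_identical(dim(conf), c(64L, 3L))
    expect_true(all(conf > 0 & conf < 1))
    # inference is deterministic (dropout off, stored batch-norm stats)
    expect_identical(conf, ns$forward_chunks(m, chunks))
  }
  expect_error(architecture_spec("ae", M = 100L, n = 64L, preset = "tiny"),
               class = "squeakseg_bad_shape")
})

test_that("whole-model gradients agree with finite differences", {
  for (a in c("ae", "unet", "rnn")) {
    m <- build_model(architecture_spec(a, M = 8L, n = 16L, preset = "tiny"),
                     seed = 6)
    set.seed(7)
    x <- array(rnorm(8 * 16 * 2), c(8, 16, 2, 1))
    y <- matrix(rbinom(32, 1, 0.5), 16, 2)
    run <- function(params) {
      m2 <- m
      m2$params <- params
      st <- new.env()
      for (nm in ls(m$state)) st[[nm]] <- m$state[[nm]]
      m2$state <- st
      tape <- ns$new_tape(grad = TRUE)
      ids <- new.env()
      getp <- function(nm) {
        if (is.null(ids[[nm]])) ids[[nm]] <- ns$tp_value(tape, m2$params[[nm]])
        ids[[nm]]
      }
      set.seed(99)  # pins the dropout masks
      out <- ns$model_forward(tape, getp, ns$tp_value(tape, x), m2,
                              training = TRUE)
      lid <- ns$op_bce_probs(tape, out, y)
      list(loss = ns$tp_get(tape, lid), tape = tape, lid = lid, ids = ids)
    }
    r <- run(m$params)
    g <- ns$tape_backward(r$tape, r$lid)
    set.seed(8)
    for (nm in sample(ls(r$ids), 5)) {
      ga <- g[[r$ids[[nm]]]]
      j <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      up <- m$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- m$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      gn <- (run(up)$loss - run(dn)$loss) / (2 * eps)
      expect_lt(abs(gn - ga[j]) / max(1e-4, abs(gn) + abs(ga[j])), 2e-3)
    }
  }
})

test_that("training reduces the loss and restores the best checkpoint", {
  ds <- make_toy_dataset(16L)
  m <- build_model(architecture_spec("ae", M = 16L, n = 64L,
                                     preset = "tiny"), seed = 2)
  cfg <- train_config(lr = 3e-3, max_epochs = 6L, patience = 3L,
                      batch_size = 4L, seed = 11L)
  fit <- train(m, ds, cfg)
  expect_true(fit$state$trained)
  h <- tidy(fit)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # early-stopping contract: restored checkpoint is the val-loss minimum
  expect_equal(fit$state$best_val_loss, min(h$val_loss))
  expect_lte(fit$state$best_val_loss, h$val_loss[nrow(h)])
  # 1-epoch training still yields valid probabilities
  quick <- train(build_model(architecture_spec("ae", M = 16L, n = 64L,
                                               preset = "tiny"), seed = 3),
                 ds, train_config(lr = 1e-3, max_epochs = 2L, patience = 1L,
                                  batch_size = 8L, seed = 1L))
  conf <- ns$forward_chunks(quick, list(ds[[1]]$x))
  expect_true(all(conf >= 0 & conf <= 1))
  expect_error(train(m, list(), cfg), class = "squeakseg_empty_dataset")
})

test_that("training is deterministic given the seed", {
  ds <- make_toy_dataset(10L)
  cfg <- train_config(lr = 1e-3, max_epochs = 2L, patience = 1L,
                      batch_size = 4L, seed = 21L)
  f1 <- train(build_model(architecture_spec("ae", M = 16L, n = 64L,
                                            preset = "tiny"), 4), ds, cfg)
  f2 <- train(build_model(architecture_spec("ae", M = 16L, n = 64L,
                                            preset = "tiny"), 4), ds, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("raising the confidence threshold never adds positive frames", {
  ds <- make_toy_dataset(12L)
  fit <- train(build_model(architecture_spec("ae", M = 16L, n = 64L,
                                             preset = "tiny"), 5),
               ds, train_config(lr = 3e-3, max_epochs = 4L, patience = 2L,
                                batch_size = 4L, seed = 31L))
  spec <- squeakseg:::new_spectrogram(
    matrix(rnorm(16 * 300, -1), 16, 300), frame_hop_s = 1e-3,
    freq_hz = (1:16) * 1000, rate = 250000L,
    cfg = stft_config(normalization = "none"), track_id = "t")
  spec$values[10, 40:80] <- 3
  previous <- Inf
  for (t_c in c(0, 0.25, 0.5, 0.75, 1)) {
    pr <- predict_track(fit, spec, t_c = t_c)
    expect_length(pr$labels, 300L)
    expect_lte(sum(pr$labels), previous)
    previous <- sum(pr$labels)
  }
  pr0 <- predict_track(fit, spec, t_c = 0)
  expect_true(all(pr0$labels == 1L))
  pr1 <- predict_track(fit, spec, t_c = 1)
  expect_true(all(pr1$labels == 0L))
  untrained <- build_model(architecture_spec("ae", M = 16L, n = 64L,
                                             preset = "tiny"), 6)
  expect_error(predict_track(untrained, spec),
               class = "squeakseg_untrained")
})

test_that("cross-validation folds are disjoint, cover all tracks, and pick the grid's lr", {
  tracks <- lapply(1:5, function(i) make_toy_dataset(2L, seed = 100 + i))
  arch <- architecture_spec("ae", M = 16L, n = 64L, preset = "tiny")
  cfg <- train_config(lr = 1e-3, max_epochs = 2L, patience = 1L,
                      batch_size = 8L, seed = 9L)
  cv <- cross_validate(tracks, arch, lr_grid = 2e-3, k = 5L, cfg = cfg)
  expect_equal(cv$best_lr, 2e-3)
  expect_identical(nrow(cv$metrics), 5L)
  folds <- squeakseg:::with_seed(cfg$seed,
                                 split(sample(5L), rep_len(1:5, 5)))
  expect_identical(sort(unname(unlist(folds))), 1:5)
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  expect_error(cross_validate(tracks, arch, 1e-3, k = 6L, cfg = cfg),
               class = "squeakseg_bad_config")
})
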
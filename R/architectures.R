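#' Segmenter architecture specification
#'
#' Three frame-labelling networks are supported, each mapping an `M x n`
#' spectrogram chunk to `n` per-frame confidences in `[0, 1]`:
#'
#' * `"ae"` — a convolutional auto-encoder: 6 encoder blocks of
#'   3x3 convolution (8, 8, 16, 16, 32, 32 filters, ReLU, He-normal
#'   init) each followed by 2x2 max pooling; an average pool over the
#'   frequency axis forms the latent sequence; the decoder is 6 blocks of
#'   1-D up-sampling (factor 2) each followed by two length-3 1-D
#'   convolutions with (32,32), (32,32), (16,16), (16,16), (8,8), (4,1)
#'   filters; the final 1-filter convolution carries the sigmoid.
#' * `"unet"` — a U-Net: 5 stride-2 3x3 convolutions (8, 16, 32, 64,
#'   96 filters, ReLU, He-normal); the decoder is 4 blocks of 2x2
#'   up-sampling plus a 3x3 convolution (64, 32, 16, 8 filters), each
#'   output concatenated with the matching encoder level; then one more
#'   up-sampling and two convolutions (8 and 1 filters, sigmoid on the
#'   last); the frequency axis is removed by average pooling at the very
#'   end, after the sigmoid.
#' * `"rnn"` — a convolutional-recurrent network: three conv blocks
#'   (16 filters 3x3, then 32 and 64 filters 5x5), each with batch
#'   normalization, ReLU, and 2x2 max pooling; an average pool over
#'   frequency yields a sequence fed through GRUs with 32, 16 and 1
#'   units; dropout 0.3; then dense layers with 256, 256 and `n` neurons
#'   (batch norm + ReLU + dropout 0.4 after the first two) and a final
#'   sigmoid.
#'
#' `preset = "tiny"` gives reduced-width variants of the same topologies
#' for fast CPU experiments and tests.
#'
#' @param name `"ae"`, `"unet"`, or `"rnn"`.
#' @param M Frequency bins of the input chunk; must be divisible by the
#'   architecture's total pooling/stride factor.
#' @param n Time frames per chunk.
#' @param preset `"paper"` (full widths above) or `"tiny"`.
#' @return A list of class `usv_arch_spec`.
#' @export
architecture_spec <- function(name = c("ae", "unet", "rnn"), M = 256L,
                              n = 2048L, preset = c("paper", "tiny")) {
  name <- match.arg(name)
  preset <- match.arg(preset)
  M <- as.integer(M); n <- as.integer(n)
  spec <- switch(name,
    ae = {
      if (preset == "paper") {
        list(enc_filters = c(8L, 8L, 16L, 16L, 32L, 32L),
             dec_filters = list(c(32L, 32L), c(32L, 32L), c(16L, 16L),
                                c(16L, 16L), c(8L, 8L), c(4L, 1L)))
      } else {
        # narrower presets starve the frequency-average bottleneck and
        # make convergence strongly init-dependent
        list(enc_filters = c(8L, 8L, 16L),
             dec_filters = list(c(16L, 16L), c(8L, 8L), c(4L, 1L)))
      }
    },
    unet = {
      if (preset == "paper") {
        list(enc_filters = c(8L, 16L, 32L, 64L, 96L),
             dec_filters = c(64L, 32L, 16L, 8L),
             final_filters = c(8L, 1L))
      } else {
        list(enc_filters = c(4L, 8L, 16L),
             dec_filters = c(8L, 4L),
             final_filters = c(4L, 1L))
      }
    },
    rnn = {
      if (preset == "paper") {
        list(conv_filters = c(16L, 32L, 64L), conv_kernels = c(3L, 5L, 5L),
             gru_units = c(32L, 16L, 1L), dense_units = c(256L, 256L),
             dropout = c(0.3, 0.4, 0.4))
      } else {
        list(conv_filters = c(4L, 8L), conv_kernels = c(3L, 3L),
             gru_units = c(8L, 4L, 1L), dense_units = c(32L, 32L),
             dropout = c(0.3, 0.4, 0.4))
      }
    })
  depth <- switch(name,
                  ae = length(spec$enc_filters),
                  unet = length(spec$enc_filters),
                  rnn = length(spec$conv_filters))
  pool <- 2L^depth
  if (M %% pool != 0L || n %% pool != 0L) {
    abort_squeakseg(
      sprintf("Input %d x %d is incompatible with the %s encoder: both dims must be divisible by %d (layer depth %d).",
              M, n, name, pool, depth),
      "squeakseg_bad_shape")
  }
  structure(c(list(name = name, preset = preset, M = M, n = n,
                   kernel = 3L), spec),
            class = "usv_arch_spec")
}

he_normal <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

glorot <- function(fan_in, fan_out, dims) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
}

# Conv2d weights: (C_in, kh, kw, C_out); conv1d: (C_in, k, C_out).
init_params <- function(arch) {
  p <- list()
  add_conv2d <- function(nm, cin, k, cout) {
    p[[paste0(nm, "_W")]] <<- he_normal(cin * k * k, c(cin, k, k, cout))
    p[[paste0(nm, "_b")]] <<- numeric(cout)
  }
  add_conv1d <- function(nm, cin, k, cout) {
    p[[paste0(nm, "_W")]] <<- he_normal(cin * k, c(cin, k, cout))
    p[[paste0(nm, "_b")]] <<- numeric(cout)
  }
  add_bn <- function(nm, c_) {
    p[[paste0(nm, "_gamma")]] <<- rep(1, c_)
    p[[paste0(nm, "_beta")]] <<- numeric(c_)
  }
  add_dense <- function(nm, fin, fout) {
    p[[paste0(nm, "_W")]] <<- glorot(fin, fout, c(fin, fout))
    p[[paste0(nm, "_b")]] <<- numeric(fout)
  }
  add_gru <- function(nm, cin, u) {
    p[[paste0(nm, "_Wx")]] <<- glorot(cin, u, c(cin, 3L * u))
    p[[paste0(nm, "_Wh")]] <<- glorot(u, u, c(u, 3L * u))
    p[[paste0(nm, "_b")]] <<- numeric(3L * u)
  }
  if (arch$name == "ae") {
    cin <- 1L
    for (i in seq_along(arch$enc_filters)) {
      add_conv2d(paste0("enc", i), cin, arch$kernel, arch$enc_filters[i])
      cin <- arch$enc_filters[i]
    }
    for (i in seq_along(arch$dec_filters)) {
      f <- arch$dec_filters[[i]]
      add_conv1d(paste0("dec", i, "a"), cin, arch$kernel, f[1])
      add_conv1d(paste0("dec", i, "b"), f[1], arch$kernel, f[2])
      cin <- f[2]
    }
  } else if (arch$name == "unet") {
    cin <- 1L
    for (i in seq_along(arch$enc_filters)) {
      add_conv2d(paste0("enc", i), cin, arch$kernel, arch$enc_filters[i])
      cin <- arch$enc_filters[i]
    }
    L <- length(arch$enc_filters)
    for (i in seq_along(arch$dec_filters)) {
      add_conv2d(paste0("dec", i), cin, arch$kernel, arch$dec_filters[i])
      cin <- arch$dec_filters[i] + arch$enc_filters[L - i]
    }
    add_conv2d("final1", cin, arch$kernel, arch$final_filters[1])
    add_conv2d("final2", arch$final_filters[1], arch$kernel, arch$final_filters[2])
  } else {
    cin <- 1L
    for (i in seq_along(arch$conv_filters)) {
      add_conv2d(paste0("conv", i), cin, arch$conv_kernels[i],
                 arch$conv_filters[i])
      add_bn(paste0("convbn", i), arch$conv_filters[i])
      cin <- arch$conv_filters[i]
    }
    for (i in seq_along(arch$gru_units)) {
      add_gru(paste0("gru", i), cin, arch$gru_units[i])
      cin <- arch$gru_units[i]
    }
    seq_len_ <- arch$n %/% 2L^length(arch$conv_filters)
    fin <- seq_len_
    for (i in seq_along(arch$dense_units)) {
      add_dense(paste0("dense", i), fin, arch$dense_units[i])
      add_bn(paste0("densebn", i), arch$dense_units[i])
      fin <- arch$dense_units[i]
    }
    add_dense("dense_out", fin, arch$n)
  }
  p
}

#' Build an (untrained) segmenter model
#'
#' Instantiates the parameter tensors of an [architecture_spec()] with
#' He-normal (convolutions) / Glorot (dense, GRU) initialization.
#'
#' @param arch A `usv_arch_spec`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `usv_segmenter`.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "usv_arch_spec"))
  params <- with_seed(seed, init_params(arch))
  state <- new.env(parent = emptyenv())
  state$trained <- FALSE
  structure(list(arch = arch, params = params, state = state,
                 history = NULL, train_config = NULL),
            class = "usv_segmenter")
}

#' Number of trainable parameters of a segmenter
#'
#' @param model A `usv_segmenter` (or a `usv_arch_spec`, which is built
#'   first).
#' @return Integer parameter count (weights, biases, and batch-norm
#'   scale/shift; running statistics are not trainable and not counted).
#' @export
parameter_count <- function(model) {
  if (inherits(model, "usv_arch_spec")) model <- build_model(model)
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.usv_segmenter <- function(x, ...) {
  cat(sprintf("<usv_segmenter> %s (%s), input %d x %d, %d parameters, %s\n",
              toupper(x$arch$name), x$arch$preset, x$arch$M, x$arch$n,
              parameter_count(x),
              if (x$state$trained) "trained" else "untrained"))
  invisible(x)
}

# Forward pass: x_id holds (M, n, B, 1); returns id of a (n, B)
# probability matrix.
model_forward <- function(tape, getp, x_id, model, training = FALSE) {
  arch <- model$arch
  state <- model$state
  switch(arch$name,
    ae = {
      h <- x_id
      for (i in seq_along(arch$enc_filters)) {
        h <- op_relu(tape, op_conv2d(tape, h, getp(paste0("enc", i, "_W")),
                                     getp(paste0("enc", i, "_b"))))
        h <- op_maxpool2d(tape, h)
      }
      h <- op_avgpool_freq(tape, h)  # latent sequence (T, B, C)
      nd <- length(arch$dec_filters)
      for (i in seq_len(nd)) {
        h <- op_upsample1d(tape, h)
        h <- op_relu(tape, op_conv1d(tape, h, getp(paste0("dec", i, "a_W")),
                                     getp(paste0("dec", i, "a_b"))))
        h <- op_conv1d(tape, h, getp(paste0("dec", i, "b_W")),
                       getp(paste0("dec", i, "b_b")))
        if (i < nd) h <- op_relu(tape, h)
      }
      op_seq_to_out(tape, op_sigmoid(tape, h))
    },
    unet = {
      enc <- list()
      h <- x_id
      L <- length(arch$enc_filters)
      for (i in seq_len(L)) {
        h <- op_relu(tape, op_conv2d(tape, h, getp(paste0("enc", i, "_W")),
                                     getp(paste0("enc", i, "_b")),
                                     stride = c(2L, 2L)))
        enc[[i]] <- h
      }
      for (i in seq_along(arch$dec_filters)) {
        h <- op_upsample2d(tape, h)
        h <- op_relu(tape, op_conv2d(tape, h, getp(paste0("dec", i, "_W")),
                                     getp(paste0("dec", i, "_b"))))
        h <- op_concat_c(tape, h, enc[[L - i]])
      }
      h <- op_upsample2d(tape, h)
      h <- op_relu(tape, op_conv2d(tape, h, getp("final1_W"), getp("final1_b")))
      h <- op_conv2d(tape, h, getp("final2_W"), getp("final2_b"))
      h <- op_sigmoid(tape, h)
      # frequency axis removed only now, after the sigmoid
      op_seq_to_out(tape, op_avgpool_freq(tape, h))
    },
    rnn = {
      h <- x_id
      for (i in seq_along(arch$conv_filters)) {
        h <- op_conv2d(tape, h, getp(paste0("conv", i, "_W")),
                       getp(paste0("conv", i, "_b")))
        h <- op_batchnorm(tape, h, getp(paste0("convbn", i, "_gamma")),
                          getp(paste0("convbn", i, "_beta")),
                          state, paste0("convbn", i), training)
        h <- op_relu(tape, h)
        h <- op_maxpool2d(tape, h)
      }
      h <- op_avgpool_freq(tape, h)
      for (i in seq_along(arch$gru_units)) {
        h <- op_gru(tape, h, getp(paste0("gru", i, "_Wx")),
                    getp(paste0("gru", i, "_Wh")), getp(paste0("gru", i, "_b")))
      }
      h <- op_dropout(tape, h, arch$dropout[1], training)
      h <- op_seq_to_dense(tape, h)  # (B, T)
      for (i in seq_along(arch$dense_units)) {
        h <- op_dense(tape, h, getp(paste0("dense", i, "_W")),
                      getp(paste0("dense", i, "_b")))
        h <- op_batchnorm(tape, h, getp(paste0("densebn", i, "_gamma")),
                          getp(paste0("densebn", i, "_beta")),
                          state, paste0("densebn", i), training)
        h <- op_relu(tape, h)
        h <- op_dropout(tape, h, arch$dropout[1 + i], training)
      }
      h <- op_dense(tape, h, getp("dense_out_W"), getp("dense_out_b"))
      op_transpose(tape, op_sigmoid(tape, h))
    })
}

# Run the model on a batch of chunk matrices without building gradients.
# chunks: list of M x n matrices. Returns an n x B matrix of confidences.
forward_chunks <- function(model, chunks, training = FALSE) {
  B <- length(chunks)
  arch <- model$arch
  x <- array(0, c(arch$M, arch$n, B, 1L))
  for (i in seq_len(B)) x[, , i, 1L] <- chunks[[i]]
  tape <- new_tape(grad = FALSE)
  getp <- function(name) tp_value(tape, model$params[[name]])
  out_id <- model_forward(tape, getp, tp_value(tape, x), model,
                          training = training)
  tp_get(tape, out_id)
}
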
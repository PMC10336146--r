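# Reverse-mode autodiff tape for the segmenter networks.
#
# Values are dense arrays; 2-D feature maps use layout (H, W, B, C)
# (frequency, time, batch, channel), 1-D sequences (T, B, C), dense
# activations (B, F). Convolutions are im2col + BLAS matrix products.
# Every op computes its forward value eagerly and, when gradients are
# enabled, pushes a closure that maps the output gradient to input
# gradients. This is deliberately minimal: just enough machinery for the
# three architectures, and every op is finite-difference checked in the
# test suite.

new_tape <- function(grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$vals <- list()
  e$records <- list()
  e$n <- 0L
  e$grad <- grad
  e
}

tp_value <- function(tape, v) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- v
  tape$n
}

# `force(id)` matters: `id` is often a lazily evaluated op call that
# appends to `tape$vals`, so it must run before the list is indexed.
tp_get <- function(tape, id) {
  force(id)
  tape$vals[[id]]
}

# inputs: integer ids (0 marks a non-differentiable input);
# backward: function(dout) -> list of gradients aligned with inputs.
tp_op <- function(tape, value, inputs, backward) {
  id <- tp_value(tape, value)
  if (tape$grad) {
    tape$records[[length(tape$records) + 1L]] <-
      list(out = id, inputs = as.integer(inputs), fn = backward)
  }
  id
}

tape_backward <- function(tape, loss_id) {
  grads <- vector("list", tape$n)
  grads[[loss_id]] <- 1
  for (rec in rev(tape$records)) {
    dout <- grads[[rec$out]]
    if (is.null(dout)) next
    gs <- rec$fn(dout)
    for (j in seq_along(rec$inputs)) {
      id <- rec$inputs[j]
      if (id > 0L && !is.null(gs[[j]])) {
        grads[[id]] <- if (is.null(grads[[id]])) gs[[j]] else grads[[id]] + gs[[j]]
      }
    }
  }
  grads
}

# ---- elementwise activations -------------------------------------------

op_relu <- function(tape, x) {
  xv <- tp_get(tape, x)
  out <- pmax(xv, 0)
  tp_op(tape, out, x, function(dout) list(dout * (xv > 0)))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-tp_get(tape, x)))
  tp_op(tape, s, x, function(dout) list(dout * s * (1 - s)))
}

# ---- 2-D convolution (same padding) ------------------------------------

# Weight layout: array (C_in, kh, kw, C_out); the im2col patch matrix has
# columns ordered channel-fastest then (ky, kx), matching
# matrix(W, C_in*kh*kw, C_out). Patch assembly/scatter is compiled
# (src/conv_ops.cpp); the products are BLAS calls.
op_conv2d <- function(tape, x, W, b, stride = c(1L, 1L)) {
  xv <- tp_get(tape, x); Wv <- tp_get(tape, W); bv <- tp_get(tape, b)
  d <- dim(xv); H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  dw <- dim(Wv); kh <- dw[2]; kw <- dw[3]; Cout <- dw[4]
  stopifnot(dw[1] == C)
  sh <- stride[1]; sw <- stride[2]
  Hout <- as.integer(ceiling(H / sh)); Wout <- as.integer(ceiling(Wd / sw))
  ph <- max((Hout - 1L) * sh + kh - H, 0L); pw <- max((Wout - 1L) * sw + kw - Wd, 0L)
  pt <- ph %/% 2L; pl <- pw %/% 2L
  if (ph > 0L || pw > 0L) {
    xp <- array(0, c(H + ph, Wd + pw, B, C))
    xp[pt + seq_len(H), pl + seq_len(Wd), , ] <- xv
  } else {
    xp <- xv
  }
  Xc <- cpp_im2col2d(xp, H + ph, Wd + pw, B, C, kh, kw, sh, sw, Hout, Wout)
  Wm <- matrix(Wv, C * kh * kw, Cout)
  Ym <- sweep(Xc %*% Wm, 2, bv, `+`)
  out <- array(Ym, c(Hout, Wout, B, Cout))
  tp_op(tape, out, c(x, W, b), function(dout) {
    dYm <- matrix(dout, Hout * Wout * B, Cout)
    db <- colSums(dYm)
    dWm <- crossprod(Xc, dYm)
    dXc <- dYm %*% t(Wm)
    dxp <- cpp_col2im2d(dXc, H + ph, Wd + pw, B, C, kh, kw, sh, sw,
                        Hout, Wout)
    dx <- if (ph > 0L || pw > 0L) {
      dxp[pt + seq_len(H), pl + seq_len(Wd), , , drop = FALSE]
    } else dxp
    list(dx, array(dWm, dim(Wv)), db)
  })
}

# ---- 1-D convolution (same padding, stride 1) --------------------------

op_conv1d <- function(tape, x, W, b) {
  xv <- tp_get(tape, x); Wv <- tp_get(tape, W); bv <- tp_get(tape, b)
  d <- dim(xv); T_ <- d[1]; B <- d[2]; C <- d[3]
  dw <- dim(Wv); k <- dw[2]; Cout <- dw[3]
  stopifnot(dw[1] == C)
  p <- k - 1L; pt <- p %/% 2L
  xp <- array(0, c(T_ + p, B, C))
  xp[pt + seq_len(T_), , ] <- xv
  Xc <- cpp_im2col1d(xp, T_ + p, B, C, k, T_)
  Wm <- matrix(Wv, C * k, Cout)
  Ym <- sweep(Xc %*% Wm, 2, bv, `+`)
  out <- array(Ym, c(T_, B, Cout))
  tp_op(tape, out, c(x, W, b), function(dout) {
    dYm <- matrix(dout, T_ * B, Cout)
    db <- colSums(dYm)
    dWm <- crossprod(Xc, dYm)
    dXc <- dYm %*% t(Wm)
    dxp <- cpp_col2im1d(dXc, T_ + p, B, C, k, T_)
    list(dxp[pt + seq_len(T_), , , drop = FALSE], array(dWm, dim(Wv)), db)
  })
}

# ---- pooling / resampling ----------------------------------------------

op_maxpool2d <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  pooled <- cpp_maxpool2d(xv, H, W, d[3], d[4])
  tp_op(tape, pooled$out, x, function(dout) {
    list(cpp_maxpool2d_backward(dout, pooled$which, H, W, d[3], d[4]))
  })
}

# Mean over the frequency axis: (H, W, B, C) -> (W, B, C).
op_avgpool_freq <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv); H <- d[1]
  out <- array(colMeans(matrix(xv, H, prod(d[-1]))), d[-1])
  tp_op(tape, out, x, function(dout) {
    list(array(rep(as.vector(dout) / H, each = H), d))
  })
}

op_upsample1d <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv); T_ <- d[1]
  out <- xv[rep(seq_len(T_), each = 2L), , , drop = FALSE]
  tp_op(tape, out, x, function(dout) {
    list(dout[seq(1L, 2L * T_, 2L), , , drop = FALSE] +
           dout[seq(2L, 2L * T_, 2L), , , drop = FALSE])
  })
}

op_upsample2d <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv); H <- d[1]; W <- d[2]
  out <- xv[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , ,
            drop = FALSE]
  tp_op(tape, out, x, function(dout) {
    ro <- seq(1L, 2L * H, 2L); re <- seq(2L, 2L * H, 2L)
    co <- seq(1L, 2L * W, 2L); ce <- seq(2L, 2L * W, 2L)
    list(dout[ro, co, , , drop = FALSE] + dout[re, co, , , drop = FALSE] +
           dout[ro, ce, , , drop = FALSE] + dout[re, ce, , , drop = FALSE])
  })
}

# Concatenate two 4-D maps along the channel axis.
op_concat_c <- function(tape, a, b) {
  av <- tp_get(tape, a); bv <- tp_get(tape, b)
  da <- dim(av); db_ <- dim(bv)
  stopifnot(all(da[1:3] == db_[1:3]))
  out <- array(0, c(da[1:3], da[4] + db_[4]))
  out[, , , seq_len(da[4])] <- av
  out[, , , da[4] + seq_len(db_[4])] <- bv
  tp_op(tape, out, c(a, b), function(dout) {
    list(dout[, , , seq_len(da[4]), drop = FALSE],
         dout[, , , da[4] + seq_len(db_[4]), drop = FALSE])
  })
}

# ---- dense / reshape ----------------------------------------------------

op_dense <- function(tape, x, W, b) {
  xv <- tp_get(tape, x); Wv <- tp_get(tape, W); bv <- tp_get(tape, b)
  out <- sweep(xv %*% Wv, 2, bv, `+`)
  tp_op(tape, out, c(x, W, b), function(dout) {
    list(dout %*% t(Wv), crossprod(xv, dout), colSums(dout))
  })
}

# (T, B, 1) sequence -> (B, T) matrix.
op_seq_to_dense <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv)
  stopifnot(d[3] == 1L)
  out <- t(array(xv, d[1:2]))
  tp_op(tape, out, x, function(dout) list(array(t(dout), d)))
}

# (B, T) matrix -> (T, B) output layout.
op_transpose <- function(tape, x) {
  xv <- tp_get(tape, x)
  tp_op(tape, t(xv), x, function(dout) list(t(dout)))
}

# (T, B, 1) sequence -> (T, B) output layout.
op_seq_to_out <- function(tape, x) {
  xv <- tp_get(tape, x)
  d <- dim(xv)
  stopifnot(d[3] == 1L)
  out <- array(xv, d[1:2])
  tp_op(tape, out, x, function(dout) list(array(dout, d)))
}

# ---- batch normalization -------------------------------------------------

# Normalizes over all axes except the last (channel/feature) one.
# Running statistics live in `state[[name]]`; `training` switches between
# batch statistics (with running update) and stored statistics.
op_batchnorm <- function(tape, x, gamma, beta, state, name, training,
                         momentum = 0.9, eps = 1e-5) {
  xv <- tp_get(tape, x); gv <- tp_get(tape, gamma); bv <- tp_get(tape, beta)
  d <- dim(xv); C <- d[length(d)]; m <- prod(d) / C
  xm <- matrix(xv, m, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    st <- state[[name]]
    if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[name]] <- list(mean = momentum * st$mean + (1 - momentum) * mu,
                          var = momentum * st$var + (1 - momentum) * v)
  } else {
    st <- state[[name]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    mu <- st$mean; v <- st$var
  }
  sd_ <- sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sd_, `/`)
  out <- array(sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`), d)
  tp_op(tape, out, c(x, gamma, beta), function(dout) {
    dm <- matrix(dout, m, C)
    dgamma <- colSums(dm * xhat)
    dbeta <- colSums(dm)
    dxhat <- sweep(dm, 2, gv, `*`)
    if (training) {
      dx <- sweep(dxhat * m - matrix(colSums(dxhat), m, C, byrow = TRUE) -
                    xhat * matrix(colSums(dxhat * xhat), m, C, byrow = TRUE),
                  2, m * sd_, `/`)
    } else {
      dx <- sweep(dxhat, 2, sd_, `/`)
    }
    list(array(dx, d), dgamma, dbeta)
  })
}

op_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- tp_get(tape, x)
  mask <- (stats::runif(length(xv)) >= rate) / (1 - rate)
  out <- xv * mask
  if (!is.null(dim(xv))) dim(out) <- dim(xv)
  tp_op(tape, out, x, function(dout) list(dout * mask))
}

# ---- GRU -----------------------------------------------------------------

# x: (T, B, Cin); Wx: (Cin, 3U); Wh: (U, 3U); b: (3U). Gate order z, r, h.
op_gru <- function(tape, x, Wx, Wh, b) {
  xv <- tp_get(tape, x); Wxv <- tp_get(tape, Wx)
  Whv <- tp_get(tape, Wh); bv <- tp_get(tape, b)
  d <- dim(xv); T_ <- d[1]; B <- d[2]; Cin <- d[3]
  U <- ncol(Whv) %/% 3L
  iz <- seq_len(U); ir <- U + iz; ih <- 2L * U + iz
  h <- matrix(0, B, U)
  out <- array(0, c(T_, B, U))
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(xv[t, , ], B, Cin)
    a <- xt %*% Wxv + h %*% Whv  # pre-activations; h-gate fixed below
    z <- 1 / (1 + exp(-sweep(a[, iz, drop = FALSE], 2, bv[iz], `+`)))
    r <- 1 / (1 + exp(-sweep(a[, ir, drop = FALSE], 2, bv[ir], `+`)))
    rh <- r * h
    # candidate uses the reset-gated state, not the raw recurrence in `a`
    ah <- sweep(xt %*% Wxv[, ih, drop = FALSE] + rh %*% Whv[, ih, drop = FALSE],
                2, bv[ih], `+`)
    hh <- tanh(ah)
    h_new <- (1 - z) * h + z * hh
    cache[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, hh = hh, rh = rh)
    h <- h_new
    out[t, , ] <- h
  }
  tp_op(tape, out, c(x, Wx, Wh, b), function(dout) {
    dWx <- array(0, dim(Wxv)); dWh <- array(0, dim(Whv)); db <- numeric(3L * U)
    dx <- array(0, d)
    dh <- matrix(0, B, U)
    Whz <- Whv[, iz, drop = FALSE]; Whr <- Whv[, ir, drop = FALSE]
    Whh <- Whv[, ih, drop = FALSE]
    Wxz <- Wxv[, iz, drop = FALSE]; Wxr <- Wxv[, ir, drop = FALSE]
    Wxh <- Wxv[, ih, drop = FALSE]
    for (t in rev(seq_len(T_))) {
      cc <- cache[[t]]
      dh <- dh + matrix(dout[t, , ], B, U)
      dhh <- dh * cc$z
      dz <- dh * (cc$hh - cc$h_prev)
      dh_prev <- dh * (1 - cc$z)
      dah <- dhh * (1 - cc$hh^2)
      dWx[, ih] <- dWx[, ih] + crossprod(cc$xt, dah)
      dWh[, ih] <- dWh[, ih] + crossprod(cc$rh, dah)
      db[ih] <- db[ih] + colSums(dah)
      drh <- dah %*% t(Whh)
      dr <- drh * cc$h_prev
      dh_prev <- dh_prev + drh * cc$r
      daz <- dz * cc$z * (1 - cc$z)
      dWx[, iz] <- dWx[, iz] + crossprod(cc$xt, daz)
      dWh[, iz] <- dWh[, iz] + crossprod(cc$h_prev, daz)
      db[iz] <- db[iz] + colSums(daz)
      dh_prev <- dh_prev + daz %*% t(Whz)
      dar <- dr * cc$r * (1 - cc$r)
      dWx[, ir] <- dWx[, ir] + crossprod(cc$xt, dar)
      dWh[, ir] <- dWh[, ir] + crossprod(cc$h_prev, dar)
      db[ir] <- db[ir] + colSums(dar)
      dh_prev <- dh_prev + dar %*% t(Whr)
      dx[t, , ] <- daz %*% t(Wxz) + dar %*% t(Wxr) + dah %*% t(Wxh)
      dh <- dh_prev
    }
    list(dx, dWx, dWh, db)
  })
}

# ---- loss ----------------------------------------------------------------

# Mean binary cross-entropy on probabilities (clipped for stability).
op_bce_probs <- function(tape, p, target, eps = 1e-7) {
  pv <- tp_get(tape, p)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pc)
  loss <- -sum(target * log(pc) + (1 - target) * log(1 - pc)) / n
  tp_op(tape, loss, p, function(dout) {
    g <- dout * (pc - target) / (pc * (1 - pc)) / n
    g[pv < eps | pv > 1 - eps] <- 0
    if (!is.null(dim(pv))) dim(g) <- dim(pv)
    list(g)
  })
}
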
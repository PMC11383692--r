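# Internal machinery of the count-regression network.
#
# Architecture: optional 2x average-pooling stem, then `n_stages` blocks of
# (3x3 convolution, stride 2, zero pad 1) + ReLU, then global average pooling
# and a fully connected layer with a single output neuron. The convolution
# forward/backward runs in C++ (src/conv_ops.cpp); orchestration, ReLU, GAP,
# the head and Adam live here. All tensors are double precision; weights for
# a conv layer are a Cout x (9 * Cin) matrix whose row layout matches the C++
# im2col (channel outer, kernel column, kernel row).

nn_init_params <- function(backbone, seed) {
  withr::with_seed(seed, {
    chans <- c(1L, backbone$channels)
    k <- backbone$kernel
    conv <- purrr::map(seq_len(backbone$n_stages), function(l) {
      fan_in <- k * k * chans[l]
      list(
        w = matrix(rnorm(chans[l + 1] * fan_in, sd = sqrt(2 / fan_in)),
          nrow = chans[l + 1]
        ),
        b = rep(0, chans[l + 1])
      )
    })
    cf <- backbone$channels[backbone$n_stages]
    head <- list(w = rnorm(cf, sd = 1 / sqrt(cf)), b = 0)
    list(conv = conv, head = head)
  })
}

nn_n_params <- function(params) {
  sum(purrr::map_int(params$conv, ~ length(.x$w) + length(.x$b))) +
    length(params$head$w) + 1L
}

# 2x2 average pooling, repeated log2(factor) times. Assumes even dims.
avg_pool2 <- function(m, factor) {
  while (factor > 1) {
    h <- nrow(m)
    w <- ncol(m)
    m <- (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
      m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
    factor <- factor / 2
  }
  m
}

# Forward pass on one tile (H x W matrix of 0..255 intensities).
# Returns the raw scalar and, when keep_cache, everything backward needs.
nn_forward <- function(params, tile, backbone, input_spec, keep_cache = FALSE) {
  x <- (unclass(tile) - input_spec$offset) / input_spec$scale
  if (backbone$stem_pool > 1) x <- avg_pool2(x, backbone$stem_pool)
  a <- array(x, dim = c(nrow(x), ncol(x), 1L))
  inputs <- if (keep_cache) vector("list", backbone$n_stages) else NULL
  pre <- if (keep_cache) vector("list", backbone$n_stages) else NULL
  for (l in seq_len(backbone$n_stages)) {
    if (keep_cache) inputs[[l]] <- a
    z <- nn_conv_fwd(
      a, params$conv[[l]]$w, params$conv[[l]]$b,
      backbone$kernel, backbone$stride, backbone$pad
    )
    if (keep_cache) pre[[l]] <- z
    a <- z
    a[a < 0] <- 0
  }
  g <- apply(a, 3L, mean)
  pred <- sum(params$head$w * g) + params$head$b
  if (!keep_cache) {
    return(list(pred = pred))
  }
  list(pred = pred, g = g, inputs = inputs, pre = pre, final = a)
}

# Backward pass for d(loss)/d(pred) = dpred; returns gradients shaped like
# the parameter list.
nn_backward <- function(params, fwd, dpred, backbone) {
  gr <- list(
    conv = purrr::map(params$conv, ~ list(w = .x$w * 0, b = .x$b * 0)),
    head = list(w = dpred * fwd$g, b = dpred)
  )
  dims <- dim(fwd$final)
  hw <- dims[1] * dims[2]
  dgap <- dpred * params$head$w
  da <- array(rep(dgap, each = hw) / hw, dim = dims)
  for (l in rev(seq_len(backbone$n_stages))) {
    dz <- da * (fwd$pre[[l]] > 0)
    bw <- nn_conv_bwd(
      fwd$inputs[[l]], params$conv[[l]]$w, dz,
      backbone$kernel, backbone$stride, backbone$pad
    )
    gr$conv[[l]]$w <- bw$dw
    gr$conv[[l]]$b <- as.numeric(bw$db)
    da <- bw$dx
  }
  gr
}

nn_grad_zero <- function(params) {
  list(
    conv = purrr::map(params$conv, ~ list(w = .x$w * 0, b = .x$b * 0)),
    head = list(w = params$head$w * 0, b = 0)
  )
}

nn_grad_add <- function(acc, gr) {
  for (l in seq_along(acc$conv)) {
    acc$conv[[l]]$w <- acc$conv[[l]]$w + gr$conv[[l]]$w
    acc$conv[[l]]$b <- acc$conv[[l]]$b + gr$conv[[l]]$b
  }
  acc$head$w <- acc$head$w + gr$head$w
  acc$head$b <- acc$head$b + gr$head$b
  acc
}

adam_init <- function(params) {
  zero <- nn_grad_zero(params)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$conv)) {
    uw <- upd(
      params$conv[[l]]$w, grads$conv[[l]]$w,
      state$m$conv[[l]]$w, state$v$conv[[l]]$w
    )
    params$conv[[l]]$w <- uw$p
    state$m$conv[[l]]$w <- uw$m
    state$v$conv[[l]]$w <- uw$v
    ub <- upd(
      params$conv[[l]]$b, grads$conv[[l]]$b,
      state$m$conv[[l]]$b, state$v$conv[[l]]$b
    )
    params$conv[[l]]$b <- ub$p
    state$m$conv[[l]]$b <- ub$m
    state$v$conv[[l]]$b <- ub$v
  }
  uw <- upd(params$head$w, grads$head$w, state$m$head$w, state$v$head$w)
  params$head$w <- uw$p
  state$m$head$w <- uw$m
  state$v$head$w <- uw$v
  ub <- upd(params$head$b, grads$head$b, state$m$head$b, state$v$head$b)
  params$head$b <- ub$p
  state$m$head$b <- ub$m
  state$v$head$b <- ub$v
  list(params = params, state = state)
}

# Count-preserving augmentation: one of the 8 dihedral orientations.
orient_tile <- function(m, o) {
  if (o >= 4L) m <- t(m)
  o <- o %% 4L
  if (o == 1L) m <- m[nrow(m):1, , drop = FALSE]
  if (o == 2L) m <- m[nrow(m):1, ncol(m):1, drop = FALSE]
  if (o == 3L) m <- m[, ncol(m):1, drop = FALSE]
  m
}
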
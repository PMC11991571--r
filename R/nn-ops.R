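# Differentiable tensor operations used by the Wave-Net graph.
# All 4-D activations have dim (H, W, C, N).

dims4 <- function(x) {
  d <- dim(x$value)
  stopifnot(length(d) == 4L)
  d
}

# depthwise 3x3 convolution, zero padding 1
op_dwconv3 <- function(x, w, b) {
  d <- dims4(x)
  y <- cpp_dwconv3_fwd(x$value, w$value, b$value, d[1], d[2], d[3], d[4])
  make_op(y, list(x, w, b), function(g) {
    r <- cpp_dwconv3_bwd(x$value, w$value, g, d[1], d[2], d[3], d[4])
    list(r$gx, r$gw, r$gb)
  })
}

# pointwise 1x1 convolution (channel projection)
op_conv1x1 <- function(x, w, b) {
  d <- dims4(x)
  y <- cpp_conv1x1_fwd(x$value, w$value, b$value, d[1], d[2], d[3], d[4])
  make_op(y, list(x, w, b), function(g) {
    r <- cpp_conv1x1_bwd(x$value, w$value, g, d[1], d[2], d[3], d[4])
    list(r$gx, r$gw, r$gb)
  })
}

# batch normalization; `state` carries running statistics across calls
op_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  d <- dims4(x)
  if (training) {
    r <- cpp_bn_fwd(x$value, gamma$value, beta$value, eps, d[1], d[2], d[3], d[4])
    m <- prod(d[c(1, 2, 4)])
    unbiased <- if (m > 1) r$var * m / (m - 1) else r$var
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * r$mean
    state$running_var <- (1 - momentum) * state$running_var + momentum * unbiased
    make_op(r$y, list(x, gamma, beta), function(g) {
      b <- cpp_bn_bwd(g, x$value, r$mean, r$invstd, gamma$value,
                      d[1], d[2], d[3], d[4])
      list(b$gx, b$ggamma, b$gbeta)
    })
  } else {
    invstd <- 1 / sqrt(state$running_var + eps)
    scale <- gamma$value * invstd
    shift <- beta$value - state$running_mean * scale
    y <- sweep(sweep(x$value, 3, scale, "*"), 3, shift, "+")
    make_op(y, list(x, gamma, beta), function(g) {
      xhat <- sweep(sweep(x$value, 3, state$running_mean, "-"), 3, invstd, "*")
      list(sweep(g, 3, scale, "*"),
           as.numeric(apply(g * xhat, 3, sum)),
           as.numeric(apply(g, 3, sum)))
    })
  }
}

op_silu <- function(x) {
  r <- cpp_silu_fwd(x$value)
  make_op(r$y, list(x),
          function(g) list(cpp_silu_bwd(x$value, r$s, g)))
}

op_sigmoid <- function(x) {
  s <- cpp_sigmoid_fwd(x$value)
  make_op(s, list(x), function(g) list(g * s * (1 - s)))
}

op_maxpool2 <- function(x) {
  d <- dims4(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("max-pooling requires even spatial dimensions, got ",
         d[1], "x", d[2])
  r <- cpp_maxpool2_fwd(x$value, d[1], d[2], d[3], d[4])
  make_op(r$y, list(x), function(g) {
    list(cpp_maxpool2_bwd(r$idx, g, d[1], d[2], d[3], d[4]))
  })
}

op_upsample2 <- function(x) {
  d <- dims4(x)
  y <- cpp_upsample2_fwd(x$value, d[1], d[2], d[3], d[4])
  make_op(y, list(x), function(g) {
    list(cpp_upsample2_bwd(g, d[1], d[2], d[3], d[4]))
  })
}

op_add <- function(a, b) {
  make_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

# concatenate a list of tensors along the channel axis
op_concat <- function(ts) {
  dl <- lapply(ts, dims4)
  H <- dl[[1]][1]; W <- dl[[1]][2]; N <- dl[[1]][4]
  cs <- vapply(dl, function(d) d[3], numeric(1))
  y <- array(0, c(H, W, sum(cs), N))
  at <- 0L
  for (k in seq_along(ts)) {
    y[, , at + seq_len(cs[k]), ] <- ts[[k]]$value
    at <- at + cs[k]
  }
  make_op(y, ts, function(g) {
    out <- vector("list", length(ts))
    at <- 0L
    for (k in seq_along(ts)) {
      out[[k]] <- g[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    out
  })
}

# pixel-mean binary cross entropy against a fixed {0,1} target array;
# probabilities clamped to [eps, 1 - eps] before the logarithm
op_bce_mean <- function(p, target, eps = 1e-7) {
  if (!all(dim(p$value) == dim(target)))
    stop("prediction and target shapes differ: ",
         paste(dim(p$value), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  pc <- pmin(pmax(p$value, eps), 1 - eps)
  m <- length(pc)
  val <- -sum(target * log(pc) + (1 - target) * log(1 - pc)) / m
  make_op(val, list(p), function(g) {
    inside <- (p$value >= eps) & (p$value <= 1 - eps)
    dp <- (-target / pc + (1 - target) / (1 - pc)) / m
    list(g * dp * inside)
  })
}

op_sum_scalars <- function(ts) {
  val <- sum(vapply(ts, function(t) t$value, numeric(1)))
  make_op(val, ts, function(g) rep(list(g), length(ts)))
}
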
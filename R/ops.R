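# Differentiable ops on (H, W, C, N) activation nodes. Each op computes its
# value through the compiled kernels and registers a backward closure on the
# tape when gradients are being recorded.

op_conv <- function(x, W, b, k, pad = k %/% 2L) {
  x <- as_node(x)
  req <- x$req || W$req || b$req
  keep <- .ag$recording && req
  r <- cpp_conv2d_fwd(x$v, W$v, b$v, k, pad, keep_col = keep)
  ag_node(r$y, req, function(g) {
    gr <- cpp_conv2d_bwd(x$v, W$v, g, k, pad, col_cache = r$col,
                         need_dx = x$req)
    r$col <- NULL  # release the cached im2col buffer
    ag_accum(W, gr$dW)
    ag_accum(b, gr$db)
    if (x$req) ag_accum(x, gr$dx)
  })
}

# Batch normalization, training mode (batch statistics). `state` is a list
# environment with running `mean`/`var`, updated in place with momentum.
op_bn_train <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5) {
  r <- cpp_bn_fwd(x$v, gamma$v, beta$v, eps)
  state$mean <- (1 - momentum) * state$mean + momentum * r$mean
  state$var <- (1 - momentum) * state$var + momentum * r$var
  req <- x$req || gamma$req || beta$req
  ag_node(r$y, req, function(g) {
    gr <- cpp_bn_bwd(x$v, gamma$v, g, r$mean, r$invstd)
    ag_accum(gamma, gr$dgamma)
    ag_accum(beta, gr$dbeta)
    ag_accum(x, gr$dx)
  })
}

op_bn_eval <- function(x, gamma, beta, state, eps = 1e-5) {
  x <- as_node(x)
  ag_leaf(cpp_bn_eval(x$v, gamma$v, beta$v, state$mean, state$var, eps))
}

op_relu <- function(x) {
  v <- cpp_relu_fwd(x$v)
  ag_node(v, x$req, function(g) ag_accum(x, cpp_relu_bwd(x$v, g)))
}

op_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$v))
  ag_node(v, x$req, function(g) ag_accum(x, g * v * (1 - v)))
}

op_add <- function(a, b) {
  v <- a$v + b$v
  ag_node(v, a$req || b$req, function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

# x * alpha with alpha a single-channel (H, W, 1, N) map.
op_mulb <- function(x, alpha) {
  v <- cpp_mulb_fwd(x$v, alpha$v)
  ag_node(v, x$req || alpha$req, function(g) {
    gr <- cpp_mulb_bwd(x$v, alpha$v, g)
    ag_accum(x, gr$dx)
    ag_accum(alpha, gr$da)
  })
}

op_concat <- function(xs) {
  v <- cpp_concat_c(lapply(xs, function(x) x$v))
  cs <- vapply(xs, function(x) dim(x$v)[3L], integer(1))
  off <- cumsum(c(0L, cs))
  ag_node(v, any(vapply(xs, function(x) x$req, logical(1))), function(g) {
    for (t in seq_along(xs)) {
      idx <- (off[t] + 1L):off[t + 1L]
      ag_accum(xs[[t]], g[, , idx, , drop = FALSE])
    }
  })
}

op_maxpool2 <- function(x) {
  r <- cpp_maxpool2_fwd(x$v)
  dims <- dim(x$v)
  ag_node(r$y, x$req, function(g) {
    ag_accum(x, cpp_maxpool2_bwd(g, r$idx, dims))
  })
}

op_upsample2 <- function(x) {
  x <- as_node(x)
  dims <- dim(x$v)
  v <- cpp_upsample2_fwd(x$v)
  ag_node(v, x$req, function(g) ag_accum(x, cpp_upsample2_bwd(g, dims)))
}

# Repeated 2x upsampling until the spatial side reaches `side` (power of 2
# ratio only, which is all the decoder pyramid needs).
op_upsample_to <- function(x, side) {
  while (dim(x$v)[1L] < side) x <- op_upsample2(x)
  x
}

op_sum_scalars <- function(xs) {
  v <- sum(vapply(xs, function(x) x$v, numeric(1)))
  ag_node(v, any(vapply(xs, function(x) x$req, logical(1))), function(g) {
    for (x in xs) ag_accum(x, g)
  })
}
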
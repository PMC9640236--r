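# The layer kernels against double-precision references and finite
# differences. Convolutions accumulate in single precision, so comparisons
# against double references use fp32-scale tolerances; the double-precision
# ops use much tighter ones.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution matches a direct sliding-window reference", {
  set.seed(2)
  H <- 5L; W <- 6L; Cin <- 3L; Cout <- 2L; N <- 2L; k <- 3L; pad <- 1L
  x <- array(rnorm(H * W * Cin * N), c(H, W, Cin, N))
  Wm <- matrix(rnorm(k * k * Cin * Cout, sd = 0.3), k * k * Cin, Cout)
  b <- rnorm(Cout)
  ref_conv <- function(x, Wm, b) {
    y <- array(0, c(H, W, Cout, N))
    for (n in 1:N) for (co in 1:Cout) for (h in 1:H) for (w in 1:W) {
      acc <- b[co]
      for (c in 1:Cin) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
        hi <- h + dy - pad; wi <- w + dx - pad
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[hi, wi, c, n] * Wm[dx + k * (dy + k * (c - 1)) + 1, co]
      }
      y[h, w, co, n] <- acc
    }
    y
  }
  yref <- ref_conv(x, Wm, b)
  ycpp <- mmanet:::cpp_conv2d_fwd(x, Wm, b, k, pad)$y
  expect_lt(max(abs(yref - ycpp)), 1e-5)

  wt <- array(rnorm(length(yref)), dim(yref))
  gr <- mmanet:::cpp_conv2d_bwd(x, Wm, wt, k, pad)
  gx <- num_grad(function(v) sum(ref_conv(array(v, dim(x)), Wm, b) * wt), x)
  gW <- num_grad(function(v) sum(ref_conv(x, matrix(v, nrow(Wm)), b) * wt),
                 Wm)
  expect_lt(max(abs(gr$dx - gx)), 1e-4)
  expect_lt(max(abs(gr$dW - gW)), 1e-4)
})

test_that("batchnorm, pooling, upsampling and gating pass finite-difference checks", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  wt <- array(rnorm(length(x)), dim(x))
  gm <- rnorm(3) + 1; bt <- rnorm(3)

  r <- mmanet:::cpp_bn_fwd(x, gm, bt, 1e-5)
  gr <- mmanet:::cpp_bn_bwd(x, gm, wt, r$mean, r$invstd)
  gx <- num_grad(function(v) sum(mmanet:::cpp_bn_fwd(array(v, dim(x)), gm,
                                                     bt, 1e-5)$y * wt), x)
  expect_lt(max(abs(gr$dx - gx)), 1e-6)
  gg <- num_grad(function(v) sum(mmanet:::cpp_bn_fwd(x, v, bt, 1e-5)$y * wt),
                 gm)
  expect_lt(max(abs(gr$dgamma - gg)), 1e-6)

  wu <- array(rnorm(10 * 10 * 3 * 2), c(10, 10, 3, 2))
  gu <- mmanet:::cpp_upsample2_bwd(wu, dim(x))
  gx <- num_grad(function(v)
    sum(mmanet:::cpp_upsample2_fwd(array(v, dim(x))) * wu), x)
  expect_lt(max(abs(gu - gx)), 1e-6)

  x6 <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w6 <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  r6 <- mmanet:::cpp_maxpool2_fwd(x6)
  g6 <- mmanet:::cpp_maxpool2_bwd(w6, r6$idx, dim(x6))
  gx <- num_grad(function(v)
    sum(mmanet:::cpp_maxpool2_fwd(array(v, dim(x6)))$y * w6), x6)
  expect_lt(max(abs(g6 - gx)), 1e-6)

  a <- array(runif(5 * 5 * 2), c(5, 5, 1, 2))
  rb <- mmanet:::cpp_mulb_bwd(x, a, wt)
  gx <- num_grad(function(v)
    sum(mmanet:::cpp_mulb_fwd(array(v, dim(x)), a) * wt), x)
  ga <- num_grad(function(v)
    sum(mmanet:::cpp_mulb_fwd(x, array(v, dim(a))) * wt), a)
  expect_lt(max(abs(rb$dx - gx)), 1e-6)
  expect_lt(max(abs(rb$da - ga)), 1e-6)
})

test_that("loss nodes have exact analytic gradients", {
  set.seed(4)
  q <- array(runif(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  G <- array(rbinom(length(q), 1, 0.4), dim(q))
  for (op in c("bce", "dice")) {
    mmanet:::ag_record_on()
    qn <- mmanet:::ag_leaf(q)
    qn$req <- TRUE
    loss <- if (op == "bce") mmanet:::op_bce_loss(qn, G, 1e-7)
            else mmanet:::op_dice_loss(qn, G, 1.0)
    mmanet:::ag_backward(loss)
    got <- qn$g
    mmanet:::ag_record_off()
    f <- if (op == "bce") function(v) bce_loss(array(v, dim(q)), G)
         else function(v) dice_loss(array(v, dim(q)), G)
    expect_lt(max(abs(got - num_grad(f, q, eps = 1e-6))), 1e-6)
  }
})

test_that("bilinear 2x upsampling preserves constants and doubles sides", {
  x <- array(2.5, c(4, 6, 1, 1))
  y <- mmanet:::cpp_upsample2_fwd(x)
  expect_equal(dim(y), c(8L, 12L, 1L, 1L))
  expect_true(all(y == 2.5))
  expect_equal(dim(upsample2x(upsample2x(matrix(0, 3, 3)))), c(12L, 12L))
})
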
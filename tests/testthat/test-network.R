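# Architecture contracts: stage geometry, head pyramid, attention
# coefficient ranges, branch independence, building-block semantics.

test_that("encoder stages halve sides and scale channels with the width multiplier", {
  cfg <- slim_config()
  expect_identical(cfg$stage_channels, c(8L, 16L, 32L, 64L, 64L))
  net <- mma_net(cfg, seed = 1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  fe <- mmanet:::enc_forward(net, "e1", mmanet:::ag_leaf(x), training = FALSE)
  expect_equal(vapply(fe, function(f) dim(f$v)[1], numeric(1)),
               c(64, 32, 16, 8, 4))
  expect_equal(vapply(fe, function(f) dim(f$v)[3], numeric(1)),
               c(8, 16, 32, 64, 64))
  xh <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  fh <- mmanet:::enc_forward(net, "e2", mmanet:::ag_leaf(xh), training = FALSE)
  expect_equal(vapply(fh, function(f) dim(f$v)[1], numeric(1)),
               c(32, 16, 8, 4, 2))
})

test_that("the two branches share no parameters", {
  net <- mma_net(slim_config(), seed = 1)
  e1 <- grep("^e1\\.", names(net$params), value = TRUE)
  e2 <- grep("^e2\\.", names(net$params), value = TRUE)
  expect_gt(length(e1), 0)
  expect_length(intersect(e1, e2), 0)
  # perturbing a branch-2 weight leaves branch-1 features untouched
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  f_before <- mmanet:::enc_forward(net, "e1", mmanet:::ag_leaf(x), FALSE)
  net$params[["e2.s1.c1.W"]]$v <- net$params[["e2.s1.c1.W"]]$v * 2
  f_after <- mmanet:::enc_forward(net, "e1", mmanet:::ag_leaf(x), FALSE)
  expect_identical(f_before[[5]]$v, f_after[[5]]$v)
})

test_that("the decoder yields the seven-head pyramid at the contracted sides", {
  for (side in c(64L, 96L)) {
    cfg <- net_config(input_side = side, num_classes = 3,
                      width_multiplier = 1 / 8)
    net <- mma_net(cfg, seed = 2)
    xf <- array(rnorm(side * side * 2), c(side, side, 1, 2))
    xh <- array(rnorm(side * side / 2), c(side / 2, side / 2, 1, 2))
    fw <- mma_forward(net, xf, xh, training = TRUE)
    expect_length(fw$heads, 7L)
    got <- vapply(fw$heads, function(h) dim(h$v)[1], numeric(1))
    expect_equal(unname(got),
                 c(side, side / 2, side / 4, side / 8,
                   side / 2, side / 4, side / 8))
    expect_true(all(vapply(fw$heads, function(h) dim(h$v)[3] == 3,
                           logical(1))))
    for (a in fw$alphas) expect_true(all(a$v >= 0 & a$v <= 1))
    for (h in fw$heads) expect_true(all(h$v >= 0 & h$v <= 1))
  }
})

test_that("a single-branch network decodes through skip connections only", {
  cfg <- slim_config(num_branches = 1L)
  net <- mma_net(cfg, seed = 3)
  xf <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  fw <- mma_forward(net, xf, training = TRUE)
  expect_length(fw$heads, 4L)
  expect_equal(unname(vapply(fw$heads, function(h) dim(h$v)[1], numeric(1))),
               c(64, 32, 16, 8))
  expect_length(grep("^(e2|ag|fb)\\.", names(net$params)), 0)
})

test_that("invalid configurations and input sizes are rejected", {
  expect_error(net_config(input_side = 100), "divisible by 32")
  expect_error(net_config(stage_channels = c(8, 16)), "length 5")
  expect_error(net_config(num_branches = 3), "1 or 2")
  net <- mma_net(slim_config(), seed = 1)
  expect_error(mma_forward(net, array(0, c(32, 32, 1, 1)),
                           array(0, c(16, 16, 1, 1))), "64x64")
  expect_error(mma_forward(net, array(0, c(64, 64, 1, 1)),
                           array(0, c(16, 16, 1, 1))), "32x32")
})

test_that("attention gating scales features monotonically through alpha", {
  g <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  l <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  r <- attention_gate(g, l, seed = 3)
  expect_true(all(r$alpha >= 0 & r$alpha <= 1))
  one <- attention_gate(g, l, module = r$module,
                        alpha_override = array(1, c(8, 8, 1)))
  expect_equal(one$output[, , , 1], l)
  zero <- attention_gate(g, l, module = r$module,
                         alpha_override = array(0, c(8, 8, 1)))
  expect_true(all(zero$output == 0))
  # gated contribution shrinks monotonically as alpha decreases
  norms <- vapply(c(1, 0.5, 0.1, 0), function(a) {
    sum(abs(attention_gate(g, l, module = r$module,
                           alpha_override = array(a, c(8, 8, 1)))$output))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_error(attention_gate(array(0, c(4, 4, 2)), array(0, c(8, 8, 2))),
               "spatial")
})

test_that("attention feature selection reduces to plain fusion when alpha is forced to 1", {
  comp <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  enc <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  a <- attention_feature_selection(comp, enc, out_channels = 4, seed = 5)
  expect_true(all(a$alpha >= 0 & a$alpha <= 1))
  expect_equal(dim(a$output), c(8L, 8L, 4L, 1L))
  forced <- attention_feature_selection(comp, enc, out_channels = 4,
                                        module = a$module, seed = 5,
                                        alpha_override = array(1, c(8, 8, 1)))
  fused <- feature_fusion(list(comp, enc), module = a$module, seed = 5)
  expect_equal(forced$output, fused$output, tolerance = 1e-12)
  for (side in c(28L, 56L)) {
    r <- attention_feature_selection(array(rnorm(side^2 * 2), c(side, side, 2)),
                                     array(rnorm(side^2 * 2), c(side, side, 2)),
                                     seed = 1)
    expect_equal(dim(r$output)[1:2], c(side, side))
  }
})

test_that("feature fusion keeps a single input's channel width", {
  x <- array(rnorm(14 * 14 * 8), c(14, 14, 8))
  f2 <- feature_fusion(list(x, x), seed = 1)
  expect_equal(dim(f2$output), c(14L, 14L, 8L, 1L))
  f3 <- feature_fusion(list(x, x, x), seed = 1)
  expect_equal(dim(f3$output), c(14L, 14L, 8L, 1L))
  expect_error(feature_fusion(list(x, array(0, c(14, 14, 4)))), "channel")
  expect_error(feature_fusion(list(x, array(0, c(7, 7, 8)))), "spatial")
})

test_that("every parameter of both branches and the decoder receives gradient", {
  cfg <- slim_config()
  net <- mma_net(cfg, seed = 4)
  set.seed(5)
  xf <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  xh <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  mk <- array(sample(0:3, 64 * 64 * 2, TRUE), c(64, 64, 2))
  labels <- build_label_pyramid(mk, 3, head_sides(cfg))
  mmanet:::ag_record_on()
  fw <- mma_forward(net, xf, xh, training = TRUE)
  loss <- mmanet:::op_total_loss(fw$heads, labels, "MLDS", 1e-7, 1)
  mmanet:::ag_backward(loss)
  gmax <- vapply(net$params, function(p)
    if (is.null(p$g)) 0 else max(abs(p$g)), numeric(1))
  mmanet:::ag_record_off()
  expect_true(all(gmax > 0))
})
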
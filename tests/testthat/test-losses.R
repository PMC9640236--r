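# Supervision: label pyramids, BCE/Dice closed forms and loop oracles,
# total-loss composition in both supervision modes.

test_that("label pyramids are exact at full scale and nearest-neighbour below", {
  mk <- matrix(0L, 4, 4)
  mk[1:2, 1:2] <- 1L
  lp <- build_label_pyramid(mk, 1L, c(4L, 2L))
  expect_identical(lp[[1]][, , 1], (mk == 1) * 1)
  # 4->2 samples input offsets (0,0),(0,2),(2,0),(2,2): only (0,0) is class 1
  expect_equal(lp[[2]][, , 1], matrix(c(1, 0, 0, 0), 2))
  # enumeration oracle on random 4x4 masks
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(sample(0:2, 16, TRUE), 4)
    lp <- build_label_pyramid(m, 2L, c(4L, 2L))
    for (ch in 1:2) for (r in 1:2) for (cc in 1:2)
      expect_equal(lp[[2]][r, cc, ch], as.numeric(m[2 * r - 1, 2 * cc - 1] == ch))
  }
  expect_true(all(lp[[2]] %in% c(0, 1)))
  expect_error(build_label_pyramid(matrix(5L, 4, 4), 3L, c(4L)),
               "outside")
  # all-background mask gives an all-zero pyramid
  z <- build_label_pyramid(matrix(0L, 8, 8), 3L, c(8L, 4L))
  expect_true(all(unlist(z) == 0))
})

test_that("BCE matches its closed forms and a scalar-loop oracle", {
  G <- matrix(c(1, 0, 0, 1), 2)
  expect_lt(bce_loss(G, G), 1e-6)
  G2 <- matrix(rbinom(9, 1, 0.5), 3)
  expect_equal(bce_loss(matrix(0.5, 3, 3), G2), log(2), tolerance = 1e-9)
  set.seed(2)
  for (i in 1:10) {
    Q <- matrix(runif(9), 3)
    G <- matrix(rbinom(9, 1, 0.5), 3)
    expect_equal(bce_loss(Q, G), oracle_bce(Q, G), tolerance = 1e-12)
  }
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("Dice loss matches hand counts and a scalar-loop oracle", {
  G <- matrix(0, 4, 4); G[1, 1:3] <- 1
  Q <- matrix(0, 4, 4); Q[1, 2:3] <- 1; Q[2, 1] <- 1
  # overlap 2 of 3+3: 1 - 4/6 = 1/3 as eps -> 0
  expect_equal(dice_loss(Q, G, eps_s = 1e-12), 1 / 3, tolerance = 1e-9)
  expect_lt(dice_loss(G, G, eps_s = 1e-12), 1e-9)
  disj <- matrix(0, 4, 4); disj[4, 4] <- 1
  expect_equal(dice_loss(disj, G, eps_s = 1e-12), 1, tolerance = 1e-9)
  expect_equal(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 0)  # both empty
  set.seed(3)
  for (i in 1:10) {
    Q <- array(runif(4 * 4 * 2), c(4, 4, 2))
    G <- array(rbinom(32, 1, 0.4), c(4, 4, 2))
    expect_equal(dice_loss(Q, G), oracle_dice_loss(Q, G), tolerance = 1e-12)
  }
})

test_that("both losses are invariant to a shared pixel permutation", {
  set.seed(4)
  Q <- matrix(runif(36), 6)
  G <- matrix(rbinom(36, 1, 0.5), 6)
  p <- sample(36)
  Qp <- matrix(Q[p], 6); Gp <- matrix(G[p], 6)
  expect_equal(bce_loss(Q, G), bce_loss(Qp, Gp))
  expect_equal(dice_loss(Q, G), dice_loss(Qp, Gp))
})

test_that("the total loss sums the seven per-head BCE+Dice terms", {
  cfg <- slim_config()
  sides <- head_sides(cfg)
  set.seed(5)
  mk <- matrix(sample(0:3, 64 * 64, TRUE), 64)
  labels <- build_label_pyramid(mk, 3, sides)
  preds <- lapply(labels, function(G) {
    array(runif(length(G)), dim(G))
  })
  tot <- total_loss(preds, labels, "MLDS")
  per_head <- mapply(function(Q, G) bce_loss(Q, G) + dice_loss(Q, G),
                     preds, labels)
  expect_equal(tot, sum(per_head), tolerance = 1e-12)
  expect_gte(tot, 0)
  # perfect prediction: near-zero total
  perfect <- lapply(labels, function(G) G)
  expect_lt(total_loss(perfect, labels, "MLDS"), 1e-3)
})

test_that("DS mode compares upsampled heads against the full-resolution label", {
  cfg <- slim_config()
  sides <- head_sides(cfg)
  set.seed(6)
  mk <- matrix(sample(0:3, 64 * 64, TRUE), 64)
  labels <- build_label_pyramid(mk, 3, sides)
  preds <- lapply(labels, function(G) array(runif(length(G)), dim(G)))
  ds <- total_loss(preds, labels, "DS")
  oracle <- sum(vapply(seq_along(preds), function(k) {
    q <- preds[[k]]
    while (dim(q)[1] < 64) {
      q4 <- array(q, c(dim(q), 1))
      q <- mmanet:::cpp_upsample2_fwd(q4)[, , , 1]
    }
    bce_loss(q, labels[[1]]) + dice_loss(q, labels[[1]])
  }, numeric(1)))
  expect_equal(ds, oracle, tolerance = 1e-12)
  expect_gte(ds, 0)
})

test_that("prediction heads stay in [0,1] and sit at the decoder sides", {
  net <- mma_net(slim_config(), seed = 7)
  fw <- mma_forward(net, array(runif(64 * 64), c(64, 64, 1, 1)),
                    array(runif(32 * 32), c(32, 32, 1, 1)))
  expect_named(fw$heads, c("m1", "m2", "m3", "m4", "n2", "n3", "n4"))
  for (h in fw$heads) {
    expect_true(all(h$v >= 0 & h$v <= 1))
  }
})
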
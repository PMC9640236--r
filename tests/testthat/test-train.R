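# Trainer: determinism, early stopping, checkpointing, leakage guards,
# cross-validation aggregation. Runs use the slim configuration and a few
# dozen optimizer steps to stay fast.

tiny_data <- function(n_cases = 2, slices = 2, seed = 31) {
  preprocess_samples(
    generate_dataset(phantom_spec(side = 64), n_cases, slices, seed = seed),
    64)
}

test_that("training is deterministic: same seed, same trajectory and weights", {
  ds <- tiny_data()
  cfg <- slim_config()
  tc <- slim_train_config(max_steps = 6, seed = 3)
  f1 <- mma_train(cfg, ds, cfg = tc)
  f2 <- mma_train(cfg, ds, cfg = tc)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  p1 <- mmanet:::predict_samples(f1$net, ds)
  p2 <- mmanet:::predict_samples(f2$net, ds)
  expect_identical(p1, p2)
  f3 <- mma_train(cfg, ds, cfg = slim_train_config(max_steps = 6, seed = 4))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("the loss decreases on a small fixture", {
  ds <- tiny_data()
  fit <- mma_train(slim_config(), ds,
                   cfg = slim_train_config(max_steps = 30, seed = 1))
  tl <- fit$history$train_loss
  expect_lt(tl[length(tl)], tl[1])
})

test_that("early stopping halts after the patience window and keeps the best epoch", {
  ds <- tiny_data(n_cases = 3)
  cases <- vapply(ds, `[[`, "", "case_id")
  train <- ds[cases != "case003"]
  val <- ds[cases == "case003"]
  tc <- train_config(learning_rate = 2e-3, batch_size = 4L,
                     max_epochs = 40L, early_stop_patience = 3L, seed = 2)
  fit <- mma_train(slim_config(), train, val, cfg = tc)
  h <- fit$history
  if (nrow(h) < tc$max_epochs) {
    expect_equal(nrow(h) - fit$best_epoch, tc$early_stop_patience)
  }
  expect_equal(max(h$val_dice), h$val_dice[fit$best_epoch])
  # restored parameters reproduce the best epoch's monitored metric
  pm <- mmanet:::predict_samples(fit$net, val)
  expect_equal(mean_fg_dice(pm, val), max(h$val_dice), tolerance = 1e-12)
})

test_that("training refuses case leakage between train and validation", {
  ds <- tiny_data()
  expect_error(mma_train(slim_config(), ds, ds,
                         cfg = slim_train_config(max_steps = 1)),
               "overlap")
})

test_that("checkpoints reload to identical predictions", {
  ds <- tiny_data()
  fit <- mma_train(slim_config(), ds,
                   cfg = slim_train_config(max_steps = 4, seed = 6))
  d <- withr::local_tempdir()
  save_checkpoint(fit, file.path(d, "ck.rds"))
  net2 <- load_checkpoint(file.path(d, "ck.rds"))
  expect_identical(mmanet:::predict_samples(fit$net, ds),
                   mmanet:::predict_samples(net2, ds))
})

test_that("mask assembly follows the thresholding contract", {
  # confident probabilities reproduce the thresholded map exactly
  p <- array(0, c(4, 4, 3))
  p[1, 1, 2] <- 1; p[2, 2, 1] <- 1
  m <- mmanet:::assemble_mask(p)
  expect_equal(m[1, 1], 2L)
  expect_equal(m[2, 2], 1L)
  expect_equal(sum(m != 0), 2)
  # all probabilities below 0.5: all background
  expect_true(all(mmanet:::assemble_mask(array(0.49, c(4, 4, 3))) == 0L))
  # C = 1 binarizes at 0.5
  q <- array(c(0.6, 0.4), c(2, 1, 1))
  expect_equal(as.vector(mmanet:::assemble_mask(q)), c(1L, 0L))
})

test_that("cross-validation keeps cases disjoint and aggregates fold means", {
  ds <- tiny_data(n_cases = 4, slices = 2)
  folds <- make_folds(sprintf("case%03d", 1:4), 2, seed = 1)
  cv <- cross_validate(ds, folds, slim_config(),
                       slim_train_config(max_steps = 4, seed = 1,
                                         max_epochs = 2L,
                                         early_stop_patience = 1L))
  rep <- cv$report
  expect_setequal(unique(rep$per_case$case_id), sprintf("case%03d", 1:4))
  # aggregation equals the flat per-fold recomputation
  for (cl in unique(rep$per_case$class)) {
    pc <- rep$per_case[rep$per_case$class == cl, ]
    expect_equal(rep$summary$dice[rep$summary$class == cl],
                 mean(tapply(pc$dice, pc$fold, mean)), tolerance = 1e-12)
  }
})

test_that("the ablation driver shares folds across modes and rejects bad modes", {
  ds <- tiny_data(n_cases = 4, slices = 2)
  folds <- make_folds(sprintf("case%03d", 1:4), 2, seed = 5)
  tc <- slim_train_config(max_steps = 2, seed = 2, max_epochs = 2L,
                          early_stop_patience = 1L)
  ab <- ablate(ds, folds, slim_config(), tc,
               modes = list(num1 = list(num_branches = 1L),
                            num2 = list(num_branches = 2L)))
  expect_equal(nrow(ab$table), 2L * 3L)  # two modes x three classes
  f1 <- ab$reports$num1$per_case[, c("case_id", "fold")]
  f2 <- ab$reports$num2$per_case[, c("case_id", "fold")]
  expect_identical(f1, f2)
  expect_error(ablate(ds, folds, slim_config(), tc,
                      modes = list(bad = list(num_branches = 7L))),
               "unknown mode")
})
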
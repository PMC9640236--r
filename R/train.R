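# Training, inference and cross-validation drivers.

stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$image)
  N <- length(samples)
  xf <- array(0, c(H, H, 1L, N))
  xh <- array(0, c(H / 2L, H / 2L, 1L, N))
  mk <- array(0L, c(H, H, N))
  for (i in seq_len(N)) {
    xf[, , 1L, i] <- samples[[i]]$image
    xh[, , 1L, i] <- make_half_resolution(samples[[i]]$image)
    mk[, , i] <- samples[[i]]$mask
  }
  list(xfull = xf, xhalf = xh, masks = mk)
}

new_adam <- function() {
  opt <- new.env(parent = emptyenv())
  opt$m <- list(); opt$v <- list(); opt$t <- 0L
  opt
}

adam_step <- function(opt, params, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$g
    if (is.null(g)) next
    if (cfg$weight_decay > 0 && endsWith(nm, ".W"))
      g <- g + cfg$weight_decay * p$v
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
      p$v <- p$v + 0  # unshare before in-place updates
    }
    cpp_adam_update(p$v, opt$m[[nm]], opt$v[[nm]], g,
                    cfg$learning_rate, b1, b2, c1, c2)
  }
  invisible(NULL)
}

# Hard mask from the C-channel probability map of the final head: background
# where every foreground probability is below 0.5, otherwise the argmax
# foreground class (C = 1 reduces to thresholding at 0.5).
assemble_mask <- function(prob) {
  d <- dim(prob)
  if (d[3] == 1L) return(matrix(as.integer(prob[, , 1] >= 0.5), d[1]))
  pm <- matrix(prob, d[1] * d[2], d[3])
  am <- max.col(pm, ties.method = "first")
  mv <- pm[cbind(seq_len(nrow(pm)), am)]
  matrix(as.integer(ifelse(mv >= 0.5, am, 0L)), d[1])
}

predict_samples <- function(net, samples, batch_size = 8L) {
  out <- vector("list", length(samples))
  for (start in seq(1L, length(samples), batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    bt <- stack_batch(samples[idx])
    fw <- mma_forward(net, bt$xfull, bt$xhalf, training = FALSE)
    q <- fw$heads$m1$v
    for (j in seq_along(idx))
      out[[idx[j]]] <- assemble_mask(q[, , , j, drop = FALSE][, , , 1])
  }
  out
}

mean_foreground_dice <- function(pred_masks, samples, C) {
  vals <- mapply(function(p, s) {
    mean(vapply(seq_len(C), function(cl)
      dice_score((p == cl) * 1, (s$mask == cl) * 1), numeric(1)))
  }, pred_masks, samples)
  mean(vals)
}

# The +0 forces copies: parameter arrays are updated in place by the
# optimizer, so snapshots must not alias them.
snapshot_net <- function(net) {
  list(params = lapply(net$params, function(p) p$v + 0),
       bn = lapply(net$bn, function(s) list(mean = s$mean, var = s$var)))
}

restore_net <- function(net, snap) {
  for (nm in names(snap$params)) net$params[[nm]]$v <- snap$params[[nm]] + 0
  for (nm in names(snap$bn)) {
    net$bn[[nm]]$mean <- snap$bn[[nm]]$mean
    net$bn[[nm]]$var <- snap$bn[[nm]]$var
  }
  invisible(net)
}

#' Train a network
#'
#' Minimizes the summed multi-head BCE + Dice objective with Adam under the
#' protocol in [train_config()]. When a validation set is given, the mean
#' foreground Dice on it is monitored each epoch; training stops after
#' `early_stop_patience` epochs without improvement and the best epoch's
#' parameters are restored. Fully deterministic under `cfg$seed`.
#'
#' @param config A [net_config()].
#' @param train_samples List of preprocessed `slice_sample`s.
#' @param val_samples Optional validation samples (case-disjoint from
#'   training; checked).
#' @param cfg A [train_config()].
#' @param augment_params Optional [augment_config()] applied on the fly to
#'   each training batch (never to validation).
#' @param net Optional existing [mma_net()] to continue training.
#' @param verbose Print one line per epoch.
#' @return An `mma_fit`: list with `net`, `history` (data frame: epoch,
#'   train_loss, val_dice, steps), `best_epoch`, `config`, `cfg`.
#' @export
mma_train <- function(config, train_samples, val_samples = NULL, cfg,
                      augment_params = NULL, net = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(train_samples) >= 1)
  if (!is.null(val_samples)) {
    tc <- unique(vapply(train_samples, `[[`, "", "case_id"))
    vc <- unique(vapply(val_samples, `[[`, "", "case_id"))
    if (length(intersect(tc, vc)) > 0)
      stop("validation cases overlap training cases: ",
           paste(intersect(tc, vc), collapse = ", "))
  }
  C <- config$num_classes
  sides <- head_sides(config)
  mode <- config$supervision
  if (is.null(net)) net <- mma_net(config, seed = cfg$seed)
  opt <- new_adam()
  n <- length(train_samples)
  steps <- 0L
  best <- list(metric = -Inf, epoch = 0L, snap = NULL)
  hist <- list()
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq(1L, n, cfg$batch_size)) {
        if (steps >= cfg$max_steps) break
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        batch <- train_samples[idx]
        if (!is.null(augment_params)) {
          sds <- sample.int(.Machine$integer.max, length(batch))
          batch <- mapply(function(s, sd) augment(s, augment_params, sd),
                          batch, sds, SIMPLIFY = FALSE)
        }
        bt <- stack_batch(batch)
        labels <- build_label_pyramid(bt$masks, C, sides)
        ag_record_on()
        fw <- mma_forward(net, bt$xfull, bt$xhalf, training = TRUE)
        loss <- op_total_loss(fw$heads, labels, mode, cfg$eps_p, cfg$eps_s)
        if (!is.finite(loss$v)) {
          ag_record_off()
          stop(sprintf(paste0("non-finite loss at step %d (epoch %d): ",
                              "loss=%g, image range [%g, %g]"),
                       steps + 1L, epoch, loss$v, min(bt$xfull),
                       max(bt$xfull)))
        }
        ag_zero_grad(net$params)
        ag_backward(loss)
        adam_step(opt, net$params, cfg)
        ag_record_off()
        steps <- steps + 1L
        ep_losses <- c(ep_losses, loss$v)
      }
      val_dice <- NA_real_
      if (!is.null(val_samples)) {
        pm <- predict_samples(net, val_samples)
        val_dice <- mean_foreground_dice(pm, val_samples, C)
      }
      metric <- if (is.na(val_dice)) -mean(ep_losses) else val_dice
      if (metric > best$metric) {
        best$metric <- metric
        best$epoch <- epoch
        best$snap <- snapshot_net(net)
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(ep_losses),
                                  val_dice = val_dice, steps = steps)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %s", epoch,
                        mean(ep_losses),
                        ifelse(is.na(val_dice), "-",
                               sprintf("%.4f", val_dice))))
      if (!is.null(val_samples) &&
          epoch - best$epoch >= cfg$early_stop_patience) break
      if (steps >= cfg$max_steps) break
    }
  })
  if (!is.null(best$snap)) restore_net(net, best$snap)
  structure(list(net = net, history = do.call(rbind, hist),
                 best_epoch = best$epoch, config = config, cfg = cfg),
            class = "mma_fit")
}

#' Segment a case volume
#'
#' Runs the fixed inference pipeline per slice -- center crop, per-case
#' max-min normalization, half-resolution derivation, forward pass -- and
#' takes the full-resolution head (M1) as the final result: a pixel is
#' background when all foreground probabilities fall below 0.5, otherwise
#' the argmax foreground class.
#'
#' @param fit An `mma_fit` (or [mma_net()]).
#' @param volume A [case_volume()] or list of `slice_sample`s.
#' @return List with `masks` (H, W, S integer array in the cropped frame),
#'   `offsets` (row/col 0-based offsets of the crop window in the original
#'   frame) and `case_id`.
#' @export
mma_predict <- function(fit, volume) {
  net <- if (inherits(fit, "mma_fit")) fit$net else fit
  side <- net$config$input_side
  if (inherits(volume, "case_volume")) {
    samples <- volume_to_samples(volume)
    orig <- dim(volume$voxels)[1:2]
  } else {
    samples <- volume
    orig <- dim(samples[[1]]$image)
  }
  samples <- preprocess_samples(samples, side)
  masks <- predict_samples(net, samples)
  arr <- array(0L, c(side, side, length(masks)))
  for (i in seq_along(masks)) arr[, , i] <- masks[[i]]
  list(masks = arr,
       offsets = c(row = (orig[1] - side) %/% 2L,
                   col = (orig[2] - side) %/% 2L),
       case_id = samples[[1]]$case_id)
}

split_by_case <- function(samples) {
  split(samples, vapply(samples, `[[`, "", "case_id"))
}

#' Case-level k-fold cross-validation
#'
#' Trains one model per fold on the cases outside it and evaluates on the
#' held-out fold's cases, pooling each case's slices before computing
#' metrics. A seeded 20% of the training cases (at least one) is carved out
#' as the early-stopping validation set, distinct from the held-out fold;
#' no case ever crosses the train/test boundary (asserted).
#'
#' @param samples Preprocessed `slice_sample`s covering all cases.
#' @param folds A [make_folds()] assignment over those cases.
#' @param config A [net_config()].
#' @param cfg A [train_config()].
#' @param augment_params Optional [augment_config()] for training batches.
#' @param val_fraction Fraction of training cases used for early stopping.
#' @param verbose Print per-epoch progress.
#' @return List with `report` (a `metrics_report` aggregated per
#'   [evaluate_cases()], first within and then across folds), `histories`
#'   and `fits`.
#' @export
cross_validate <- function(samples, folds, config, cfg,
                           augment_params = NULL, val_fraction = 0.2,
                           verbose = FALSE) {
  stopifnot(inherits(folds, "fold_assignment"))
  by_case <- split_by_case(samples)
  cases <- names(by_case)
  if (!setequal(cases, names(folds$assignment)))
    stop("fold assignment does not match the dataset's cases")
  predictions <- list(); ground_truths <- list()
  histories <- list(); fits <- list()
  for (f in seq_len(folds$k) - 1L) {
    test_cases <- cases[folds$assignment[cases] == f]
    rest <- setdiff(cases, test_cases)
    if (length(test_cases) == 0L) next
    stopifnot(length(intersect(test_cases, rest)) == 0L)
    n_val <- if (length(rest) > 1L) max(1L, round(val_fraction * length(rest)))
             else 0L
    val_cases <- if (n_val > 0)
      with_seed(cfg$seed + 100L + f, sample(rest, n_val)) else character(0)
    train_cases <- setdiff(rest, val_cases)
    fit <- mma_train(config,
                     unlist(by_case[train_cases], recursive = FALSE),
                     if (n_val > 0) unlist(by_case[val_cases],
                                           recursive = FALSE) else NULL,
                     cfg, augment_params = augment_params,
                     verbose = verbose)
    for (cs in test_cases) {
      sl <- by_case[[cs]]
      pm <- predict_samples(fit$net, sl)
      H <- nrow(sl[[1]]$image)
      parr <- array(0L, c(H, H, length(sl)))
      garr <- array(0L, c(H, H, length(sl)))
      for (i in seq_along(sl)) {
        parr[, , i] <- pm[[i]]
        garr[, , i] <- sl[[i]]$mask
      }
      predictions[[cs]] <- parr
      ground_truths[[cs]] <- garr
    }
    histories[[f + 1L]] <- fit$history
    fits[[f + 1L]] <- fit
  }
  class_ids <- seq_len(config$num_classes)
  report <- evaluate_cases(predictions, ground_truths, class_ids,
                           class_names = default_class_names(config),
                           folds = folds$assignment)
  list(report = report, histories = histories, fits = fits)
}

default_class_names <- function(config) {
  if (config$num_classes == 3L) c("RV", "Myo", "LV")
  else if (config$num_classes == 1L) "LA"
  else paste0("class", seq_len(config$num_classes))
}

#' Architecture/supervision ablation
#'
#' Runs [cross_validate()] once per mode with identical folds and seeds, so
#' differences are attributable to the varied component only. A mode is a
#' list with `num_branches` (1 or 2) and `supervision` ("DS" or "MLDS").
#'
#' @param samples,folds,config,cfg,augment_params As in [cross_validate()].
#' @param modes Named list of modes; default: the four combinations of
#'   branch count and supervision.
#' @return List with `table` (one row per mode x class with all four
#'   metrics) and `reports`.
#' @export
ablate <- function(samples, folds, config, cfg,
                   modes = list(
                     num1_ds = list(num_branches = 1L, supervision = "DS"),
                     num1_mlds = list(num_branches = 1L, supervision = "MLDS"),
                     num2_ds = list(num_branches = 2L, supervision = "DS"),
                     num2_mlds = list(num_branches = 2L, supervision = "MLDS")),
                   augment_params = NULL) {
  for (m in modes) {
    if (!all(names(m) %in% c("num_branches", "supervision")))
      stop("unknown mode field in ", paste(names(m), collapse = ","))
    if (!is.null(m$num_branches) && !m$num_branches %in% c(1L, 2L))
      stop("unknown mode: num_branches must be 1 or 2")
    if (!is.null(m$supervision) && !m$supervision %in% c("DS", "MLDS"))
      stop("unknown mode: supervision must be DS or MLDS")
  }
  rows <- list(); reports <- list()
  for (nm in names(modes)) {
    mode <- modes[[nm]]
    cfg_i <- config
    if (!is.null(mode$num_branches)) cfg_i$num_branches <- mode$num_branches
    if (!is.null(mode$supervision)) cfg_i$supervision <- mode$supervision
    cv <- cross_validate(samples, folds, cfg_i, cfg,
                         augment_params = augment_params)
    s <- cv$report$summary
    s <- cbind(data.frame(mode = nm,
                          num_branches = cfg_i$num_branches,
                          supervision = cfg_i$supervision), s)
    rows[[nm]] <- s
    reports[[nm]] <- cv$report
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       reports = reports)
}

#' Save / load checkpoints
#'
#' A checkpoint stores the configuration echo, all parameter arrays, batch
#' norm running statistics, the fixed head order and the build seed, so a
#' reloaded network verifies compatibility and reproduces predictions
#' exactly.
#'
#' @param fit An `mma_fit` or `mma_net`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(fit, path) {
  net <- if (inherits(fit, "mma_fit")) fit$net else fit
  ck <- c(list(config = net$config, head_order = head_names(net$config),
               seed = net$seed), snapshot_net(net))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns an [mma_net()] with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- mma_net(ck$config, seed = ck$seed)
  if (!identical(head_names(net$config), ck$head_order))
    stop("checkpoint incompatible: head order differs")
  restore_net(net, ck)
  net
}
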
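#' Network configuration
#'
#' Describes one dual-branch (or single-branch) segmentation network. The
#' full-resolution branch sees `input_side` pixels, the second branch half
#' that; five VGG19-style encoder stages halve the side four times, so
#' `input_side` must be divisible by 32.
#'
#' @param input_side Input side in pixels (divisible by 32). Default 224,
#'   the short-axis crop size used throughout.
#' @param num_classes Number of foreground classes C (3 for RV/Myo/LV
#'   short-axis data, 1 for a single-structure task such as the left atrium).
#' @param stage_channels Channel counts of the five encoder stages before
#'   width scaling; defaults to the VGG19 widths.
#' @param width_multiplier Fraction applied to `stage_channels`; slim test
#'   configurations use e.g. 1/8.
#' @param num_branches 2 for the dual-resolution network, 1 for the
#'   single-branch ablation baseline.
#' @param supervision "MLDS" (each head supervised at its own scale) or
#'   "DS" (heads upsampled to full resolution before the loss).
#' @return A `net_config` list.
#' @export
net_config <- function(input_side = 224L, num_classes = 3L,
                       stage_channels = c(64L, 128L, 256L, 512L, 512L),
                       width_multiplier = 1, num_branches = 2L,
                       supervision = c("MLDS", "DS")) {
  supervision <- match.arg(supervision)
  if (length(stage_channels) != 5L)
    stop("stage_channels must have length 5")
  if (input_side %% 32L != 0L)
    stop("input_side must be divisible by 32, got ", input_side)
  if (!num_branches %in% c(1L, 2L))
    stop("num_branches must be 1 or 2")
  if (num_classes < 1L) stop("num_classes must be >= 1")
  ch <- pmax(1L, as.integer(round(stage_channels * width_multiplier)))
  structure(list(
    input_side = as.integer(input_side),
    num_classes = as.integer(num_classes),
    stage_channels = ch,
    width_multiplier = width_multiplier,
    num_branches = as.integer(num_branches),
    supervision = supervision
  ), class = "net_config")
}

#' Training configuration
#'
#' Optimization protocol: Adam with first-moment coefficient 0.9 (the
#' conventional reading of "momentum" for Adam), weight decay 1e-4 applied
#' to convolution weights, learning rate 5e-4, batch size 32, up to 1000
#' epochs with early stopping after 20 epochs without improvement of the
#' monitored validation mean foreground Dice. Desk-scale runs shrink
#' `batch_size`, `max_epochs` and optionally cap `max_steps`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Slices per optimization step.
#' @param adam_beta1,adam_beta2 Adam moment coefficients.
#' @param weight_decay L2 penalty added to convolution-weight gradients.
#' @param max_epochs Upper bound on epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (only active when a validation set is supplied).
#' @param max_steps Optional cap on total optimizer steps (Inf = no cap).
#' @param seed Seed controlling initialization, shuffling and augmentation.
#' @param eps_p Probability clamp inside the BCE loss.
#' @param eps_s Dice smoothing constant.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 32L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         weight_decay = 1e-4, max_epochs = 1000L,
                         early_stop_patience = 20L, max_steps = Inf,
                         seed = 1L, eps_p = 1e-7, eps_s = 1.0) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, early_stop_patience < max_epochs)
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
    weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    max_steps = max_steps, seed = as.integer(seed),
    eps_p = eps_p, eps_s = eps_s
  ), class = "train_config")
}

#' Read a YAML experiment configuration
#'
#' One file drives the command-line tools; recognised blocks are `data`,
#' `preprocess` (target_side, augmentation ranges, k, seed), `model`
#' (arguments of [net_config()]), `loss` (supervision mode, eps values) and
#' `train` (arguments of [train_config()]).
#'
#' @param path Path to a YAML file.
#' @return Nested list of configuration blocks.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname load_config
#' @param cfg Parsed configuration list.
#' @export
net_config_from <- function(cfg) {
  m <- cfg$model %||% list()
  l <- cfg$loss %||% list()
  do.call(net_config, c(m[intersect(names(m), names(formals(net_config)))],
                        if (!is.null(l$mode)) list(supervision = l$mode)))
}

#' @rdname load_config
#' @export
train_config_from <- function(cfg) {
  t <- cfg$train %||% list()
  l <- cfg$loss %||% list()
  args <- t[intersect(names(t), names(formals(train_config)))]
  if (!is.null(l$eps_p)) args$eps_p <- l$eps_p
  if (!is.null(l$eps_s)) args$eps_s <- l$eps_s
  do.call(train_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
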
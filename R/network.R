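# Network construction and forward pass.
#
# Parameters are materialized lazily on the first forward pass (under the
# build seed), so the wiring below is the single definition of the
# architecture. A network is an environment holding `config`, `params`
# (named list of parameter nodes) and `bn` (running batch-norm statistics).

new_module_env <- function(config = NULL) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$params <- list()
  st$bn <- list()
  class(st) <- "mma_module"
  st
}

get_conv <- function(st, name, cin, cout, k) {
  wn <- paste0(name, ".W")
  if (is.null(st$params[[wn]])) {
    sd <- sqrt(2 / (k * k * cin))
    W <- matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout)
    st$params[[wn]] <- ag_param(W)
    st$params[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  }
  list(W = st$params[[wn]], b = st$params[[paste0(name, ".b")]], k = k)
}

get_bn <- function(st, name, c) {
  gn <- paste0(name, ".gamma")
  if (is.null(st$params[[gn]])) {
    st$params[[gn]] <- ag_param(rep(1, c))
    st$params[[paste0(name, ".beta")]] <- ag_param(numeric(c))
    state <- new.env(parent = emptyenv())
    state$mean <- numeric(c)
    state$var <- rep(1, c)
    st$bn[[name]] <- state
  }
  list(gamma = st$params[[gn]], beta = st$params[[paste0(name, ".beta")]],
       state = st$bn[[name]])
}

conv_op <- function(st, name, x, cout, k) {
  cin <- dim(x$v)[3L]
  ly <- get_conv(st, name, cin, cout, k)
  op_conv(x, ly$W, ly$b, k)
}

# conv -> batchnorm -> ReLU, the basic block of every stage.
cbr <- function(st, name, x, cout, k, training) {
  h <- conv_op(st, name, x, cout, k)
  bn <- get_bn(st, paste0(name, ".bn"), cout)
  h <- if (training) op_bn_train(h, bn$gamma, bn$beta, bn$state)
       else op_bn_eval(h, bn$gamma, bn$beta, bn$state)
  op_relu(h)
}

# VGG19-style encoder: five stages of (2, 2, 4, 4, 4) 3x3 convolutions with
# 2x max-pooling between stages. Returns the pre-pool feature of each stage.
enc_forward <- function(st, prefix, x, training) {
  ch <- st$config$stage_channels
  nconv <- c(2L, 2L, 4L, 4L, 4L)
  feats <- vector("list", 5L)
  h <- as_node(x)
  for (s in 1:5) {
    for (k in seq_len(nconv[s]))
      h <- cbr(st, sprintf("%s.s%d.c%d", prefix, s, k), h, ch[s], 3L, training)
    feats[[s]] <- h
    if (s < 5) h <- op_maxpool2(h)
  }
  feats
}

# Additive attention gate: project gating and local features to an
# intermediate width with 1x1 convolutions, add, ReLU, 1x1 conv to one
# channel, sigmoid; the local feature is scaled by the coefficient map.
ag_apply <- function(st, name, gating, local, alpha_override = NULL) {
  inter <- max(dim(local$v)[3L] %/% 2L, 1L)
  g1 <- conv_op(st, paste0(name, ".g"), gating, inter, 1L)
  x1 <- conv_op(st, paste0(name, ".x"), local, inter, 1L)
  s <- op_relu(op_add(g1, x1))
  alpha <- op_sigmoid(conv_op(st, paste0(name, ".psi"), s, 1L, 1L))
  if (!is.null(alpha_override)) alpha <- ag_leaf(alpha_override)
  list(out = op_mulb(local, alpha), alpha = alpha)
}

# Attention feature selection: the complementary (decoder-side) feature
# yields a coefficient map that suppresses background in the same-scale
# encoder feature; complementary and gated encoder features are then
# concatenated and projected by two 3x3 convolutions to `cout` channels.
afs_apply <- function(st, name, comp, enc, cout, training,
                      alpha_override = NULL) {
  alpha <- op_sigmoid(conv_op(st, paste0(name, ".att"), comp, 1L, 1L))
  if (!is.null(alpha_override)) alpha <- ag_leaf(alpha_override)
  gated <- op_mulb(enc, alpha)
  h <- op_concat(list(comp, gated))
  h <- cbr(st, paste0(name, ".f1"), h, cout, 3L, training)
  h <- cbr(st, paste0(name, ".f2"), h, cout, 3L, training)
  list(out = h, alpha = alpha)
}

# Feature fusion: channel concatenation followed by two 3x3 convolutions
# projecting back to `cout` channels.
fus_apply <- function(st, name, xs, cout, training) {
  h <- op_concat(xs)
  h <- cbr(st, paste0(name, ".f1"), h, cout, 3L, training)
  cbr(st, paste0(name, ".f2"), h, cout, 3L, training)
}

# Mutual-assistance decoder. ME is M_E[1..5]; NE[[j-1]] holds N_E[j],
# j = 2..6. The bottleneck B is computed once and shared by both branches'
# stage-4 features; below stage 4 each step fuses the two branches' previous
# decoder features into one complementary feature per scale.
dec_forward_dual <- function(st, ME, NE, training) {
  ch <- st$config$stage_channels
  alphas <- list()
  g <- op_upsample2(NE[[5]])                       # Up(N_E6), side s/16
  agr <- ag_apply(st, "ag", g, ME[[5]])
  alphas$ag <- agr$alpha
  B <- fus_apply(st, "fb", list(g, agr$out), ch[5], training)
  upB <- op_upsample2(B)                           # side s/8
  m4 <- afs_apply(st, "m4", upB, ME[[4]], ch[4], training)
  n4 <- afs_apply(st, "n4", upB, NE[[3]], ch[4], training)
  alphas$m4 <- m4$alpha; alphas$n4 <- n4$alpha
  C3 <- op_upsample2(fus_apply(st, "f3", list(m4$out, n4$out), ch[4],
                               training))
  m3 <- afs_apply(st, "m3", C3, ME[[3]], ch[3], training)
  n3 <- afs_apply(st, "n3", C3, NE[[2]], ch[3], training)
  alphas$m3 <- m3$alpha; alphas$n3 <- n3$alpha
  C2 <- op_upsample2(fus_apply(st, "f2", list(m3$out, n3$out), ch[3],
                               training))
  m2 <- afs_apply(st, "m2", C2, ME[[2]], ch[2], training)
  n2 <- afs_apply(st, "n2", C2, NE[[1]], ch[2], training)
  alphas$m2 <- m2$alpha; alphas$n2 <- n2$alpha
  C1 <- op_upsample2(fus_apply(st, "f1", list(m2$out, n2$out), ch[2],
                               training))
  m1 <- afs_apply(st, "m1", C1, ME[[1]], ch[1], training)
  alphas$m1 <- m1$alpha
  list(M = list(m1$out, m2$out, m3$out, m4$out),
       N = list(n2$out, n3$out, n4$out), alphas = alphas)
}

# Single-branch fallback (branch-count ablation): a plain skip-connection
# decoder built from attention feature selection, no gate, no cross-branch
# fusion.
dec_forward_single <- function(st, ME, training) {
  ch <- st$config$stage_channels
  alphas <- list()
  h <- ME[[5]]
  outs <- vector("list", 4L)
  for (i in 4:1) {
    r <- afs_apply(st, sprintf("m%d", i), op_upsample2(h), ME[[i]], ch[i],
                   training)
    alphas[[sprintf("m%d", i)]] <- r$alpha
    outs[[i]] <- r$out
    h <- r$out
  }
  list(M = outs, N = list(), alphas = alphas)
}

#' Build a segmentation network
#'
#' Constructs the dual-branch (or single-branch) network described by a
#' [net_config()]: two parameter-independent VGG19-style encoders, the
#' mutual-assistance decoder (attention gate, attention feature selection,
#' feature fusion) and one 1x1-convolution prediction head per decoder
#' feature. Weights use fan-in He initialization under `seed`.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mma_net` environment with `params`, `bn` and `config`.
#' @export
mma_net <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  st <- new_module_env(config)
  st$seed <- as.integer(seed)
  class(st) <- c("mma_net", class(st))
  s <- config$input_side
  with_seed(seed, {
    xf <- array(0, c(s, s, 1L, 1L))
    xh <- array(0, c(s / 2L, s / 2L, 1L, 1L))
    mma_forward(st, xf, xh, training = TRUE)
  })
  # the materializing pass must not leave traces in the running statistics
  for (state in st$bn) {
    state$mean[] <- 0
    state$var[] <- 1
  }
  st
}

#' Forward pass
#'
#' Runs both encoder branches and the mutual-assistance decoder, and applies
#' the per-scale prediction heads (1x1 convolution + sigmoid, no resizing).
#' With two branches the prediction pyramid has seven members in the fixed
#' order M1, M2, M3, M4, N2, N3, N4 (sides s, s/2, s/4, s/8, s/2, s/4, s/8);
#' a single-branch network yields the four M heads.
#'
#' @param net An [mma_net()].
#' @param xfull Full-resolution batch, array (side, side, 1, N).
#' @param xhalf Half-resolution batch (side/2, side/2, 1, N); ignored for
#'   single-branch networks.
#' @param training Logical; batch statistics (TRUE) vs running statistics
#'   (FALSE) in batch normalization.
#' @return List with `heads` (probability nodes), `decoder` (M/N features)
#'   and `alphas` (attention coefficient nodes).
#' @export
mma_forward <- function(net, xfull, xhalf = NULL, training = FALSE) {
  cfg <- net$config
  s <- cfg$input_side
  xfull <- as_node(xfull)
  if (!all(dim(xfull$v)[1:2] == s))
    stop("full-resolution input must be ", s, "x", s)
  ME <- enc_forward(net, "e1", xfull, training)
  if (cfg$num_branches == 2L) {
    if (is.null(xhalf)) stop("dual-branch network needs the half-resolution input")
    xhalf <- as_node(xhalf)
    if (!all(dim(xhalf$v)[1:2] == s / 2L))
      stop("half-resolution input must be ", s / 2L, "x", s / 2L)
    NE <- enc_forward(net, "e2", xhalf, training)
    dec <- dec_forward_dual(net, ME, NE, training)
  } else {
    dec <- dec_forward_single(net, ME, training)
  }
  feats <- c(dec$M, dec$N)
  names(feats) <- head_names(cfg)
  heads <- lapply(names(feats), function(nm) {
    op_sigmoid(conv_op(net, paste0("head.", nm), feats[[nm]],
                       cfg$num_classes, 1L))
  })
  names(heads) <- names(feats)
  list(heads = heads, decoder = dec[c("M", "N")], alphas = dec$alphas)
}

#' Prediction-head sides and names
#'
#' @param config A [net_config()].
#' @return Integer vector of head spatial sides (named by head).
#' @export
head_sides <- function(config) {
  s <- config$input_side
  sides <- if (config$num_branches == 2L)
    c(s, s / 2L, s / 4L, s / 8L, s / 2L, s / 4L, s / 8L)
  else c(s, s / 2L, s / 4L, s / 8L)
  stats::setNames(as.integer(sides), head_names(config))
}

head_names <- function(config) {
  if (config$num_branches == 2L) c("m1", "m2", "m3", "m4", "n2", "n3", "n4")
  else c("m1", "m2", "m3", "m4")
}

n_params <- function(net) {
  sum(vapply(net$params, function(p) length(p$v), numeric(1)))
}

wrap4 <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Standalone decoder building blocks
#'
#' Functional versions of the decoder operators for inspection and testing.
#' Weights are created on first use inside `module` (an environment returned
#' by the previous call) so repeated calls reuse identical parameters. Batch
#' normalization runs on batch statistics, making each call a pure function
#' of inputs, weights and seed.
#'
#' `upsample2x` doubles both spatial sides by bilinear interpolation.
#' `attention_gate(gating, local)` computes coefficients in \[0,1\] from the
#' deep gating feature and returns the local feature scaled by them.
#' `attention_feature_selection(complementary, encoder_feature)` gates the
#' encoder feature by coefficients computed from the complementary feature,
#' then fuses both into `out_channels` channels.
#' `feature_fusion(features)` concatenates equal-channel features and
#' projects back to the width of a single input with two 3x3 convolutions.
#'
#' @param x,gating,local,complementary,encoder_feature,features Arrays
#'   (H, W, C) or (H, W, C, N); `features` is a list of them.
#' @param module Optional module environment from a previous call (reuses
#'   weights); created when NULL.
#' @param seed Seed for weight creation.
#' @param alpha_override Optional array forced in place of the computed
#'   coefficients (test hook for the suppression contract).
#' @param out_channels Output channels of the fused feature.
#' @return List with `output` (+ `alpha` where applicable) and `module`.
#' @export
upsample2x <- function(x) {
  d <- dim(x)
  y <- cpp_upsample2_fwd(wrap4(x))
  if (length(d) == 2L) y <- y[, , 1L, 1L]
  else if (length(d) == 3L) y <- y[, , , 1L, drop = FALSE][, , , 1L]
  y
}

#' @rdname upsample2x
#' @export
attention_gate <- function(gating, local, module = NULL, seed = 1L,
                           alpha_override = NULL) {
  gating <- wrap4(gating); local <- wrap4(local)
  if (!all(dim(gating)[1:2] == dim(local)[1:2]))
    stop("gating and local features must share spatial size")
  if (is.null(module)) module <- new_module_env()
  if (!is.null(alpha_override)) alpha_override <- wrap4(alpha_override)
  r <- with_seed(seed, ag_apply(module, "op", ag_leaf(gating),
                                ag_leaf(local), alpha_override))
  list(output = r$out$v, alpha = r$alpha$v, module = module)
}

#' @rdname upsample2x
#' @export
attention_feature_selection <- function(complementary, encoder_feature,
                                        out_channels = NULL, module = NULL,
                                        seed = 1L, alpha_override = NULL) {
  comp <- wrap4(complementary); enc <- wrap4(encoder_feature)
  if (!all(dim(comp)[1:2] == dim(enc)[1:2]))
    stop("complementary and encoder features must share spatial size")
  if (is.null(out_channels)) out_channels <- dim(enc)[3L]
  if (is.null(module)) module <- new_module_env()
  if (!is.null(alpha_override)) alpha_override <- wrap4(alpha_override)
  r <- with_seed(seed, afs_apply(module, "op", ag_leaf(comp), ag_leaf(enc),
                                 out_channels, training = TRUE,
                                 alpha_override))
  list(output = r$out$v, alpha = r$alpha$v, module = module)
}

#' @rdname upsample2x
#' @export
feature_fusion <- function(features, module = NULL, seed = 1L) {
  xs <- lapply(features, wrap4)
  if (length(xs) < 2L) stop("feature_fusion needs at least two features")
  dims <- vapply(xs, function(x) dim(x)[1:3], integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("fused features must share spatial size")
  if (any(dims[3, ] != dims[3, 1]))
    stop("fused features must share channel count")
  if (is.null(module)) module <- new_module_env()
  r <- with_seed(seed, fus_apply(module, "op", lapply(xs, ag_leaf),
                                 dims[3, 1], training = TRUE))
  list(output = r$v, module = module)
}
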
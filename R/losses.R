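# Multilabel deep supervision: per-scale label pyramids and the combined
# binary cross-entropy + Dice objective, summed over the prediction heads.

#' One-hot encoding of an integer class mask
#'
#' @param mask Integer matrix with values in 0..C (0 = background).
#' @param C Number of foreground classes.
#' @return Array (H, W, C) of 0/1 values, one channel per foreground class.
#' @export
one_hot_mask <- function(mask, C) {
  if (any(mask > C) || any(mask < 0))
    stop("mask contains class ids outside 0..", C)
  d <- dim(mask)
  oh <- array(0, c(d[1], d[2], C))
  for (c in seq_len(C)) oh[, , c] <- (mask == c) * 1
  oh
}

# Nearest-neighbour downsampling by an integer factor: top-left sampling,
# i.e. output (i, j) takes input (f*i, f*j) in 0-based coordinates. Keeps
# labels binary.
nn_downsample <- function(x, side) {
  d <- dim(x)
  f <- d[1] %/% side
  stopifnot(f * side == d[1])
  idx <- (seq_len(side) - 1L) * f + 1L
  if (length(d) == 2L) x[idx, idx]
  else if (length(d) == 3L) x[idx, idx, , drop = FALSE]
  else x[idx, idx, , , drop = FALSE]
}

#' Build the per-scale label pyramid
#'
#' Each prediction head is supervised at its own resolution: the mask is
#' one-hot encoded and downsampled by nearest neighbour to each head's side,
#' so every target stays crisp binary. The full-resolution member equals the
#' one-hot mask exactly.
#'
#' @param mask Integer mask matrix (side equal to the largest head side), or
#'   a 3D array (H, W, N) of masks for a batch.
#' @param C Number of foreground classes.
#' @param sides Integer vector of head sides (see [head_sides()]).
#' @return List of arrays (side, side, C\[, N\]), one per head.
#' @export
build_label_pyramid <- function(mask, C, sides) {
  batched <- length(dim(mask)) == 3L
  if (batched) {
    N <- dim(mask)[3]
    full <- array(0, c(dim(mask)[1], dim(mask)[2], C, N))
    for (n in seq_len(N)) full[, , , n] <- one_hot_mask(mask[, , n], C)
  } else {
    full <- one_hot_mask(mask, C)
  }
  if (dim(full)[1] != max(sides))
    stop("mask side must equal the largest head side")
  lapply(sides, function(s) nn_downsample(full, s))
}

#' Binary cross-entropy loss
#'
#' Mean over pixels (and channels and batch) of
#' \eqn{-[G \log Q + (1-G)\log(1-Q)]}, with probabilities clamped to
#' \eqn{[\epsilon_p, 1-\epsilon_p]}.
#'
#' @param Q Probability array, values in \[0,1\].
#' @param G Binary target array of the same shape.
#' @param eps_p Clamp constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(Q, G, eps_p = 1e-7) {
  if (!identical(dim(Q), dim(G))) stop("Q and G shapes differ")
  qc <- pmin(pmax(Q, eps_p), 1 - eps_p)
  -mean(G * log(qc) + (1 - G) * log(1 - qc))
}

#' Dice loss
#'
#' Per channel (and batch member) \eqn{1 - (2\sum GQ + \epsilon_s) /
#' (\sum G + \sum Q + \epsilon_s)}, averaged over channels; the smoothing
#' constant makes an empty prediction of an empty target lossless.
#'
#' @inheritParams bce_loss
#' @param eps_s Smoothing constant.
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(Q, G, eps_s = 1.0) {
  if (!identical(dim(Q), dim(G))) stop("Q and G shapes differ")
  d <- dim(Q)
  if (is.null(d)) d <- c(length(Q), 1L)
  hw <- d[1] * d[2]
  m <- prod(d) / hw
  qm <- matrix(Q, hw, m)
  gm <- matrix(G, hw, m)
  num <- 2 * colSums(qm * gm) + eps_s
  den <- colSums(qm) + colSums(gm) + eps_s
  mean(1 - num / den)
}

# Node versions used in training; same formulas with analytic gradients.
op_bce_loss <- function(q, G, eps_p) {
  qc <- pmin(pmax(q$v, eps_p), 1 - eps_p)
  n <- length(qc)
  v <- -mean(G * log(qc) + (1 - G) * log(1 - qc))
  ag_node(v, q$req, function(g) {
    inside <- (q$v > eps_p & q$v < 1 - eps_p) * 1
    dq <- g * inside * (-G / qc + (1 - G) / (1 - qc)) / n
    dim(dq) <- dim(q$v)
    ag_accum(q, dq)
  })
}

op_dice_loss <- function(q, G, eps_s) {
  d <- dim(q$v)
  hw <- d[1] * d[2]
  m <- prod(d) / hw
  qm <- matrix(q$v, hw, m)
  gm <- matrix(G, hw, m)
  num <- 2 * colSums(qm * gm) + eps_s
  den <- colSums(qm) + colSums(gm) + eps_s
  v <- mean(1 - num / den)
  ag_node(v, q$req, function(g) {
    # d/dq (1 - num/den) = (num - 2 g den) / den^2, per (channel, sample)
    dq <- (rep(num / den^2, each = hw) - 2 * gm * rep(1 / den, each = hw)) *
      (g / m)
    dim(dq) <- d
    ag_accum(q, dq)
  })
}

#' Total multi-head loss
#'
#' Sum over the prediction heads of BCE + Dice. In MLDS mode each head is
#' compared with the label at its own scale; in DS mode (the deep-supervision
#' ablation) each head is first bilinearly upsampled to full resolution and
#' compared with the full-resolution label only.
#'
#' @param preds List of probability arrays, ordered as [head_sides()].
#' @param labels Label pyramid from [build_label_pyramid()] (MLDS), whose
#'   first member is the full-resolution target used in DS mode.
#' @param mode "MLDS" or "DS".
#' @param eps_p,eps_s Loss constants.
#' @return Non-negative scalar.
#' @export
total_loss <- function(preds, labels, mode = c("MLDS", "DS"),
                       eps_p = 1e-7, eps_s = 1.0) {
  mode <- match.arg(mode)
  nodes <- lapply(preds, function(p) ag_leaf(wrap4(p)))
  labels <- lapply(labels, wrap4)
  op_total_loss(nodes, labels, mode, eps_p, eps_s)$v
}

op_total_loss <- function(heads, labels, mode, eps_p, eps_s) {
  if (length(heads) != length(labels)) stop("head/label pyramid mismatch")
  full_side <- dim(labels[[1]])[1]
  terms <- vector("list", 2L * length(heads))
  for (k in seq_along(heads)) {
    q <- heads[[k]]
    if (mode == "DS") {
      q <- op_upsample_to(q, full_side)
      G <- labels[[1]]
    } else {
      G <- labels[[k]]
    }
    if (!identical(dim(q$v), dim(G)))
      stop("head ", k, " shape does not match its target")
    terms[[2 * k - 1]] <- op_bce_loss(q, G, eps_p)
    terms[[2 * k]] <- op_dice_loss(q, G, eps_s)
  }
  op_sum_scalars(terms)
}
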
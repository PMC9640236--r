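# Minimal reverse-mode tape for the network layers.
#
# A node is an environment holding `v` (value: numeric array), `g`
# (accumulated gradient, NULL until backward reaches it), `req` (does any
# ancestor require gradients) and `bw` (closure applying the chain rule to
# the node's parents). Ops append nodes to a global tape while recording is
# on; `ag_backward()` walks the tape in reverse creation order, which is a
# valid topological order for a define-by-run graph.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L
.ag$recording <- FALSE

ag_record_on <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

ag_record_off <- function() {
  .ag$tape <- list()
  .ag$n <- 0L
  .ag$recording <- FALSE
  invisible(NULL)
}

ag_leaf <- function(value, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$req <- req
  nd$bw <- NULL
  nd
}

ag_param <- function(value) ag_leaf(value, req = TRUE)

as_node <- function(x) if (is.environment(x)) x else ag_leaf(x)

# Register an interior node. `bw` receives the node's accumulated gradient.
ag_node <- function(value, req, bw) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$req <- req
  if (.ag$recording && req) {
    nd$bw <- bw
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) length(.ag$tape) <- 2L * n
    .ag$tape[[n]] <- nd
    .ag$n <- n
  } else {
    nd$bw <- NULL
  }
  nd
}

ag_accum <- function(node, grad) {
  if (!node$req) return(invisible(NULL))
  if (is.null(node$g)) node$g <- grad else node$g <- node$g + grad
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the recorded tape.
ag_backward <- function(loss) {
  stopifnot(.ag$recording)
  loss$g <- 1
  for (i in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
    .ag$tape[[i]] <- NULL  # free activations as we go
  }
  .ag$n <- 0L
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# Run expr with a private RNG stream; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
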
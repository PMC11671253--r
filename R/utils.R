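# Internal numerical helpers shared across modules.

sigmoid <- function(x) stats::plogis(x)

# Activation registry. Gradients are taken w.r.t. the pre-activation value.
.act_funs <- list(
  identity   = function(x) x,
  relu       = function(x) pmax(x, 0),
  elu        = function(x) {
    neg <- x < 0
    x[neg] <- exp(x[neg]) - 1
    x
  },
  leaky_relu = function(x) x * ((x > 0) + 0.2 * (x <= 0))
)

.act_grads <- list(
  identity   = function(x) array(1, dim = dim(x) %||% length(x)),
  relu       = function(x) (x > 0) * 1,
  elu        = function(x) {
    g <- x * 0 + 1
    neg <- x < 0
    g[neg] <- exp(x[neg])
    g
  },
  leaky_relu = function(x) (x > 0) + 0.2 * (x <= 0)
)

act_fun <- function(name) {
  f <- .act_funs[[name]]
  if (is.null(f)) stop("unknown activation: ", name, call. = FALSE)
  f
}

act_grad <- function(name) {
  f <- .act_grads[[name]]
  if (is.null(f)) stop("unknown activation: ", name, call. = FALSE)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot (Xavier) uniform initialisation; the standard choice for GCN/GAT
# stacks, which keeps activation variance roughly constant across layers.
glorot_matrix <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

glorot_vector <- function(n) {
  lim <- sqrt(6 / (n + 1))
  stats::runif(n, -lim, lim)
}

# Apply f elementwise over parallel nested lists of numeric arrays
# (parameter trees, gradient trees, optimizer moments).
tree_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- vector("list", length(xs[[1]]))
    names(out) <- names(xs[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(xs, `[[`, i)))
    }
    out
  } else {
    do.call(f, xs)
  }
}

tree_zeros_like <- function(params) tree_map(function(p) p * 0, params)

# Adam optimizer over a parameter tree; weight decay enters the gradient as
# classic L2 regularisation (the convention of torch's Adam weight_decay).
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), step = 0L)
}

adam_step <- function(params, grads, state, lr, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  g <- if (wd > 0) tree_map(function(g, p) g + wd * p, grads, params) else grads
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, g)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, g)
  c1 <- 1 - beta1^state$step
  c2 <- 1 - beta2^state$step
  params <- tree_map(
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
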
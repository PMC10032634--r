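# Internal numeric primitives shared by the public attention ops and the
# batched training engine. All operate on matrices whose rows are samples.

gelu <- function(x) x * stats::pnorm(x)

# d/dx [x * Phi(x)] = Phi(x) + x * phi(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# clamp probabilities away from {0,1} before taking logs
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# multiply each row of X (B x d) by the length-d vector v
rowwise_mul <- function(X, v) X * rep(v, each = nrow(X))

# add a length-d bias vector to each row of X
add_bias <- function(X, b) X + rep(b, each = nrow(X))

softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# --- layer normalization (per row, biased variance, learnable gain/bias) ---

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = add_bias(rowwise_mul(xhat, g), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- rowwise_mul(dY, cache$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# --- dropout (inverted scaling; inert unless training) ---

drop_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

drop_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# --- affine layer ---

lin_fwd <- function(X, W, b) add_bias(X %*% W, b)

lin_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# --- parameter-tree utilities -------------------------------------------

# apply f leaf-wise across one or more identically shaped nested lists
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# flatten to a named list of leaves, names are $-paths
tree_leaves <- function(tree, prefix = "") {
  if (!is.list(tree)) {
    out <- list(tree)
    names(out) <- prefix
    return(out)
  }
  nm <- names(tree)
  if (is.null(nm)) nm <- as.character(seq_along(tree))
  out <- list()
  for (i in seq_along(tree)) {
    p <- if (prefix == "") nm[i] else paste0(prefix, "$", nm[i])
    out <- c(out, tree_leaves(tree[[i]], p))
  }
  out
}

# read/modify a single leaf via its $-path (used by gradient checks)
tree_get <- function(tree, path) {
  for (k in strsplit(path, "$", fixed = TRUE)[[1L]]) {
    tree <- if (grepl("^[0-9]+$", k)) tree[[as.integer(k)]] else tree[[k]]
  }
  tree
}

tree_set <- function(tree, path, value) {
  keys <- strsplit(path, "$", fixed = TRUE)[[1L]]
  if (length(keys) == 1L) {
    k <- keys
    if (grepl("^[0-9]+$", k)) tree[[as.integer(k)]] <- value else tree[[k]] <- value
    return(tree)
  }
  k <- keys[1L]
  rest <- paste(keys[-1L], collapse = "$")
  if (grepl("^[0-9]+$", k)) k <- as.integer(k)
  tree[[k]] <- tree_set(tree[[k]], rest, value)
  tree
}

# --- AdamW optimizer -----------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * ((m / c1) / (sqrt(v / c2) + eps) + weight_decay * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
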
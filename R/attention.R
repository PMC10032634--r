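#' Attention layer configuration
#'
#' Describes the shared geometry of every multi-head attention layer in the
#' model: the embedding dimension `d`, the number of heads `n_heads` (each
#' head works in `dk = d / n_heads` dimensions), the hidden width of the
#' position-wise feed-forward network `d_ff`, and the dropout rate applied
#' to each sub-layer output during training.
#'
#' Defaults follow the published full-scale model (d = 512, 8 heads,
#' d_ff = 2048, dropout 0.1); tests and desk-scale runs pass smaller values.
#'
#' @param d embedding dimension; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param d_ff hidden dimension of the feed-forward sub-layer.
#' @param dropout dropout rate in `[0, 1)` for sub-layer outputs.
#' @return an object of class `attention_config`.
#' @export
attention_config <- function(d = 512L, n_heads = 8L, d_ff = 2048L,
                             dropout = 0.1) {
  if (d %% n_heads != 0)
    stop("embedding dimension d (", d, ") must be divisible by n_heads (",
         n_heads, ")")
  if (d_ff < 1) stop("d_ff must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  dk <- d %/% n_heads
  # block-indicator matrix mapping the d concatenated head columns to heads;
  # used by the batched engine to reduce per-head inner products at once
  bind <- matrix(0, d, n_heads)
  for (j in seq_len(n_heads)) bind[((j - 1) * dk + 1):(j * dk), j] <- 1
  structure(list(d = as.integer(d), n_heads = as.integer(n_heads),
                 dk = as.integer(dk), d_ff = as.integer(d_ff),
                 dropout = dropout, bind = bind),
            class = "attention_config")
}

#' Initialize one multi-head attention layer
#'
#' Head projections are stored column-stacked: `Wq`, `Wk`, `Wv` are `d x d`
#' matrices whose j-th block of `dk` columns is the per-head projection
#' matrix of head j; `Wo` is the `d x d` output projection applied to the
#' concatenated heads. The feed-forward sub-layer has weights `W1`
#' (`d x d_ff`), `W2` (`d_ff x d`) and biases `b1`, `b2`; the two layer
#' norms carry learnable gain/bias.
#'
#' @param config an [attention_config()].
#' @return a named list of parameter arrays.
#' @export
init_attention_layer <- function(config) {
  d <- config$d; dff <- config$d_ff
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d),
       W1 = glorot(d, dff), b1 = numeric(dff),
       W2 = glorot(dff, d), b2 = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(dk)) V` over an `S x dk` token sequence.
#' Each row of the returned weight matrix sums to 1.
#'
#' @param Q,K,V numeric matrices with `S` rows and `dk` columns (`Q` and `K`
#'   must share `dk`; `V` may have a different column count).
#' @return list with `output` (`S x ncol(V)`) and `weights` (`S x S`).
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (!all(is.finite(Q), is.finite(K), is.finite(V)))
    stop("non-finite values in attention inputs")
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  dk <- ncol(K)
  if (dk < 1) stop("key dimension must be >= 1")
  W <- softmax_rows(Q %*% t(K) / sqrt(dk))
  list(output = W %*% V, weights = W)
}

#' Multi-head attention
#'
#' `Concat(head_1, ..., head_n) Wo` where
#' `head_j = Attention(Q Wq_j, K Wk_j, V Wv_j)` and the per-head projections
#' are the column blocks of `params$Wq/Wk/Wv`.
#'
#' @param Q,K,V `S x d` matrices.
#' @param params parameters from [init_attention_layer()].
#' @param config the matching [attention_config()].
#' @return `S x d` matrix.
#' @export
multi_head_attention <- function(Q, K, V, params, config) {
  d <- config$d; n <- config$n_heads; dk <- config$dk
  if (ncol(Q) != d) stop("token dimension does not match config$d")
  heads <- vector("list", n)
  for (j in seq_len(n)) {
    blk <- ((j - 1) * dk + 1):(j * dk)
    heads[[j]] <- scaled_dot_product_attention(
      Q %*% params$Wq[, blk, drop = FALSE],
      K %*% params$Wk[, blk, drop = FALSE],
      V %*% params$Wv[, blk, drop = FALSE])$output
  }
  do.call(cbind, heads) %*% params$Wo
}

#' Position-wise feed-forward network
#'
#' `W2' f(W1' h + b1) + b2` with f the Gaussian Error Linear Unit, applied
#' independently to each row of `h`.
#'
#' @param h a d-vector or an `S x d` matrix of tokens.
#' @param params layer parameters (uses `W1`, `b1`, `W2`, `b2`).
#' @return same shape as `h`.
#' @export
feed_forward <- function(h, params) {
  vec <- is.null(dim(h))
  H <- if (vec) matrix(h, 1L) else as.matrix(h)
  out <- lin_fwd(gelu(lin_fwd(H, params$W1, params$b1)), params$W2, params$b2)
  if (vec) drop(out) else out
}

#' Full multi-head attention layer (post-norm transformer block)
#'
#' Self-attention over the token sequence followed by the position-wise
#' feed-forward network, each wrapped in dropout + residual + layer
#' normalization:
#' `u = LN(tokens + Drop(MHA(tokens)))`; `out = LN(u + Drop(FFN(u)))`.
#' With `training = FALSE` dropout is inert and the layer is deterministic.
#'
#' @param tokens `S x d` matrix (S tokens; S = 2 in the cross-fusion model).
#' @param params parameters from [init_attention_layer()].
#' @param config the matching [attention_config()].
#' @param training logical; enables dropout.
#' @return `S x d` matrix.
#' @export
attention_layer <- function(tokens, params, config, training = FALSE) {
  tokens <- as.matrix(tokens)
  a <- multi_head_attention(tokens, tokens, tokens, params, config)
  a <- drop_fwd(a, config$dropout, training)$out
  u <- ln_fwd(tokens + a, params$ln1_g, params$ln1_b)$out
  f <- feed_forward(u, params)
  f <- drop_fwd(f, config$dropout, training)$out
  ln_fwd(u + f, params$ln2_g, params$ln2_b)$out
}
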
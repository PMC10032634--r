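#' Model architecture configuration
#'
#' Bundles every structural hyperparameter of the cross-fusion model: the
#' shared embedding dimension `d`, the per-source MLP hidden width `de`, the
#' attention geometry (`n_heads`, `d_ff`), the number of attention layers
#' `L` in encoder and decoder, the predictor hidden width `dh`, and the two
#' dropout rates. Defaults are the published full-scale settings
#' (d = 512, de = 1024, 8 heads, d_ff = 2048, L = 6, dh = 256, dropout 0.1
#' in encoder/decoder and 0.3 in the predictor).
#'
#' @param d shared embedding dimension (divisible by `n_heads`).
#' @param de hidden width of each source-projection MLP.
#' @param n_heads number of attention heads.
#' @param d_ff feed-forward hidden width inside attention layers.
#' @param L number of attention layers in the encoder (and decoder);
#'   `L = 0` gives the no-attention (concatenation) ablation.
#' @param dh predictor hidden width.
#' @param dropout dropout rate in encoder/decoder.
#' @param dropout_predictor dropout rate on the predictor hidden layer.
#' @return object of class `model_config` (contains an [attention_config()]
#'   as `$attn`).
#' @export
model_config <- function(d = 512L, de = 1024L, n_heads = 8L, d_ff = 2048L,
                         L = 6L, dh = 256L, dropout = 0.1,
                         dropout_predictor = 0.3) {
  if (L < 0) stop("L must be >= 0")
  attn <- attention_config(d = d, n_heads = n_heads, d_ff = d_ff,
                           dropout = dropout)
  structure(list(d = as.integer(d), de = as.integer(de), L = as.integer(L),
                 dh = as.integer(dh), dropout = dropout,
                 dropout_predictor = dropout_predictor, attn = attn),
            class = "model_config")
}

init_source_mlp <- function(d_in, de, d) {
  list(W1 = glorot(d_in, de), b1 = numeric(de),
       ln1_g = rep(1, de), ln1_b = numeric(de),
       W2 = glorot(de, d), b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

init_inverse_mlp <- function(d, de, d_out) {
  list(W1 = glorot(d, de), b1 = numeric(de),
       ln1_g = rep(1, de), ln1_b = numeric(de),
       W2 = glorot(de, d_out), b2 = numeric(d_out))
}

#' Initialize encoder parameters
#'
#' One two-layer projection MLP per feature source plus `L` attention
#' layers. Weights are Glorot-uniform, biases zero; call [set.seed()] (or
#' go through [pretrain()], which seeds from its config) for
#' reproducibility.
#'
#' @param d_in integer vector of source input dimensions (one per token).
#' @param model a [model_config()].
#' @return encoder parameter tree (`$mlps`, `$layers`).
#' @export
init_encoder <- function(d_in, model) {
  list(mlps = lapply(d_in, init_source_mlp, de = model$de, d = model$d),
       layers = if (model$L > 0)
         lapply(seq_len(model$L), function(i) init_attention_layer(model$attn))
       else list())
}

#' Initialize decoder parameters
#'
#' Mirror image of the encoder: `L` attention layers followed by one
#' inverse MLP per source (`d -> de -> d_in`, sigmoid output). Parameters
#' are independent of (not tied to) the encoder's.
#'
#' @inheritParams init_encoder
#' @return decoder parameter tree (`$layers`, `$mlps`).
#' @export
init_decoder <- function(d_in, model) {
  list(layers = if (model$L > 0)
         lapply(seq_len(model$L), function(i) init_attention_layer(model$attn))
       else list(),
       mlps = lapply(d_in, function(dm)
         init_inverse_mlp(model$d, model$de, dm)))
}

init_predictor <- function(n_sources, model, K) {
  list(Wh = glorot(2L * model$d, model$dh), bh = numeric(model$dh),
       Wo = glorot(model$dh, K), bo = numeric(K))
}

#' Project one source feature vector into the shared embedding space
#'
#' The two-layer source MLP `f(LN(W2 f(LN(W1 x + b1)) + b2))` with f the
#' GELU and LN layer normalization; this is the deterministic
#' (dropout-off) single-vector form used for inspection and testing.
#'
#' @param x input vector (length `d_in`) or matrix with rows as proteins.
#' @param params one element of `encoder$mlps`.
#' @param dropout dropout rate used when `training = TRUE`.
#' @param training logical; enables dropout.
#' @return embedding of dimension `d` (vector in, vector out).
#' @export
mlp_project <- function(x, params, dropout = 0, training = FALSE) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else as.matrix(x)
  out <- mlp_batch_fwd(X, params, dropout, training)$out
  if (vec) drop(out) else out
}

#' Encode a protein's two source features into hidden embeddings
#'
#' Each source is projected by its MLP, then the resulting tokens are
#' cross-fused by the encoder's attention layers; the two output tokens
#' `h1`, `h2` (in source order) form the protein's hidden embedding.
#'
#' @param x1,x2 source feature vectors (or matrices, proteins in rows).
#'   Pass `x2 = NULL` for a single-source encoder.
#' @param encoder parameters from [init_encoder()].
#' @param model the matching [model_config()].
#' @param training logical; enables dropout.
#' @return list with `h1` and `h2` (`h2` is `NULL` for single-source).
#' @export
encode <- function(x1, x2, encoder, model, training = FALSE) {
  vec <- is.null(dim(x1))
  asmat <- function(x) if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  Xs <- if (is.null(x2)) list(asmat(x1)) else list(asmat(x1), asmat(x2))
  H <- encoder_batch_fwd(Xs, encoder, model$attn, training)$H
  h1 <- if (vec) drop(H[[1L]]) else H[[1L]]
  h2 <- if (length(H) > 1L) { if (vec) drop(H[[2L]]) else H[[2L]] } else NULL
  list(h1 = h1, h2 = h2)
}

#' Decode hidden embeddings back to reconstructed source features
#'
#' The decoder passes the hidden tokens through its `L` attention layers
#' and reconstructs each source with an inverse MLP whose output layer is a
#' sigmoid, so every reconstructed entry lies strictly in (0, 1).
#'
#' @param h list with `h1`, `h2` as returned by [encode()].
#' @param decoder parameters from [init_decoder()].
#' @param model the matching [model_config()].
#' @param training logical; enables dropout.
#' @return list with `x1hat`, `x2hat` (matching input shapes).
#' @export
decode <- function(h, decoder, model, training = FALSE) {
  vec <- is.null(dim(h$h1))
  asmat <- function(x) if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  H <- if (is.null(h$h2)) list(asmat(h$h1)) else list(asmat(h$h1), asmat(h$h2))
  Xhat <- decoder_batch_fwd(H, decoder, model$attn, training)$Xhat
  list(x1hat = if (vec) drop(Xhat[[1L]]) else Xhat[[1L]],
       x2hat = if (length(Xhat) > 1L) {
         if (vec) drop(Xhat[[2L]]) else Xhat[[2L]]
       } else NULL)
}
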
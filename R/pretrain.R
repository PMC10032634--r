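#' Reconstruction loss for self-supervised pre-training
#'
#' Mean over proteins of the summed binary cross-entropy between original
#' and reconstructed features of both sources:
#' `(1/N) sum_i sum_m sum_j -[x log xhat + (1 - x) log(1 - xhat)]`.
#' Targets may be soft values in `[0, 1]` (the min-max-normalized network
#' columns are used as-is); reconstructions are clipped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param X1,X2 original feature matrices (proteins in rows), entries in
#'   `[0, 1]`. `X2`/`X2hat` may be `NULL` for a single-source model.
#' @param X1hat,X2hat reconstructions in `(0, 1)`, same shapes.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(X1, X1hat, X2 = NULL, X2hat = NULL) {
  bce_sum <- function(X, Xhat) {
    X <- as.matrix(X); Xhat <- clip_prob(as.matrix(Xhat))
    if (!all(dim(X) == dim(Xhat)))
      stop("original and reconstructed feature shapes differ")
    -sum(X * log(Xhat) + (1 - X) * log(1 - Xhat))
  }
  n <- nrow(as.matrix(X1))
  total <- bce_sum(X1, X1hat)
  if (!is.null(X2)) {
    if (nrow(as.matrix(X2)) != n) stop("sources have different protein counts")
    total <- total + bce_sum(X2, X2hat)
  }
  total / n
}

#' Pre-training configuration
#'
#' Published defaults: 5000 epochs of AdamW at learning rate 1e-5 for the
#' first 2500 epochs and 1e-6 afterwards, batch size 32. Desk-scale runs
#' pass far smaller `epochs`.
#'
#' @param epochs total training epochs.
#' @param batch_size minibatch size.
#' @param lr_phase1,lr_phase2 learning rates before/after `phase1_epochs`.
#' @param phase1_epochs epoch at which the learning rate switches.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 5000L, batch_size = 32L,
                            lr_phase1 = 1e-5, lr_phase2 = 1e-6,
                            phase1_epochs = 2500L, weight_decay = 0.01,
                            seed = 1L) {
  if (phase1_epochs > epochs && epochs > 0)
    phase1_epochs <- epochs
  stopifnot(epochs >= 0, batch_size >= 1, lr_phase1 > 0, lr_phase2 > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 phase1_epochs = as.integer(phase1_epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "pretrain_config")
}

# shared one-batch loss + gradient for the encoder-decoder
pretrain_batch_grad <- function(Xs, enc, dec, model, training = TRUE) {
  B <- nrow(Xs[[1L]])
  ef <- encoder_batch_fwd(Xs, enc, model$attn, training)
  df <- decoder_batch_fwd(ef$H, dec, model$attn, training)
  loss <- 0
  dlogits <- vector("list", length(Xs))
  for (s in seq_along(Xs)) {
    Xhat <- clip_prob(df$Xhat[[s]])
    loss <- loss - sum(Xs[[s]] * log(Xhat) + (1 - Xs[[s]]) * log(1 - Xhat))
    # d loss / d pre-sigmoid logits (clip treated as identity)
    dlogits[[s]] <- (df$Xhat[[s]] - Xs[[s]]) / B
  }
  loss <- loss / B
  db <- decoder_batch_bwd(dlogits, df$cache, dec, model$attn)
  genc <- encoder_batch_bwd(db$dH, ef$cache, enc, model$attn)
  list(loss = loss, g_enc = genc, g_dec = db$dp)
}

#' Self-supervised pre-training of the encoder-decoder
#'
#' Trains the cross-fusion encoder and its mirror decoder to reconstruct
#' both feature sources of every network protein (annotated or not) under
#' the summed binary cross-entropy objective, with minibatch AdamW, seeded
#' per-epoch shuffling, and a hard learning-rate switch at the phase
#' boundary.
#'
#' @param x1 network feature matrix (proteins x d1), entries in `[0, 1]`.
#' @param x2 attribute matrix (proteins x d2), binary; `NULL` for a
#'   single-source model.
#' @param model a [model_config()].
#' @param config a [pretrain_config()].
#' @return object of class `crossfuse_pretrain`: list with `encoder`,
#'   `decoder`, `history` (per-epoch mean batch loss), `model`, `config`.
#' @export
pretrain <- function(x1, x2, model = model_config(),
                     config = pretrain_config()) {
  x1 <- as.matrix(x1)
  Xs <- if (is.null(x2)) list(x1) else list(x1, as.matrix(x2))
  if (!is.null(x2) && nrow(Xs[[2L]]) != nrow(x1))
    stop("x1 and x2 must be row-aligned over the same proteins")
  set.seed(config$seed)
  d_in <- vapply(Xs, ncol, integer(1))
  enc <- init_encoder(d_in, model)
  dec <- init_decoder(d_in, model)
  history <- numeric(0)
  if (config$epochs > 0) {
    opt_e <- adamw_init(enc)
    opt_d <- adamw_init(dec)
    n <- nrow(x1)
    for (epoch in seq_len(config$epochs)) {
      lr <- if (epoch <= config$phase1_epochs) config$lr_phase1 else config$lr_phase2
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1L, n)]
        Xb <- lapply(Xs, function(X) X[idx, , drop = FALSE])
        bg <- pretrain_batch_grad(Xb, enc, dec, model, training = TRUE)
        if (!is.finite(bg$loss))
          stop("non-finite pre-training loss at epoch ", epoch,
               ", batch starting at shuffled position ", st)
        epoch_loss <- epoch_loss + bg$loss * length(idx)
        se <- adamw_step(enc, bg$g_enc, opt_e, lr,
                         weight_decay = config$weight_decay)
        enc <- se$params; opt_e <- se$state
        sd <- adamw_step(dec, bg$g_dec, opt_d, lr,
                         weight_decay = config$weight_decay)
        dec <- sd$params; opt_d <- sd$state
      }
      history <- c(history, epoch_loss / n)
    }
  }
  structure(list(encoder = enc, decoder = dec, history = history,
                 model = model, config = config,
                 d_in = d_in),
            class = "crossfuse_pretrain")
}

#' @export
print.crossfuse_pretrain <- function(x, ...) {
  cat("Pre-trained cross-fusion encoder-decoder\n")
  cat(sprintf("  sources: %s (input dims %s), embedding d = %d, L = %d layers\n",
              length(x$d_in), paste(x$d_in, collapse = ", "),
              x$model$d, x$model$L))
  if (length(x$history))
    cat(sprintf("  %d epochs; reconstruction loss %.4f -> %.4f\n",
                length(x$history), x$history[1], x$history[length(x$history)]))
  else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive of all named parameter arrays plus configuration and
#' seed, written with R's native serialization.
#'
#' @param object any model object (e.g. `crossfuse_pretrain` or `crossfuse`).
#' @param path file path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
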
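#' Asymmetric loss for multi-label GO prediction
#'
#' Focal-style binary cross-entropy that down-weights easy negatives:
#' `(1/(N K)) sum_ik -[y (1-p)^g+ log p + (1-y) p^g- log(1-p)]`.
#' With `gamma_pos = gamma_neg = 0` it reduces exactly to mean binary
#' cross-entropy. Defaults `gamma_pos = 0`, `gamma_neg = 2`.
#'
#' @param Y binary label matrix (proteins x K).
#' @param P score matrix in `(0, 1)`, same shape; clipped to
#'   `[1e-7, 1 - 1e-7]`.
#' @param gamma_pos,gamma_neg non-negative focusing parameters.
#' @return scalar loss.
#' @export
asymmetric_loss <- function(Y, P, gamma_pos = 0, gamma_neg = 2) {
  Y <- as.matrix(Y); P <- clip_prob(as.matrix(P))
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  if (gamma_pos < 0 || gamma_neg < 0) stop("focusing parameters must be >= 0")
  pos <- -Y * (1 - P)^gamma_pos * log(P)
  neg <- -(1 - Y) * P^gamma_neg * log(1 - P)
  sum(pos + neg) / length(Y)
}

# gradient of the summed (unscaled) asymmetric loss w.r.t. the logits
asl_grad_logits <- function(Y, P, gamma_pos, gamma_neg) {
  Pc <- clip_prob(P)
  dpos <- -(1 - Pc)^gamma_pos / Pc
  if (gamma_pos > 0)
    dpos <- dpos + gamma_pos * (1 - Pc)^(gamma_pos - 1) * log(Pc)
  dneg <- Pc^gamma_neg / (1 - Pc)
  if (gamma_neg > 0)
    dneg <- dneg - gamma_neg * Pc^(gamma_neg - 1) * log(1 - Pc)
  (Y * dpos + (1 - Y) * dneg) * Pc * (1 - Pc)
}

#' Fine-tuning configuration
#'
#' Published defaults: 100 epochs, the pre-trained encoder frozen for the
#' first 50 while the predictor trains at 1e-4; in the second phase the
#' encoder is unfrozen at 1e-6 and the predictor continues at 1e-5.
#' Asymmetric-loss focusing parameters default to `gamma_pos = 0`,
#' `gamma_neg = 2`.
#'
#' @param epochs total epochs.
#' @param freeze_epochs epochs during which encoder parameters are frozen.
#' @param lr_predictor_phase1,lr_encoder_phase2,lr_predictor_phase2
#'   AdamW learning rates for the two phases.
#' @param batch_size minibatch size.
#' @param gamma_pos,gamma_neg asymmetric-loss focusing parameters.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed integer seed (shuffling, dropout, fresh initialization).
#' @param use_pretrained if `FALSE`, ignore any supplied pre-trained
#'   encoder and train from random initialization (ablation).
#' @param merge_train_val if `TRUE` (default) train on the union of the
#'   split's training and validation proteins.
#' @return object of class `finetune_config`.
#' @export
finetune_config <- function(epochs = 100L, freeze_epochs = 50L,
                            lr_predictor_phase1 = 1e-4,
                            lr_encoder_phase2 = 1e-6,
                            lr_predictor_phase2 = 1e-5,
                            batch_size = 32L, gamma_pos = 0, gamma_neg = 2,
                            weight_decay = 0.01, seed = 1L,
                            use_pretrained = TRUE, merge_train_val = TRUE) {
  stopifnot(freeze_epochs <= epochs, gamma_pos >= 0, gamma_neg >= 0,
            batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 freeze_epochs = as.integer(freeze_epochs),
                 lr_predictor_phase1 = lr_predictor_phase1,
                 lr_encoder_phase2 = lr_encoder_phase2,
                 lr_predictor_phase2 = lr_predictor_phase2,
                 batch_size = as.integer(batch_size),
                 gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 use_pretrained = isTRUE(use_pretrained),
                 merge_train_val = isTRUE(merge_train_val)),
            class = "finetune_config")
}

#' Predict GO-term scores from a hidden embedding
#'
#' The predictor head `sigmoid(Wo' sigmoid(Wh' (h1 || h2) + bh) + bo)`:
#' both activations are logistic sigmoids, the input is the concatenation
#' of the two source embeddings (a single-source embedding is concatenated
#' with itself), and dropout on the hidden layer is active only during
#' training. Scores are strictly in (0, 1).
#'
#' @param h list with `h1` (and optionally `h2`) from [encode()], vectors
#'   or matrices.
#' @param params predictor parameters (`Wh`, `bh`, `Wo`, `bo`).
#' @param dropout hidden-layer dropout rate when training.
#' @param training logical.
#' @return K-vector (or proteins x K matrix) of scores.
#' @export
predict_scores <- function(h, params, dropout = 0.3, training = FALSE) {
  vec <- is.null(dim(h$h1))
  asmat <- function(x) if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  h2 <- if (is.null(h$h2)) h$h1 else h$h2
  Hcat <- cbind(asmat(h$h1), asmat(h2))
  out <- predictor_batch_fwd(Hcat, params, dropout, training)$out
  if (vec) drop(out) else out
}

#' Fine-tune the encoder + predictor for GO-term prediction
#'
#' Attaches a two-layer sigmoid predictor to the (optionally pre-trained)
#' encoder and minimizes the asymmetric loss over the split's training
#' proteins with AdamW. Phase 1 (`epoch <= freeze_epochs`) updates only the
#' predictor; phase 2 unfreezes the encoder with a fresh optimizer state at
#' its own learning rate.
#'
#' @param pretrained a `crossfuse_pretrain` object (or bare encoder parameter
#'   tree); ignored when `config$use_pretrained` is `FALSE` or `NULL` is
#'   given, in which case the encoder is freshly initialized.
#' @param features list of source feature matrices (`x1`, optionally `x2`),
#'   rows named by protein, covering at least the split's proteins.
#' @param split a `dataset_split` from [select_go_terms()].
#' @param model a [model_config()]; defaults to the one stored in
#'   `pretrained`.
#' @param config a [finetune_config()].
#' @return object of class `crossfuse`; see [crossfuse()] for its contents.
#' @export
finetune <- function(pretrained, features, split,
                     model = NULL, config = finetune_config()) {
  if (inherits(pretrained, "crossfuse_pretrain")) {
    if (is.null(model)) model <- pretrained$model
    enc0 <- pretrained$encoder
  } else {
    enc0 <- pretrained
  }
  if (is.null(model)) stop("a model_config is required")
  features <- lapply(features, as.matrix)
  d_in <- vapply(features, ncol, integer(1))
  K <- length(split$go_terms)
  set.seed(config$seed)
  if (config$use_pretrained && !is.null(enc0)) {
    mlp_dims <- vapply(enc0$mlps, function(m) nrow(m$W1), integer(1))
    if (!identical(unname(mlp_dims), unname(d_in)))
      stop("pre-trained encoder input dimensions (",
           paste(mlp_dims, collapse = ","), ") do not match features (",
           paste(d_in, collapse = ","), ")")
    enc <- enc0
  } else {
    enc <- init_encoder(d_in, model)
  }
  predictor <- init_predictor(length(features), model, K)

  use <- if (config$merge_train_val)
    c(split$train_proteins, split$val_proteins) else split$train_proteins
  Yt <- rbind(split$Y_train,
              if (config$merge_train_val) split$Y_val)
  missing <- setdiff(use, rownames(features[[1L]]))
  if (length(missing))
    stop("training proteins missing from features: ",
         paste(utils::head(missing, 5), collapse = ", "))
  Xtr <- lapply(features, function(X) X[use, , drop = FALSE])
  n <- length(use)

  opt_p <- adamw_init(predictor)
  opt_e <- NULL
  d <- model$d
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    phase2 <- epoch > config$freeze_epochs
    if (phase2 && is.null(opt_e)) opt_e <- adamw_init(enc)
    lr_p <- if (phase2) config$lr_predictor_phase2 else config$lr_predictor_phase1
    ord <- sample.int(n)
    epoch_loss <- 0
    for (st in seq(1L, n, by = config$batch_size)) {
      idx <- ord[st:min(st + config$batch_size - 1L, n)]
      Xb <- lapply(Xtr, function(X) X[idx, , drop = FALSE])
      Yb <- Yt[idx, , drop = FALSE]
      ef <- encoder_batch_fwd(Xb, enc, model$attn, training = TRUE)
      H1 <- ef$H[[1L]]
      H2 <- if (length(ef$H) > 1L) ef$H[[2L]] else ef$H[[1L]]
      pf <- predictor_batch_fwd(cbind(H1, H2), predictor,
                                model$dropout_predictor, training = TRUE)
      loss <- asymmetric_loss(Yb, pf$out, config$gamma_pos, config$gamma_neg)
      if (!is.finite(loss))
        stop("non-finite fine-tuning loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * length(idx)
      dz <- asl_grad_logits(Yb, pf$out, config$gamma_pos, config$gamma_neg) /
        length(Yb)
      pb <- predictor_batch_bwd(dz, pf$cache, predictor)
      sp <- adamw_step(predictor, pb$dp, opt_p, lr_p,
                       weight_decay = config$weight_decay)
      predictor <- sp$params; opt_p <- sp$state
      if (phase2) {
        dH1 <- pb$dHcat[, seq_len(d), drop = FALSE]
        dH2 <- pb$dHcat[, d + seq_len(d), drop = FALSE]
        dH <- if (length(ef$H) > 1L) list(dH1, dH2) else list(dH1 + dH2)
        ge <- encoder_batch_bwd(dH, ef$cache, enc, model$attn)
        se <- adamw_step(enc, ge, opt_e, config$lr_encoder_phase2,
                         weight_decay = config$weight_decay)
        enc <- se$params; opt_e <- se$state
      }
    }
    history <- c(history, epoch_loss / n)
  }
  structure(list(encoder = enc, predictor = predictor, model = model,
                 config = config, go_terms = split$go_terms,
                 aspect = split$aspect, d_in = d_in, history = history),
            class = "crossfuse")
}

#' Score proteins against the model's GO-term list
#'
#' Deterministic forward pass (dropout off) over the given feature rows;
#' columns follow the split's term order.
#'
#' @param object a fitted `crossfuse` model.
#' @param features list of source feature matrices, rows named by protein.
#' @param proteins protein identifiers to score (default: all feature rows).
#' @return proteins x K score matrix with dimnames.
#' @export
score_proteins <- function(object, features, proteins = NULL) {
  stopifnot(inherits(object, "crossfuse"))
  features <- lapply(features, as.matrix)
  if (is.null(proteins)) proteins <- rownames(features[[1L]])
  missing <- setdiff(proteins, rownames(features[[1L]]))
  if (length(missing))
    stop("unknown protein ids: ", paste(missing, collapse = ", "))
  Xs <- lapply(features, function(X) X[proteins, , drop = FALSE])
  ef <- encoder_batch_fwd(Xs, object$encoder, object$model$attn,
                          training = FALSE)
  H1 <- ef$H[[1L]]
  H2 <- if (length(ef$H) > 1L) ef$H[[2L]] else ef$H[[1L]]
  P <- predictor_batch_fwd(cbind(H1, H2), object$predictor,
                           object$model$dropout_predictor,
                           training = FALSE)$out
  dimnames(P) <- list(proteins, object$go_terms)
  P
}

#' Hidden embeddings for a set of proteins
#'
#' Concatenated encoder output tokens `(h1 || h2)` per protein, the
#' representation whose cluster quality the Davies-Bouldin index measures.
#'
#' @inheritParams score_proteins
#' @return proteins x 2d matrix (proteins x d for single-source models).
#' @export
embed_proteins <- function(object, features, proteins = NULL) {
  features <- lapply(features, as.matrix)
  if (is.null(proteins)) proteins <- rownames(features[[1L]])
  Xs <- lapply(features, function(X) X[proteins, , drop = FALSE])
  enc <- if (inherits(object, "crossfuse") || inherits(object, "crossfuse_pretrain"))
    object$encoder else object
  mdl <- object$model
  ef <- encoder_batch_fwd(Xs, enc, mdl$attn, training = FALSE)
  E <- do.call(cbind, ef$H)
  rownames(E) <- proteins
  E
}
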
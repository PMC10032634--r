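#' Fit the cross-fusion function-prediction model
#'
#' One-call interface over the two training stages: self-supervised
#' pre-training of the encoder-decoder on all network proteins, then
#' fine-tuning of encoder + predictor on the split's training labels under
#' the freeze/unfreeze schedule. Returns a classed model object with
#' `print`, `summary`, `predict` and `plot` methods.
#'
#' @param network_features `N x N` matrix from [normalize_adjacency()]
#'   (proteins in rows/columns); protein i's feature is its column.
#' @param attributes binary `N x d2` matrix from [build_attribute_matrix()],
#'   or `NULL` for a network-only model.
#' @param split a `dataset_split` from [select_go_terms()].
#' @param model a [model_config()].
#' @param pretrain a [pretrain_config()], or `NULL` to skip pre-training
#'   (random-initialization ablation).
#' @param finetune a [finetune_config()].
#' @return object of class `crossfuse` (as from [finetune()]) with the
#'   pre-training history attached as `$pretrain_history` and the feature
#'   list as `$features`.
#' @export
crossfuse <- function(network_features, attributes, split,
                  model = model_config(),
                  pretrain = pretrain_config(),
                  finetune = finetune_config()) {
  features <- if (is.null(attributes)) list(x1 = as.matrix(network_features))
  else list(x1 = as.matrix(network_features), x2 = as.matrix(attributes))
  pre <- NULL
  if (!is.null(pretrain) && isTRUE(finetune$use_pretrained)) {
    pre <- crossfuseGO::pretrain(features$x1, features$x2, model, pretrain)
  }
  fit <- crossfuseGO::finetune(pre, features, split, model, finetune)
  fit$pretrain_history <- if (is.null(pre)) numeric(0) else pre$history
  fit$features <- features
  fit
}

#' @export
print.crossfuse <- function(x, ...) {
  cat("Cross-fusion GO prediction model\n")
  cat(sprintf("  aspect: %s, %d GO terms\n", x$aspect, length(x$go_terms)))
  cat(sprintf("  sources: %d (input dims %s), d = %d, L = %d, %d heads\n",
              length(x$d_in), paste(x$d_in, collapse = ", "),
              x$model$d, x$model$L, x$model$attn$n_heads))
  cat(sprintf("  pre-trained: %s; fine-tuned %d epochs (%d frozen)\n",
              if (length(x$pretrain_history %||% numeric(0))) "yes" else "no",
              x$config$epochs, x$config$freeze_epochs))
  if (length(x$history))
    cat(sprintf("  asymmetric loss %.4f -> %.4f\n",
                x$history[1], x$history[length(x$history)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.crossfuse <- function(object, split = NULL, features = NULL, ...) {
  features <- features %||% object$features
  cat("Cross-fusion GO prediction model\n\n")
  print(object)
  if (!is.null(split) && !is.null(features) &&
      length(split$test_proteins)) {
    P <- score_proteins(object, features, split$test_proteins)
    E <- embed_proteins(object, features, split$test_proteins)
    cat("\nHeld-out (test set) performance:\n")
    print(evaluate_predictions(split$Y_test, P, E))
  }
  invisible(object)
}

#' Predict GO-term scores for proteins
#'
#' @param object a fitted `crossfuse` model.
#' @param features list of source feature matrices (defaults to the ones
#'   stored at fit time).
#' @param proteins protein ids to score (default: all rows).
#' @param ... unused.
#' @return proteins x K score matrix in (0, 1).
#' @export
predict.crossfuse <- function(object, features = NULL, proteins = NULL, ...) {
  score_proteins(object, features %||% object$features, proteins)
}

#' Plot training histories of a fitted model
#'
#' Reconstruction loss per pre-training epoch (if present) and asymmetric
#' loss per fine-tuning epoch, with the freeze/unfreeze boundary marked.
#'
#' @param x a fitted `crossfuse` model.
#' @param ... passed to [plot()].
#' @export
plot.crossfuse <- function(x, ...) {
  two <- length(x$pretrain_history %||% numeric(0)) > 0
  if (two) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    plot(x$pretrain_history, type = "l", xlab = "epoch",
         ylab = "reconstruction loss", main = "Pre-training", ...)
  }
  plot(x$history, type = "l", xlab = "epoch", ylab = "asymmetric loss",
       main = "Fine-tuning", ...)
  graphics::abline(v = x$config$freeze_epochs + 0.5, lty = 2)
  invisible(x)
}
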
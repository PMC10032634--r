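#' Assemble a pipeline run configuration
#'
#' Thin schema over the four stage configurations plus a global seed. The
#' input is either a directory of TSV fixtures (as written by
#' [synth_write_fixture()]) or an in-memory `synth_dataset`.
#'
#' @param fixture_dir directory containing network.tsv, domains.tsv,
#'   locations.tsv and go.tsv (mutually exclusive with `dataset`).
#' @param dataset a `synth_dataset`.
#' @param preprocess named list of [preprocess_dataset()] arguments
#'   (aspect, t0, t1, thresholds, ...).
#' @param model named list of [model_config()] arguments.
#' @param pretrain named list of [pretrain_config()] arguments, or `NULL`
#'   to skip pre-training.
#' @param finetune named list of [finetune_config()] arguments.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir optional output directory for scores, checkpoint and
#'   manifest.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(fixture_dir = NULL, dataset = NULL,
                       preprocess = list(), model = list(),
                       pretrain = list(), finetune = list(),
                       seed = 1L, out_dir = NULL) {
  if (is.null(fixture_dir) == is.null(dataset))
    stop("exactly one of fixture_dir or dataset must be given")
  if (!is.null(fixture_dir)) {
    need <- file.path(fixture_dir,
                      c("network.tsv", "domains.tsv", "locations.tsv",
                        "go.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(fixture_dir = fixture_dir, dataset = dataset,
                 preprocess = preprocess, model = model,
                 pretrain = pretrain, finetune = finetune,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$dataset)) {
    ds <- config$dataset
    list(network = ds$network,
         domains = ds$domain_annotations,
         locations = ds$location_annotations,
         annotations = ds$annotations)
  } else {
    list(network = read_ppi_network(file.path(config$fixture_dir,
                                              "network.tsv")),
         domains = utils::read.table(file.path(config$fixture_dir,
                                               "domains.tsv"),
                                     header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE),
         locations = utils::read.table(file.path(config$fixture_dir,
                                                 "locations.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE),
         annotations = read_annotation_table(file.path(config$fixture_dir,
                                                       "go.tsv")))
  }
}

variant_features <- function(prep, variant) {
  nd <- attr(prep$attributes, "n_domain")
  switch(variant,
         full = ,
         no_pretrain = ,
         no_attention = list(x1 = prep$network_features,
                             x2 = prep$attributes),
         network_only = list(x1 = prep$network_features),
         attributes_only = ,
         domain_plus_location = list(x1 = prep$attributes),
         domain_only = list(x1 = prep$attributes[, seq_len(nd),
                                                 drop = FALSE]),
         location_only = list(
           x1 = prep$attributes[, -seq_len(nd), drop = FALSE]),
         stop("unknown variant '", variant, "'; valid: ",
              paste(ABLATION_VARIANTS, collapse = ", ")))
}

#' Valid ablation variant names
#' @export
ABLATION_VARIANTS <- c("no_pretrain", "no_attention", "network_only",
                       "attributes_only", "domain_only", "location_only",
                       "domain_plus_location")

run_variant <- function(prep, config, variant = "full") {
  feats <- variant_features(prep, variant)
  margs <- config$model
  if (variant == "no_attention") margs$L <- 0L
  mdl <- do.call(model_config, margs)
  pargs <- config$pretrain
  fargs <- config$finetune
  fargs$seed <- config$seed + 1L
  if (variant == "no_pretrain" || is.null(pargs))
    fargs$use_pretrained <- FALSE
  pre <- NULL
  if (!is.null(pargs) && !identical(fargs$use_pretrained, FALSE)) {
    pargs$seed <- config$seed
    pre <- pretrain(feats$x1, feats$x2 %||% NULL,
                    mdl, do.call(pretrain_config, pargs))
  }
  fit <- finetune(pre, feats, prep$split, mdl,
                  do.call(finetune_config, fargs))
  fit$pretrain_history <- if (is.null(pre)) numeric(0) else pre$history
  fit$features <- feats
  P <- score_proteins(fit, feats, prep$split$test_proteins)
  E <- embed_proteins(fit, feats, prep$split$test_proteins)
  ev <- evaluate_predictions(prep$split$Y_test, P, E)
  list(fit = fit, scores = P, eval = ev)
}

#' Run the full pipeline
#'
#' Preprocess, pre-train, fine-tune and evaluate in sequence; returns (and
#' optionally writes) a manifest with the applied filters, stage seeds and
#' the metric report. Determinism: the same configuration and seed
#' reproduce the same manifest (modulo timestamps).
#'
#' @param config a [run_config()].
#' @return list with `manifest`, `prep`, `fit`, `scores`, `eval`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)
  prep <- do.call(preprocess_dataset,
                  c(list(network = inputs$network,
                         domain_annotations = inputs$domains,
                         location_annotations = inputs$locations,
                         annotations = inputs$annotations),
                    config$preprocess))
  res <- run_variant(prep, config, "full")
  ev <- res$eval
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossfuseGO")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    preprocess = prep$manifest,
    metrics = list(m_aupr = ev$m_aupr, M_aupr = ev$M_aupr,
                   f1_top3 = ev$f1_top3, acc = ev$acc, fmax = ev$fmax,
                   fmax_tau = ev$fmax_tau,
                   davies_bouldin = ev$davies_bouldin))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    sc <- data.frame(protein = rep(rownames(res$scores),
                                   ncol(res$scores)),
                     go_term = rep(colnames(res$scores),
                                   each = nrow(res$scores)),
                     score = as.vector(res$scores))
    score_path <- file.path(config$out_dir, "scores.tsv")
    utils::write.table(sc, score_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ckpt_path <- file.path(config$out_dir, "model.ckpt")
    save_checkpoint(res$fit, ckpt_path)
    manifest$files <- as.list(tools::md5sum(c(score_path, ckpt_path)))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, prep = prep, fit = res$fit,
       scores = res$scores, eval = ev)
}

#' Ablation comparison
#'
#' Runs the full model plus the requested variants under a shared seed and
#' tabulates test m-AUPR, M-AUPR and Fmax per variant. Single-source
#' variants drop the missing source's token and run attention over a
#' length-1 sequence.
#'
#' @param config a [run_config()].
#' @param variants subset of [ABLATION_VARIANTS] (empty set allowed).
#' @param include_full include the unablated model as the first row.
#' @return data.frame with columns variant, m_aupr, M_aupr, fmax.
#' @export
ablate <- function(config, variants = character(0), include_full = TRUE) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(variants, ABLATION_VARIANTS)
  if (length(bad))
    stop("unknown variant(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(ABLATION_VARIANTS, collapse = ", "))
  todo <- c(if (include_full) "full", variants)
  if (!length(todo))
    return(data.frame(variant = character(0), m_aupr = numeric(0),
                      M_aupr = numeric(0), fmax = numeric(0)))
  inputs <- load_run_inputs(config)
  prep <- do.call(preprocess_dataset,
                  c(list(network = inputs$network,
                         domain_annotations = inputs$domains,
                         location_annotations = inputs$locations,
                         annotations = inputs$annotations),
                    config$preprocess))
  rows <- lapply(todo, function(v) {
    ev <- run_variant(prep, config, v)$eval
    data.frame(variant = v, m_aupr = ev$m_aupr,
               M_aupr = ev$M_aupr, fmax = ev$fmax)
  })
  do.call(rbind, rows)
}
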
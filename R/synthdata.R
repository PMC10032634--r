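#' Specification of a synthetic planted-module dataset
#'
#' Describes a planted-partition PPI network (edge probability `p_in`
#' within modules, `p_out` between), module-linked binary attributes
#' (each module has a characteristic attribute template; each protein's
#' attributes are the template with independent bit flips at
#' `attribute_flip_rate`), and module-linked GO annotations
#' (`terms_per_module` terms per module, per-protein label flips at
#' `label_noise_rate`, annotation dates drawn around a per-protein center
#' inside `date_range` with `date_jitter_days` of record-level jitter, and
#' evidence codes sampled from `evidence_code_pool`). Each positive
#' protein-term pair emits `n_evidence_records` independent records so that
#' non-experimental evidence codes in the pool exercise the evidence filter
#' without erasing labels outright.
#'
#' Defaults define the desk-scale study conditions used throughout the
#' test suite: 200 proteins in 4 modules, `p_in = 0.3`, `p_out = 0.02`,
#' 30 domain + 10 location terms (d2 = 40), 2 GO terms per module among 8,
#' dates spanning 2015-2022 around the 2018/2020 temporal cutoffs.
#'
#' @param n_proteins,n_modules network size and number of planted modules.
#' @param p_in,p_out within/between-module edge probabilities
#'   (`p_out <= p_in`).
#' @param weight_range integer range of STRING-style edge weights.
#' @param n_domain_terms,n_location_terms attribute vocabulary sizes.
#' @param template_density probability an attribute term belongs to a
#'   module's template.
#' @param attribute_flip_rate per-bit flip probability on attributes.
#' @param n_go_terms,terms_per_module GO vocabulary size and planted terms
#'   per module (`terms_per_module * n_modules <= n_go_terms`).
#' @param label_noise_rate per-(protein, term) label flip probability.
#' @param date_range character vector of two ISO dates.
#' @param date_jitter_days record date jitter around the protein's center.
#' @param n_evidence_records records emitted per positive pair.
#' @param evidence_code_pool codes sampled per record (the default mixes
#'   the eight experimental codes with IEA and ISS, which the evidence
#'   filter must discard).
#' @param aspect GO aspect assigned to every annotation.
#' @param seed integer seed; the dataset is fully determined by it.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 200L, n_modules = 4L,
                       p_in = 0.3, p_out = 0.02,
                       weight_range = c(200L, 1000L),
                       n_domain_terms = 30L, n_location_terms = 10L,
                       template_density = 0.4,
                       attribute_flip_rate = 0.1,
                       n_go_terms = 8L, terms_per_module = 2L,
                       label_noise_rate = 0.1,
                       date_range = c("2015-01-01", "2022-12-31"),
                       date_jitter_days = 60L,
                       n_evidence_records = 2L,
                       evidence_code_pool = c(EXPERIMENTAL_EVIDENCE,
                                              "IEA", "ISS"),
                       aspect = "BPO", seed = 7L) {
  if (p_out > p_in) stop("p_out must not exceed p_in")
  if (any(c(p_in, p_out, attribute_flip_rate, label_noise_rate) < 0) ||
      any(c(p_in, p_out, attribute_flip_rate, label_noise_rate) > 1))
    stop("probabilities must lie in [0, 1]")
  if (terms_per_module * n_modules > n_go_terms)
    stop("infeasible spec: terms_per_module * n_modules (",
         terms_per_module * n_modules, ") exceeds n_go_terms (",
         n_go_terms, ")")
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic dataset
#'
#' Produces a planted-partition weighted network, module-linked binary
#' attributes, and a GO annotation table with dates and evidence codes,
#' plus the ground-truth module assignment. Fully determined by
#' `spec$seed`; parseable by the data-preparation functions with no
#' special-casing.
#'
#' @param spec a [synth_spec()].
#' @return object of class `synth_dataset`: list with `network`
#'   (`ppi_network`), `domain_annotations`, `location_annotations`,
#'   `annotations` (`annotation_table`), `modules` (named integer vector),
#'   `module_terms` (list module -> planted GO terms), and `spec`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  prot <- sprintf("P%04d", seq_len(n))
  modules <- stats::setNames(sample.int(spec$n_modules, n, replace = TRUE),
                             prot)

  # planted-partition edges over the upper triangle
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- modules[pr[, 1L]] == modules[pr[, 2L]]
  p_edge <- ifelse(same, spec$p_in, spec$p_out)
  keep <- stats::runif(nrow(pr)) < p_edge
  ei <- pr[keep, , drop = FALSE]
  w <- sample(seq(spec$weight_range[1L], spec$weight_range[2L]),
              nrow(ei), replace = TRUE)
  edges <- data.frame(protein_a = prot[ei[, 1L]], protein_b = prot[ei[, 2L]],
                      weight = w, stringsAsFactors = FALSE)
  network <- ppi_network(edges, proteins = prot)

  # module attribute templates with per-protein bit flips
  terms_attr <- c(sprintf("D%03d", seq_len(spec$n_domain_terms)),
                  sprintf("L%03d", seq_len(spec$n_location_terms)))
  d2 <- length(terms_attr)
  templates <- matrix(stats::runif(spec$n_modules * d2) < spec$template_density,
                      spec$n_modules, d2)
  A <- templates[modules, , drop = FALSE]
  flips <- matrix(stats::runif(n * d2) < spec$attribute_flip_rate, n, d2)
  A <- A != flips  # XOR
  dimnames(A) <- list(prot, terms_attr)
  to_ann <- function(M) {
    idx <- which(M, arr.ind = TRUE)
    data.frame(protein = rownames(M)[idx[, 1L]],
               term = colnames(M)[idx[, 2L]],
               stringsAsFactors = FALSE)
  }
  is_dom <- seq_len(spec$n_domain_terms)
  domain_annotations <- to_ann(A[, is_dom, drop = FALSE])
  location_annotations <- to_ann(A[, -is_dom, drop = FALSE])

  # module-linked GO labels with per-pair flips
  go_terms <- sprintf("GO:%07d", seq_len(spec$n_go_terms))
  module_terms <- lapply(seq_len(spec$n_modules), function(m) {
    go_terms[((m - 1L) * spec$terms_per_module + 1L):
               (m * spec$terms_per_module)]
  })
  L <- matrix(FALSE, n, spec$n_go_terms, dimnames = list(prot, go_terms))
  for (m in seq_len(spec$n_modules))
    L[modules == m, module_terms[[m]]] <- TRUE
  lflips <- matrix(stats::runif(length(L)) < spec$label_noise_rate,
                   n, spec$n_go_terms)
  L <- L != lflips

  # annotation records: per-protein date center, jittered per record
  d0 <- as.Date(spec$date_range[1L]); d1 <- as.Date(spec$date_range[2L])
  centers <- stats::setNames(
    d0 + round(stats::runif(n) * as.numeric(d1 - d0)), prot)
  pos <- which(L, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("spec produced no annotations")
  rec <- pos[rep(seq_len(nrow(pos)), each = spec$n_evidence_records), ,
             drop = FALSE]
  p_id <- prot[rec[, 1L]]
  dates <- centers[p_id] +
    round(stats::runif(nrow(rec), -spec$date_jitter_days,
                       spec$date_jitter_days))
  dates <- pmin(pmax(dates, d0), d1)
  annotations <- annotation_table(data.frame(
    protein = p_id,
    go_term = go_terms[rec[, 2L]],
    aspect = spec$aspect,
    evidence = sample(spec$evidence_code_pool, nrow(rec), replace = TRUE),
    date = as.character(dates),
    stringsAsFactors = FALSE))

  structure(list(network = network,
                 domain_annotations = domain_annotations,
                 location_annotations = location_annotations,
                 annotations = annotations,
                 modules = modules,
                 module_terms = module_terms,
                 labels = L * 1L,
                 spec = spec),
            class = "synth_dataset")
}

#' Write a synthetic dataset as TSV fixtures
#'
#' Emits exactly the dialects the readers consume: `network.tsv`
#' (protein1, protein2, combined_score), `domains.tsv` / `locations.tsv`
#' (protein, term), `go.tsv` (protein, go_term, aspect, evidence, date),
#' plus `truth.json` with the ground-truth module assignment.
#'
#' @param dataset a `synth_dataset`.
#' @param dir target directory; must not already contain fixture files.
#' @return named character vector of written paths.
#' @export
synth_write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             domains = file.path(dir, "domains.tsv"),
             locations = file.path(dir, "locations.tsv"),
             go = file.path(dir, "go.tsv"),
             truth = file.path(dir, "truth.json"))
  if (any(file.exists(paths)))
    stop("fixture files already exist in ", dir)
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE)
  net <- dataset$network$edges
  names(net) <- c("protein1", "protein2", "combined_score")
  wt(net, paths["network"])
  wt(dataset$domain_annotations, paths["domains"])
  wt(dataset$location_annotations, paths["locations"])
  ann <- dataset$annotations
  ann$date <- as.character(ann$date)
  wt(as.data.frame(ann), paths["go"])
  jsonlite::write_json(list(modules = as.list(dataset$modules),
                            module_terms = dataset$module_terms),
                       paths["truth"], auto_unbox = TRUE)
  paths
}
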
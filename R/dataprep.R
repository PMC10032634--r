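#' Default experimental evidence codes
#'
#' The evidence codes accepted as experimental annotations under the
#' CAFA-style protocol used here.
#' @export
EXPERIMENTAL_EVIDENCE <- c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TA")

#' Read a weighted PPI edge list
#'
#' Three-column TSV (`protein_a`, `protein_b`, `weight`); a header line is
#' detected automatically (STRING detail-file names `protein1`, `protein2`,
#' `combined_score` are accepted). Duplicate unordered pairs are collapsed
#' by keeping the first occurrence; self-loops are dropped.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return object of class `ppi_network`: list with `proteins` (ordered
#'   identifiers) and `edges` (data.frame protein_a, protein_b, weight).
#' @export
read_ppi_network <- function(path, sep = "\t") {
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 3L) stop("network file must have 3 columns: ", path)
  df <- df[, 1:3]
  names(df) <- c("protein_a", "protein_b", "weight")
  ppi_network(df)
}

#' Construct a PPI network from an edge data frame
#'
#' @param edges data.frame with columns protein_a, protein_b, weight.
#' @param proteins optional full protein universe (defaults to all proteins
#'   appearing in edges); isolated proteins may be included this way.
#' @return object of class `ppi_network`.
#' @export
ppi_network <- function(edges, proteins = NULL) {
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight))) stop("non-finite edge weights")
  if (any(edges$weight < 0)) stop("negative edge weights are not allowed")
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b),
                paste(edges$protein_b, edges$protein_a))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (is.null(proteins))
    proteins <- sort(unique(c(edges$protein_a, edges$protein_b)))
  structure(list(proteins = proteins, edges = edges), class = "ppi_network")
}

#' Min-max-normalized adjacency matrix
#'
#' Builds the symmetric weighted adjacency matrix (non-edges and the
#' diagonal are 0) and applies global min-max normalization over all `N x N`
#' entries, mapping the minimum to exactly 0 and the maximum to exactly 1.
#' Column i is protein i's network feature vector.
#'
#' @param network a `ppi_network`.
#' @return `N x N` matrix with protein dimnames, entries in `[0, 1]`.
#' @export
normalize_adjacency <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  prot <- network$proteins
  n <- length(prot)
  if (n < 2L) stop("network must contain at least 2 proteins")
  A <- matrix(0, n, n, dimnames = list(prot, prot))
  e <- network$edges
  ia <- match(e$protein_a, prot)
  ib <- match(e$protein_b, prot)
  if (anyNA(ia) || anyNA(ib))
    stop("edges reference proteins absent from the protein list")
  A[cbind(ia, ib)] <- e$weight
  A[cbind(ib, ia)] <- e$weight
  lo <- min(A); hi <- max(A)
  if (hi == lo)
    stop("degenerate network: all adjacency entries are equal (min = max)")
  (A - lo) / (hi - lo)
}

#' Binary attribute matrix from domain and location annotations
#'
#' Bag-of-words encoding over the domain vocabulary (terms occurring fewer
#' than `min_domain_count` times among the given proteins are removed
#' first) concatenated with the subcellular-location vocabulary. Both
#' vocabularies are ordered lexicographically; domain columns come first.
#' Proteins without any retained annotation get all-zero rows.
#'
#' @param domain_annotations data.frame with columns `protein`, `term`.
#' @param location_annotations data.frame with columns `protein`, `term`.
#' @param proteins ordered protein universe defining the rows.
#' @param min_domain_count minimum occurrence count for domain terms
#'   (default 6).
#' @return binary proteins x d2 matrix; attributes `vocabulary` (named
#'   counts for `domain_terms` and `location_terms`) and `n_domain`.
#' @export
build_attribute_matrix <- function(domain_annotations, location_annotations,
                                   proteins, min_domain_count = 6L) {
  norm_ann <- function(df) {
    df <- df[, 1:2]
    names(df) <- c("protein", "term")
    df <- unique(df[df$protein %in% proteins, , drop = FALSE])
    df
  }
  dom <- norm_ann(domain_annotations)
  loc <- norm_ann(location_annotations)
  dom_counts <- table(dom$term)
  keep <- sort(names(dom_counts)[dom_counts >= min_domain_count])
  loc_terms <- sort(unique(loc$term))
  if (length(keep) + length(loc_terms) == 0L)
    stop("empty attribute vocabulary after the min_domain_count (",
         min_domain_count, ") domain-frequency filter")
  dom <- dom[dom$term %in% keep, , drop = FALSE]
  d2 <- length(keep) + length(loc_terms)
  M <- matrix(0, length(proteins), d2,
              dimnames = list(proteins, c(keep, loc_terms)))
  if (nrow(dom))
    M[cbind(match(dom$protein, proteins), match(dom$term, keep))] <- 1
  if (nrow(loc))
    M[cbind(match(loc$protein, proteins),
            length(keep) + match(loc$term, loc_terms))] <- 1
  vocab <- list(
    domain_terms = as.integer(table(factor(dom$term, levels = keep))),
    location_terms = as.integer(table(factor(loc$term, levels = loc_terms))))
  names(vocab$domain_terms) <- keep
  names(vocab$location_terms) <- loc_terms
  attr(M, "vocabulary") <- vocab
  attr(M, "n_domain") <- length(keep)
  M
}

#' Read a GO annotation table
#'
#' GAF-like TSV with columns `protein`, `go_term`, `aspect` (BPO/MFO/CCO),
#' `evidence`, `date` (ISO 8601).
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return validated data.frame (class `annotation_table`).
#' @export
read_annotation_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  annotation_table(df)
}

#' @rdname read_annotation_table
#' @param records data.frame with the five annotation columns.
#' @export
annotation_table <- function(records) {
  need <- c("protein", "go_term", "aspect", "evidence", "date")
  if (!all(need %in% names(records)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  records <- records[, need]
  bad <- setdiff(unique(records$aspect), c("BPO", "MFO", "CCO"))
  if (length(bad))
    stop("invalid GO aspect(s): ", paste(bad, collapse = ", "))
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stop("unparseable annotation dates")
  class(records) <- c("annotation_table", "data.frame")
  records
}

#' Keep only experimentally supported annotations
#'
#' Filters the annotation table to records whose evidence code is in
#' `allowed` (default: the eight experimental codes in
#' [EXPERIMENTAL_EVIDENCE]); record order is preserved and an empty result
#' is permitted.
#'
#' @param table an `annotation_table`.
#' @param allowed character vector of evidence codes to keep.
#' @return filtered `annotation_table`.
#' @export
filter_evidence <- function(table, allowed = EXPERIMENTAL_EVIDENCE) {
  table[table$evidence %in% allowed, , drop = FALSE]
}

#' CAFA-style temporal split of annotated proteins
#'
#' A protein with any annotation dated on or before `t0` goes to the
#' training set; otherwise, with any annotation in `(t0, t1]`, to the
#' validation set; otherwise (all annotations after `t1`) to the test set.
#' The table should already be evidence-filtered. Proteins with no
#' annotations simply do not appear.
#'
#' @param table an `annotation_table`.
#' @param t0,t1 cutoff dates, `t0 < t1`; defaults 2018-01-01, 2020-12-31.
#' @return named character vector protein -> "train"/"val"/"test".
#' @export
temporal_split <- function(table, t0 = "2018-01-01", t1 = "2020-12-31") {
  t0 <- as.Date(t0); t1 <- as.Date(t1)
  if (!(t0 < t1)) stop("t0 must precede t1")
  if (nrow(table) == 0L) return(stats::setNames(character(0), character(0)))
  first <- tapply(as.numeric(table$date), table$protein, min)
  set <- ifelse(first <= as.numeric(t0), "train",
                ifelse(first <= as.numeric(t1), "val", "test"))
  stats::setNames(as.character(set), names(first))
}

#' Select GO terms and build the labelled split
#'
#' Applies both selection rules: a term must have at least `min_train`,
#' `min_val` and `min_test` positive proteins in the respective sets, and
#' must not annotate more than `max_network_fraction` of the network's
#' proteins (strictly more; a term at exactly the fraction is kept). Term
#' order is lexicographic by GO id. Proteins absent from the network are
#' dropped with a warning.
#'
#' @param assignment named vector from [temporal_split()].
#' @param table evidence-filtered `annotation_table`.
#' @param network a `ppi_network` (defines N and the protein universe).
#' @param aspect restrict to one GO aspect (`"BPO"`, `"MFO"`, `"CCO"`), or
#'   `NULL` for all records.
#' @param min_train,min_val,min_test minimum positive counts (10, 5, 1).
#' @param max_network_fraction maximum annotated fraction of network
#'   proteins (0.05).
#' @return object of class `dataset_split`: list with `aspect`, `go_terms`,
#'   `train_proteins`, `val_proteins`, `test_proteins` and binary label
#'   matrices `Y_train`, `Y_val`, `Y_test` (rows aligned to the protein
#'   vectors, columns to `go_terms`).
#' @export
select_go_terms <- function(assignment, table, network, aspect = NULL,
                            min_train = 10L, min_val = 5L, min_test = 1L,
                            max_network_fraction = 0.05) {
  stopifnot(inherits(network, "ppi_network"))
  if (!is.null(aspect)) table <- table[table$aspect == aspect, , drop = FALSE]
  n_net <- length(network$proteins)
  off <- setdiff(unique(table$protein), network$proteins)
  if (length(off)) {
    warning(length(off), " annotated protein(s) absent from the PPI network",
            " were dropped")
    table <- table[table$protein %in% network$proteins, , drop = FALSE]
  }
  assignment <- assignment[names(assignment) %in% network$proteins]
  pairs <- unique(table[, c("protein", "go_term")])
  pairs$set <- assignment[pairs$protein]
  pairs <- pairs[!is.na(pairs$set), , drop = FALSE]
  terms <- sort(unique(pairs$go_term))
  if (!length(terms)) stop("no GO terms present for aspect ",
                           if (is.null(aspect)) "ALL" else aspect)
  cnt <- function(set) {
    tab <- table(factor(pairs$go_term[pairs$set == set], levels = terms))
    as.integer(tab)
  }
  n_tr <- cnt("train"); n_va <- cnt("val"); n_te <- cnt("test")
  n_ann <- as.integer(table(factor(pairs$go_term, levels = terms)))
  ok_min <- n_tr >= min_train & n_va >= min_val & n_te >= min_test
  ok_frac <- n_ann <= max_network_fraction * n_net
  keep <- ok_min & ok_frac
  if (!any(keep)) {
    culprit <- if (any(ok_min)) {
      paste0("the max_network_fraction (", max_network_fraction, ") cap")
    } else {
      paste0("the minimum-positive thresholds (", min_train, ", ", min_val,
             ", ", min_test, ")")
    }
    stop("no GO terms survive selection; last terms eliminated by ", culprit)
  }
  terms <- terms[keep]
  pairs <- pairs[pairs$go_term %in% terms, , drop = FALSE]
  # a set's proteins are those with at least one positive among the
  # selected terms, so no label row is all-zero
  label_matrix <- function(set) {
    sub <- pairs[pairs$set == set, , drop = FALSE]
    prot <- sort(unique(sub$protein))
    Y <- matrix(0L, length(prot), length(terms),
                dimnames = list(prot, terms))
    if (nrow(sub))
      Y[cbind(match(sub$protein, prot), match(sub$go_term, terms))] <- 1L
    Y
  }
  Y_tr <- label_matrix("train"); Y_va <- label_matrix("val")
  Y_te <- label_matrix("test")
  structure(list(aspect = if (is.null(aspect)) "ALL" else aspect,
                 go_terms = terms,
                 train_proteins = rownames(Y_tr),
                 val_proteins = rownames(Y_va),
                 test_proteins = rownames(Y_te),
                 Y_train = Y_tr, Y_val = Y_va, Y_test = Y_te),
            class = "dataset_split")
}

#' Merge training and validation sets of a split
#'
#' Returns a new split whose training block is the row-concatenation of the
#' original training and validation blocks (the convention used for the
#' final model fit); the test block and term list are unchanged and the
#' validation block becomes empty.
#'
#' @param split a `dataset_split`.
#' @return a `dataset_split`.
#' @export
merge_train_val <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  split$Y_train <- rbind(split$Y_train, split$Y_val)
  split$train_proteins <- c(split$train_proteins, split$val_proteins)
  split$val_proteins <- character(0)
  split$Y_val <- split$Y_val[0L, , drop = FALSE]
  split
}

#' Write / read a dataset split as plain text
#'
#' The split is stored as one TSV label matrix per set plus a JSON manifest
#' carrying the aspect, the term order and set sizes; reading the directory
#' back reproduces identical matrices and term order.
#'
#' @param split a `dataset_split`.
#' @param dir directory (created if needed).
#' @return `write_split` returns the directory invisibly; `read_split`
#'   returns the restored `dataset_split`.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in c("train", "val", "test")) {
    Y <- split[[paste0("Y_", set)]]
    df <- data.frame(protein = rownames(Y), Y, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("labels_", set, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(aspect = split$aspect, go_terms = split$go_terms,
                   n_train = length(split$train_proteins),
                   n_val = length(split$val_proteins),
                   n_test = length(split$test_proteins))
  jsonlite::write_json(manifest, file.path(dir, "split.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "split.json"),
                                  simplifyVector = TRUE)
  terms <- as.character(manifest$go_terms)
  get <- function(set) {
    df <- utils::read.table(file.path(dir, paste0("labels_", set, ".tsv")),
                            sep = "\t", header = TRUE, check.names = FALSE,
                            colClasses = c("character", rep("integer",
                                                            length(terms))))
    Y <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(Y) <- "integer"
    rownames(Y) <- df$protein
    Y[, terms, drop = FALSE]
  }
  Y_tr <- get("train"); Y_va <- get("val"); Y_te <- get("test")
  structure(list(aspect = manifest$aspect, go_terms = terms,
                 train_proteins = rownames(Y_tr),
                 val_proteins = rownames(Y_va),
                 test_proteins = rownames(Y_te),
                 Y_train = Y_tr, Y_val = Y_va, Y_test = Y_te),
            class = "dataset_split")
}

#' One-shot preprocessing of raw inputs into model-ready matrices
#'
#' Applies the full preparation pipeline: min-max adjacency normalization,
#' attribute bag-of-words with the domain-frequency filter, evidence
#' filtering, temporal split, and GO-term selection.
#'
#' @param network a `ppi_network`.
#' @param domain_annotations,location_annotations data.frames
#'   (protein, term).
#' @param annotations an `annotation_table`.
#' @param aspect GO aspect to model, or `NULL` for all.
#' @param t0,t1 temporal cutoffs.
#' @param allowed_evidence evidence codes to keep.
#' @param min_domain_count domain-frequency filter threshold.
#' @param min_train,min_val,min_test,max_network_fraction GO-term selection
#'   thresholds (see [select_go_terms()]).
#' @return list with `network_features`, `attributes`, `split`, and a
#'   `manifest` of applied filters and counts.
#' @export
preprocess_dataset <- function(network, domain_annotations,
                               location_annotations, annotations,
                               aspect = NULL,
                               t0 = "2018-01-01", t1 = "2020-12-31",
                               allowed_evidence = EXPERIMENTAL_EVIDENCE,
                               min_domain_count = 6L,
                               min_train = 10L, min_val = 5L, min_test = 1L,
                               max_network_fraction = 0.05) {
  net_feat <- normalize_adjacency(network)
  attrs <- build_attribute_matrix(domain_annotations, location_annotations,
                                  network$proteins, min_domain_count)
  filtered <- filter_evidence(annotations, allowed_evidence)
  assignment <- temporal_split(filtered, t0, t1)
  split <- select_go_terms(assignment, filtered, network, aspect,
                           min_train, min_val, min_test,
                           max_network_fraction)
  manifest <- list(
    n_proteins = length(network$proteins),
    n_edges = nrow(network$edges),
    n_annotations_raw = nrow(annotations),
    n_annotations_experimental = nrow(filtered),
    allowed_evidence = allowed_evidence,
    t0 = as.character(t0), t1 = as.character(t1),
    min_domain_count = min_domain_count,
    d2 = ncol(attrs),
    n_domain_terms = attr(attrs, "n_domain"),
    go_term_thresholds = c(min_train, min_val, min_test),
    max_network_fraction = max_network_fraction,
    n_go_terms = length(split$go_terms),
    n_train = length(split$train_proteins),
    n_val = length(split$val_proteins),
    n_test = length(split$test_proteins))
  list(network_features = net_feat, attributes = attrs, split = split,
       manifest = manifest)
}
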
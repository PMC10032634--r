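# Evaluation measures for multi-label protein function prediction.

# step-wise average precision (no interpolation); ties grouped by score
aupr_binary <- function(y, s) {
  y <- as.numeric(y); s <- as.numeric(s)
  pos <- sum(y)
  if (pos == 0) stop("AUPR undefined: no positive labels")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  n <- cumsum(n_g)
  prec <- tp / n
  rec <- tp / pos
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Micro-averaged area under the precision-recall curve
#'
#' The AUPR of the flattened label and score matrices, computed as
#' step-wise average precision with tied scores grouped.
#'
#' @param Y binary label matrix.
#' @param P score matrix, same shape.
#' @return scalar in `[0, 1]`.
#' @export
micro_aupr <- function(Y, P) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  aupr_binary(as.vector(Y), as.vector(P))
}

#' Macro-averaged AUPR over GO terms
#'
#' Unweighted mean of per-term (per-column) AUPRs; columns with no positive
#' protein have undefined AUPR and are excluded (their count is reported in
#' the `n_excluded` attribute).
#'
#' @inheritParams micro_aupr
#' @return scalar in `[0, 1]` with attribute `n_excluded`.
#' @export
macro_aupr <- function(Y, P) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  has_pos <- colSums(Y) > 0
  if (!any(has_pos)) stop("AUPR undefined for every term: no positives")
  vals <- vapply(which(has_pos), function(k) aupr_binary(Y[, k], P[, k]),
                 numeric(1))
  structure(mean(vals), n_excluded = sum(!has_pos), per_term = vals)
}

# top-3 binarization: each protein's three best-scored terms, ties at the
# cut broken deterministically by term (column) order
top3_binarize <- function(P) {
  K <- ncol(P)
  B <- matrix(0L, nrow(P), K, dimnames = dimnames(P))
  for (i in seq_len(nrow(P))) {
    B[i, order(-P[i, ], seq_len(K))[1:3]] <- 1L
  }
  B
}

#' Top-3 micro F1
#'
#' Marks each protein's three highest-scored terms as predicted positives,
#' sums the per-term two-by-two confusion matrices, and returns the
#' harmonic mean of the micro precision and recall on the summed matrix.
#'
#' @inheritParams micro_aupr
#' @return scalar in `[0, 1]`.
#' @export
f1_top3 <- function(Y, P) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (ncol(Y) < 3L) stop("top-3 F1 requires at least 3 GO terms")
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  B <- top3_binarize(P)
  tp <- sum(B == 1 & Y == 1)
  prec <- tp / sum(B)
  rec <- tp / sum(Y)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Exact-match accuracy
#'
#' Fraction of proteins whose thresholded predicted term set
#' (`P >= threshold`) equals the true term set exactly.
#'
#' @inheritParams micro_aupr
#' @param threshold score threshold (default 0.5).
#' @return scalar in `[0, 1]`.
#' @export
accuracy_exact <- function(Y, P, threshold = 0.5) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  pred <- (P >= threshold) * 1L
  mean(rowSums(pred != Y) == 0L)
}

#' Protein-centric Fmax
#'
#' For each threshold on a grid (default 0.01 to 1.00 in steps of 0.01),
#' precision is averaged over the `q(tau)` proteins with at least one score
#' at or above the threshold, recall over all `g` proteins; Fmax is the
#' maximum harmonic mean over thresholds with `q(tau) > 0`.
#'
#' Proteins with no true term contribute zero recall (they remain in `g`);
#' an entirely zero label matrix is an error.
#'
#' @inheritParams micro_aupr
#' @param tau_grid vector of thresholds to scan.
#' @return list with `fmax` and the maximizing threshold `tau`.
#' @export
fmax <- function(Y, P, tau_grid = seq(0.01, 1, by = 0.01)) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) stop("Y and P must have the same shape")
  if (sum(Y) == 0) stop("Fmax undefined: label matrix has no positives")
  g <- nrow(Y)
  npos <- rowSums(Y)
  best <- -Inf; best_tau <- NA_real_
  any_q <- FALSE
  for (tau in tau_grid) {
    predicted <- P >= tau
    n_pred <- rowSums(predicted)
    covered <- n_pred > 0
    q <- sum(covered)
    if (q == 0) next
    any_q <- TRUE
    tp <- rowSums(predicted & (Y == 1))
    pr <- mean(tp[covered] / n_pred[covered])
    rc_i <- ifelse(npos > 0, tp / npos, 0)
    rc <- mean(rc_i)
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best) { best <- f; best_tau <- tau }
  }
  if (!any_q)
    stop("Fmax undefined: no protein reaches any threshold on the grid")
  list(fmax = best, tau = best_tau)
}

#' Cluster proteins by exact GO-term set
#'
#' Two proteins belong to the same cluster iff their annotated term sets
#' are identical; proteins with empty term sets are excluded.
#'
#' @param Y binary label matrix with protein rownames.
#' @return named integer vector protein -> cluster id.
#' @export
cluster_by_term_set <- function(Y) {
  Y <- as.matrix(Y)
  nz <- rowSums(Y) > 0
  Y <- Y[nz, , drop = FALSE]
  key <- apply(Y, 1L, paste, collapse = "")
  ids <- match(key, unique(key))
  stats::setNames(ids, rownames(Y))
}

#' Davies-Bouldin index of a clustered embedding
#'
#' `(1/k) sum_i max_{j != i} (s_i + s_j) / d_ij` with `s_i` the mean
#' Euclidean distance of cluster i's members to their centroid and `d_ij`
#' the centroid distance. Lower is better; 0 when every member sits on its
#' (distinct) centroid.
#'
#' @param embeddings numeric matrix, proteins in rows (rownames used to
#'   match `clusters`).
#' @param clusters named vector protein -> cluster id, e.g. from
#'   [cluster_by_term_set()].
#' @return scalar `>= 0`.
#' @export
davies_bouldin <- function(embeddings, clusters) {
  embeddings <- as.matrix(embeddings)
  if (!is.null(rownames(embeddings)) && !is.null(names(clusters)))
    embeddings <- embeddings[names(clusters), , drop = FALSE]
  ids <- unique(clusters)
  k <- length(ids)
  if (k < 2L) stop("Davies-Bouldin index requires at least 2 clusters")
  cent <- matrix(0, k, ncol(embeddings))
  s <- numeric(k)
  for (i in seq_len(k)) {
    M <- embeddings[clusters == ids[i], , drop = FALSE]
    cent[i, ] <- colMeans(M)
    s[i] <- mean(sqrt(rowSums((M - rep(cent[i, ], each = nrow(M)))^2)))
  }
  R <- numeric(k)
  for (i in seq_len(k)) {
    d <- sqrt(rowSums((cent - rep(cent[i, ], each = k))^2))
    R[i] <- max((s[i] + s[-i]) / d[-i])
  }
  mean(R)
}

#' Full evaluation report
#'
#' Computes every prediction measure (micro/macro AUPR, top-3 F1,
#' exact-match accuracy, Fmax with its threshold) and, when an embedding is
#' supplied, the Davies-Bouldin index over term-set clusters.
#'
#' @param Y binary label matrix (test proteins x K).
#' @param P score matrix, same shape.
#' @param embeddings optional protein embedding matrix for the
#'   Davies-Bouldin index.
#' @return list of class `crossfuse_eval`.
#' @export
evaluate_predictions <- function(Y, P, embeddings = NULL) {
  fm <- fmax(Y, P)
  ma <- macro_aupr(Y, P)
  out <- list(m_aupr = micro_aupr(Y, P),
              M_aupr = as.numeric(ma),
              n_terms_excluded = attr(ma, "n_excluded"),
              f1_top3 = f1_top3(Y, P),
              acc = accuracy_exact(Y, P),
              fmax = fm$fmax, fmax_tau = fm$tau,
              per_term_aupr = attr(ma, "per_term"))
  if (!is.null(embeddings)) {
    cl <- cluster_by_term_set(Y)
    if (length(unique(cl)) >= 2L)
      out$davies_bouldin <- davies_bouldin(embeddings, cl)
  }
  class(out) <- "crossfuse_eval"
  out
}

#' @export
print.crossfuse_eval <- function(x, ...) {
  cat("Protein function prediction evaluation\n")
  cat(sprintf("  m-AUPR: %.4f   M-AUPR: %.4f   F1(top-3): %.4f\n",
              x$m_aupr, x$M_aupr, x$f1_top3))
  cat(sprintf("  ACC: %.4f   Fmax: %.4f (tau = %.2f)\n",
              x$acc, x$fmax, x$fmax_tau))
  if (!is.null(x$davies_bouldin))
    cat(sprintf("  Davies-Bouldin: %.4f\n", x$davies_bouldin))
  invisible(x)
}
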
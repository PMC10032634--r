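# Literal, loop-based transcriptions of the printed formulas. These stay
# deliberately naive and independent of the package's vectorized paths.

oracle_gelu <- function(x) 0.5 * x * (1 + pracma::erf(x / sqrt(2)))

oracle_layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  g * (x - mu) / sqrt(v + eps) + b
}

# softmax(Q K' / sqrt(dk)) V with explicit loops
oracle_sdpa <- function(Q, K, V) {
  S <- nrow(Q); dk <- ncol(K)
  W <- matrix(0, S, nrow(K))
  for (i in seq_len(S)) {
    logits <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(logits - max(logits))
    W[i, ] <- e / sum(e)
  }
  out <- matrix(0, S, ncol(V))
  for (i in seq_len(S))
    for (j in seq_len(nrow(V)))
      out[i, ] <- out[i, ] + W[i, j] * V[j, ]
  list(output = out, weights = W)
}

# concatenate-and-project with explicit per-head slicing
oracle_mha <- function(Q, K, V, params, config) {
  n <- config$n_heads; dk <- config$dk
  heads <- NULL
  for (j in seq_len(n)) {
    blk <- ((j - 1) * dk + 1):(j * dk)
    h <- oracle_sdpa(Q %*% params$Wq[, blk, drop = FALSE],
                     K %*% params$Wk[, blk, drop = FALSE],
                     V %*% params$Wv[, blk, drop = FALSE])$output
    heads <- cbind(heads, h)
  }
  heads %*% params$Wo
}

# W2' f(W1' h + b1) + b2 with explicit double loops and reference GELU
oracle_ffn <- function(h, params) {
  dff <- length(params$b1); d <- length(params$b2)
  a <- numeric(dff)
  for (j in seq_len(dff)) a[j] <- sum(h * params$W1[, j]) + params$b1[j]
  z <- oracle_gelu(a)
  out <- numeric(d)
  for (j in seq_len(d)) out[j] <- sum(z * params$W2[, j]) + params$b2[j]
  out
}

# source MLP f(LN(W2 f(LN(W1 x + b1)) + b2)) step by step
oracle_mlp_project <- function(x, p) {
  a1 <- as.vector(x %*% p$W1) + p$b1
  z1 <- oracle_gelu(oracle_layer_norm(a1, p$ln1_g, p$ln1_b))
  a2 <- as.vector(z1 %*% p$W2) + p$b2
  oracle_gelu(oracle_layer_norm(a2, p$ln2_g, p$ln2_b))
}

# triple-loop summed BCE, mean over proteins
oracle_reconstruction_loss <- function(Xs, Xhats, eps = 1e-7) {
  N <- nrow(Xs[[1]])
  total <- 0
  for (i in seq_len(N))
    for (m in seq_along(Xs))
      for (j in seq_len(ncol(Xs[[m]]))) {
        x <- Xs[[m]][i, j]
        xh <- min(max(Xhats[[m]][i, j], eps), 1 - eps)
        total <- total - (x * log(xh) + (1 - x) * log(1 - xh))
      }
  total / N
}

# double-loop asymmetric loss
oracle_asl <- function(Y, P, gp, gn, eps = 1e-7) {
  total <- 0
  for (i in seq_len(nrow(Y)))
    for (k in seq_len(ncol(Y))) {
      p <- min(max(P[i, k], eps), 1 - eps)
      total <- total - Y[i, k] * (1 - p)^gp * log(p) -
        (1 - Y[i, k]) * p^gn * log(1 - p)
    }
  total / (nrow(Y) * ncol(Y))
}

# exhaustive threshold-sweep AUPR over all distinct scores
oracle_aupr <- function(y, s) {
  ths <- sort(unique(s), decreasing = TRUE)
  pos <- sum(y)
  prev_rec <- 0
  area <- 0
  for (t in ths) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / pos
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# brute-force top-3 confusion-matrix F1
oracle_f1_top3 <- function(Y, P) {
  N <- nrow(Y); K <- ncol(Y)
  B <- matrix(0, N, K)
  for (i in seq_len(N)) {
    r <- rank(-P[i, ], ties.method = "first")
    B[i, r <= 3] <- 1
  }
  TP <- 0; FP <- 0; FN <- 0
  for (k in seq_len(K)) {
    TP <- TP + sum(B[, k] == 1 & Y[, k] == 1)
    FP <- FP + sum(B[, k] == 1 & Y[, k] == 0)
    FN <- FN + sum(B[, k] == 0 & Y[, k] == 1)
  }
  prec <- TP / (TP + FP); rec <- TP / (TP + FN)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# literal evaluation of the protein-centric precision/recall at each tau
oracle_fmax <- function(Y, P, grid = seq(0.01, 1, by = 0.01)) {
  g <- nrow(Y)
  best <- -Inf; best_tau <- NA
  for (tau in grid) {
    q_set <- which(apply(P, 1, max) >= tau)
    if (length(q_set) == 0) next
    prs <- numeric(length(q_set))
    for (ii in seq_along(q_set)) {
      i <- q_set[ii]
      prs[ii] <- sum(P[i, ] >= tau & Y[i, ] == 1) / sum(P[i, ] >= tau)
    }
    rcs <- numeric(g)
    for (i in seq_len(g)) {
      npos <- sum(Y[i, ] == 1)
      rcs[i] <- if (npos > 0) sum(P[i, ] >= tau & Y[i, ] == 1) / npos else 0
    }
    pr <- mean(prs); rc <- mean(rcs)
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best) { best <- f; best_tau <- tau }
  }
  list(fmax = best, tau = best_tau)
}

# textbook Davies-Bouldin with explicit loops
oracle_db <- function(X, cl) {
  ids <- unique(cl)
  k <- length(ids)
  cent <- list(); s <- numeric(k)
  for (i in seq_len(k)) {
    M <- X[cl == ids[i], , drop = FALSE]
    cent[[i]] <- colMeans(M)
    dd <- 0
    for (r in seq_len(nrow(M))) dd <- dd + sqrt(sum((M[r, ] - cent[[i]])^2))
    s[i] <- dd / nrow(M)
  }
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (s[i] + s[j]) / dij)
    }
    total <- total + best
  }
  total / k
}

rand_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc), nr, nc)
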
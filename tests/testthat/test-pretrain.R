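test_that("source MLP projection follows its formula", {
  mdl <- model_config(d = 4, de = 6, n_heads = 1, d_ff = 8, L = 0, dh = 4)
  set.seed(23)
  p <- init_source_mlp_for_test <- crossfuseGO:::init_source_mlp(10, 6, 4)
  # all-zero weights and input: LN of a constant vector maps to 0
  p0 <- rapply(p, function(x) x * 0, how = "replace")
  p0$ln1_g <- rep(1, 6); p0$ln2_g <- rep(1, 4)
  expect_equal(mlp_project(numeric(10), p0), numeric(4))
  # determinism with dropout off
  x <- runif(10)
  expect_identical(mlp_project(x, p), mlp_project(x, p))
  # step-by-step oracle with reference layer norm and erf GELU
  expect_equal(mlp_project(x, p), oracle_mlp_project(x, p),
               tolerance = 1e-10)
})

test_that("encoding with an empty attention stack is the bare projection", {
  mdl <- model_config(d = 4, de = 6, n_heads = 1, d_ff = 8, L = 0, dh = 4)
  set.seed(29)
  enc <- init_encoder(c(7L, 5L), mdl)
  x1 <- runif(7); x2 <- runif(5)
  h <- encode(x1, x2, enc, mdl)
  expect_equal(h$h1, mlp_project(x1, enc$mlps[[1]]))
  expect_equal(h$h2, mlp_project(x2, enc$mlps[[2]]))
})

test_that("encoding equals the manual MLP + attention-layer composition", {
  mdl <- model_config(d = 8, de = 6, n_heads = 2, d_ff = 12, L = 2, dh = 4)
  set.seed(29)
  enc <- init_encoder(c(7L, 5L), mdl)
  x1 <- runif(7); x2 <- runif(5)
  tokens <- rbind(mlp_project(x1, enc$mlps[[1]]),
                  mlp_project(x2, enc$mlps[[2]]))
  for (l in 1:2) tokens <- attention_layer(tokens, enc$layers[[l]], mdl$attn)
  h <- encode(x1, x2, enc, mdl)
  expect_equal(h$h1, tokens[1, ], tolerance = 1e-10)
  expect_equal(h$h2, tokens[2, ], tolerance = 1e-10)
})

test_that("decoder reconstructions are sigmoid-bounded", {
  mdl <- model_config(d = 4, de = 6, n_heads = 1, d_ff = 8, L = 0, dh = 4)
  set.seed(31)
  dec <- init_decoder(c(7L, 5L), mdl)
  h <- list(h1 = rnorm(4), h2 = rnorm(4))
  out <- decode(h, dec, mdl)
  expect_true(all(out$x1hat > 0 & out$x1hat < 1))
  expect_true(all(out$x2hat > 0 & out$x2hat < 1))
  # zero inverse MLPs reconstruct sigmoid(0) = 0.5 everywhere
  dec0 <- dec
  dec0$mlps <- rapply(dec0$mlps, function(x) x * 0, how = "replace")
  for (s in 1:2) {
    dec0$mlps[[s]]$ln1_g <- rep(1, 6)
  }
  out0 <- decode(h, dec0, mdl)
  expect_equal(out0$x1hat, rep(0.5, 7))
  expect_equal(out0$x2hat, rep(0.5, 5))
})

test_that("decoding equals the manual attention + inverse-MLP composition", {
  mdl <- model_config(d = 8, de = 6, n_heads = 2, d_ff = 12, L = 1, dh = 4)
  set.seed(31)
  dec <- init_decoder(c(7L, 5L), mdl)
  h <- list(h1 = rnorm(8), h2 = rnorm(8))
  tokens <- attention_layer(rbind(h$h1, h$h2), dec$layers[[1]], mdl$attn)
  inv <- function(hh, p) {
    a1 <- as.vector(hh %*% p$W1) + p$b1
    z <- oracle_gelu(oracle_layer_norm(a1, p$ln1_g, p$ln1_b))
    1 / (1 + exp(-(as.vector(z %*% p$W2) + p$b2)))
  }
  out <- decode(h, dec, mdl)
  expect_equal(out$x1hat, inv(tokens[1, ], dec$mlps[[1]]), tolerance = 1e-8)
  expect_equal(out$x2hat, inv(tokens[2, ], dec$mlps[[2]]), tolerance = 1e-8)
})

test_that("reconstruction loss matches analytic and loop-oracle values", {
  # x = [1, 0] against 0.5 gives 2 ln 2
  expect_equal(reconstruction_loss(matrix(c(1, 0), 1), matrix(0.5, 1, 2)),
               2 * log(2))
  # reconstructing the (clipped) truth gives ~0
  X <- matrix(c(1, 0, 1, 1), 2)
  expect_lt(reconstruction_loss(X, crossfuseGO:::clip_prob(X)), 1e-5)
  # triple-loop oracle on a random instance, two sources
  set.seed(37)
  X1 <- matrix(rbinom(40, 1, 0.5), 5); X1h <- matrix(runif(40), 5)
  X2 <- matrix(rbinom(15, 1, 0.5), 5); X2h <- matrix(runif(15), 5)
  expect_equal(reconstruction_loss(X1, X1h, X2, X2h),
               oracle_reconstruction_loss(list(X1, X2), list(X1h, X2h)),
               tolerance = 1e-12)
  # linearity: equals the mean over proteins of per-protein BCE sums
  per_row <- vapply(1:5, function(i) {
    oracle_reconstruction_loss(list(X1[i, , drop = FALSE],
                                    X2[i, , drop = FALSE]),
                               list(X1h[i, , drop = FALSE],
                                    X2h[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(reconstruction_loss(X1, X1h, X2, X2h), mean(per_row),
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  mdl <- model_config(d = 8, de = 6, n_heads = 2, d_ff = 10, L = 2, dh = 4)
  set.seed(41)
  N <- 6
  X1 <- matrix(runif(N * 9), N)
  X2 <- matrix(rbinom(N * 5, 1, 0.4), N)
  enc <- init_encoder(c(9L, 5L), mdl)
  dec <- init_decoder(c(9L, 5L), mdl)
  bg <- crossfuseGO:::pretrain_batch_grad(list(X1, X2), enc, dec, mdl,
                                          training = FALSE)
  lossfun <- function(enc, dec) {
    crossfuseGO:::pretrain_batch_grad(list(X1, X2), enc, dec, mdl,
                                      training = FALSE)$loss
  }
  eps <- 1e-5
  check <- function(tree, grads, other, enc_side) {
    paths <- sample(names(crossfuseGO:::tree_leaves(grads)), 5)
    for (pth in paths) {
      leaf <- crossfuseGO:::tree_get(tree, pth)
      i <- sample(length(leaf), 1)
      up <- leaf; up[i] <- up[i] + eps
      dn <- leaf; dn[i] <- dn[i] - eps
      tu <- crossfuseGO:::tree_set(tree, pth, up)
      td <- crossfuseGO:::tree_set(tree, pth, dn)
      num <- if (enc_side) (lossfun(tu, other) - lossfun(td, other)) / (2 * eps)
      else (lossfun(other, tu) - lossfun(other, td)) / (2 * eps)
      ana <- crossfuseGO:::tree_get(grads, pth)[i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4)
    }
  }
  check(enc, bg$g_enc, dec, TRUE)
  check(dec, bg$g_dec, enc, FALSE)
})

test_that("pre-training honours the zero-epoch and determinism contracts", {
  mdl <- model_config(d = 8, de = 6, n_heads = 2, d_ff = 10, L = 1, dh = 4)
  set.seed(43)
  X1 <- matrix(runif(40 * 12), 40)
  X2 <- matrix(rbinom(40 * 6, 1, 0.3), 40)
  # zero epochs: parameters equal the seeded initialization, empty history
  p0 <- pretrain(X1, X2, mdl, pretrain_config(epochs = 0, seed = 5))
  set.seed(5)
  expect_equal(p0$encoder, init_encoder(c(12L, 6L), mdl))
  expect_length(p0$history, 0)
  # identical seeds give bit-identical loss histories
  cfg <- pretrain_config(epochs = 8, batch_size = 16, lr_phase1 = 1e-3,
                         lr_phase2 = 1e-3, phase1_epochs = 4, seed = 11)
  r1 <- pretrain(X1, X2, mdl, cfg)
  r2 <- pretrain(X1, X2, mdl, cfg)
  expect_identical(r1$history, r2$history)
  expect_length(r1$history, 8)
})

test_that("pre-training reduces the reconstruction loss", {
  run <- desk_recovery_run()
  hist <- run$pre$history
  expect_length(hist, 200)
  expect_lt(hist[length(hist)], hist[1])
})

test_that("checkpoints round-trip to identical encodings", {
  run <- desk_recovery_run()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(run$pre, path)
  back <- load_checkpoint(path)
  x1 <- run$prep$network_features[1, ]
  x2 <- run$prep$attributes[1, ]
  expect_identical(encode(x1, x2, back$encoder, back$model),
                   encode(x1, x2, run$pre$encoder, run$pre$model))
})
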
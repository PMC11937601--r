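# Fusion core: token assembly, windowed attention (with the dense-attention
# keystone equivalence), shifted layers, and the classification head.

test_that("token assembly yields N = image tokens + 3 pooled tokens at dim 96", {
  set.seed(20)
  fus <- fusion_core(dims = list(image = 64, clinical = 32, report = 32,
                                 numeric = 32),
                     n_image_tokens = 49, D = 96, heads = 3, dk = 32,
                     M = 13, n_layers = 2)
  expect_equal(fus$n_tokens, 52)
  expect_equal(fus$n_padded, 52)
  bo1 <- list(image = matrix(rnorm(49 * 64), 49, 64),
              clinical = rnorm(32), report = rnorm(32), numeric = rnorm(32))
  H0 <- project_and_assemble(fus, bo1)
  expect_equal(dim(H0), c(52, 96))
  # zero projections and type embeddings -> all tokens zero
  for (p in fus$params[1:4]) p$value <- p$value * 0
  fus$type_emb$value <- fus$type_emb$value * 0
  expect_equal(project_and_assemble(fus, bo1), matrix(0, 52, 96))
  # minimal sequence: numeric only
  fn <- fusion_core(dims = list(numeric = 32), n_image_tokens = 0,
                    modalities = "numeric", M = 4, n_layers = 2)
  expect_equal(fn$n_tokens, 1)
  expect_error(fusion_core(dims = list(), n_image_tokens = 0,
                           modalities = character(0)), "masked")
})

test_that("window attention matches the dense oracle when M >= N", {
  set.seed(21)
  H <- matrix(rnorm(9 * 8), 9, 8)
  wq <- matrix(rnorm(64), 8, 8); wk <- matrix(rnorm(64), 8, 8)
  wv <- matrix(rnorm(64), 8, 8)
  got <- window_attention(H, wq, wk, wv, M = 16, heads = 1)
  want <- oracle_dense_attention(H, wq, wk, wv)
  expect_lt(max(abs(got - want)), 1e-5)
  expect_error(window_attention(H, wq, wk, wv, M = 4, heads = 3), "divide")
})

test_that("zero query/key projections give window-mean outputs", {
  set.seed(22)
  H <- matrix(rnorm(8 * 6), 8, 6)
  wv <- matrix(rnorm(36), 6, 6)
  z <- matrix(0, 6, 6)
  out <- window_attention(H, z, z, wv, M = 4, heads = 1)
  V <- H %*% wv
  for (w in 1:2) {
    rows <- (w - 1) * 4 + 1:4
    for (r in rows) expect_equal(out[r, ], colMeans(V[rows, ]))
  }
})

test_that("a two-token window with scores (0, ln 3) weighs 0.25 / 0.75", {
  # from the first token's view: softmax(0, ln 3) = (1, 3)/4
  s <- c(0, log(3))
  a <- exp(s) / sum(exp(s))
  expect_equal(a, c(0.25, 0.75))
  # realize those scores through the attention: Q row 1 = 1, K = scores
  dk <- 1
  H <- matrix(c(1, 1), 2, 1)
  wq <- matrix(1, 1, 1); wv <- matrix(1, 1, 1)
  # K must produce (0, ln 3) * sqrt(dk) as H %*% wk per token: use V trick
  K <- matrix(c(0, log(3)), 2, 1)
  out <- softmax_rows(matrix((H %*% wq) %*% t(K) / sqrt(dk), 2, 2))
  expect_equal(out[1, ], c(0.25, 0.75))
})

test_that("swin layers are residual-identity when zeroed and invert their shift", {
  set.seed(23)
  B <- 2; Np <- 8; D <- 6
  sl <- swin_layer(D = D, heads = 2, dk = 3, M = 4, shifted = TRUE,
                   shift = 2, ffn_hidden = 8)
  for (p in c(sl$msa$params, sl$fc1$params, sl$fc2$params)) {
    p$value <- p$value * 0
  }
  X <- matrix(rnorm(B * Np * D), B * Np, D)
  mask <- rep(TRUE, B * Np)
  expect_equal(sl$forward(X, mask, B, Np), X)   # exact round-trip identity
})

test_that("shifted layers propagate perturbations across window boundaries", {
  set.seed(24)
  B <- 1; Np <- 8; D <- 6; M <- 4
  layers <- list(
    swin_layer(D, heads = 2, dk = 3, M = M, shifted = FALSE, ffn_hidden = 8),
    swin_layer(D, heads = 2, dk = 3, M = M, shifted = TRUE, shift = 2,
               ffn_hidden = 8))
  run <- function(X) {
    mask <- rep(TRUE, Np)
    for (s in layers) X <- s$forward(X, mask, B, Np)
    X
  }
  X <- matrix(rnorm(Np * D), Np, D)
  X2 <- X; X2[2, ] <- X2[2, ] + 1   # perturb inside window 1
  d1 <- rowSums(abs(run(X2) - run(X)))
  expect_gt(max(d1[5:8]), 0)        # reaches window 2 after the shifted layer
  # one regular layer alone keeps the perturbation inside its window
  d0 <- rowSums(abs(layers[[1]]$forward(X2, rep(TRUE, Np), B, Np) -
                      layers[[1]]$forward(X, rep(TRUE, Np), B, Np)))
  expect_equal(max(d0[5:8]), 0)
})

test_that("attention score arrays stay per-window sized (complexity bound)", {
  set.seed(25)
  B <- 2; Np <- 12; M <- 4; D <- 6
  msa <- nn_wmsa(D, heads = 2, dk = 3, M = M)
  X <- matrix(rnorm(B * Np * D), B * Np, D)
  invisible(msa$forward(X, rep(TRUE, B * Np), B, Np))
  for (ca in msa$last_attention) {
    expect_lte(length(ca$A) / B, M^2)   # per head, per sample: <= M^2 scores
  }
  expect_equal(length(msa$last_attention), (Np / M) * 2)  # windows x heads
})

test_that("window outputs are permutation-equivariant within a window", {
  set.seed(26)
  msa <- nn_wmsa(6, heads = 2, dk = 3, M = 4)
  Np <- 8; B <- 1
  X <- matrix(rnorm(Np * 6), Np, 6)
  out <- msa$forward(X, rep(TRUE, Np), B, Np)
  p <- c(3, 1, 4, 2)                       # permute window 1 tokens
  Xp <- X; Xp[1:4, ] <- X[p, ]
  outp <- msa$forward(Xp, rep(TRUE, Np), B, Np)
  expect_equal(outp[1:4, ], out[p, ], tolerance = 1e-12)
  expect_equal(outp[5:8, ], out[5:8, ], tolerance = 1e-12)
})

test_that("the classification head pools, maps, and normalizes", {
  hp <- list(W = matrix(0, 96, 5), b = rep(0, 5))
  r <- classify(matrix(0, 10, 96), hp)
  expect_equal(r$probabilities, rep(0.2, 5))
  # hand softmax of logits (1, 0, 0, 0, 0)
  hp2 <- list(W = matrix(0, 4, 5), b = c(1, 0, 0, 0, 0))
  r2 <- classify(matrix(0, 3, 4), hp2)
  expect_equal(r2$probabilities[1], exp(1) / (exp(1) + 4))
  expect_equal(r2$probabilities[1], 0.4046, tolerance = 1e-4)
  set.seed(27)
  hp3 <- list(W = matrix(rnorm(96 * 5), 96, 5), b = rnorm(5))
  r3 <- classify(matrix(rnorm(5 * 96), 5, 96), hp3)
  expect_lt(abs(sum(r3$probabilities) - 1), 1e-6)
  expect_equal(r3$label, which.max(r3$logits))
})

test_that("the assembled model is deterministic and finite in eval mode", {
  set.seed(28)
  model <- build_model(model_config("desk64"))
  smp <- tiny_samples(4)
  std <- fit_standardizer(t(vapply(smp, `[[`, numeric(15), "labs")))
  ok <- 0
  for (i in seq_len(min(20, length(smp)))) {
    b <- prepare_batch(smp[i], std)
    l1 <- model$forward(b)
    l2 <- model$forward(b)
    if (all(is.finite(l1)) && identical(l1, l2)) ok <- ok + 1
  }
  expect_equal(ok, 20)
})
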
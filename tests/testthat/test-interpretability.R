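# Interpretability: Grad-CAM contracts, attention export normalization, and
# occlusion-based modality contributions.

test_that("Grad-CAM respects its contract and the null-gradient case", {
  set.seed(60)
  model <- build_model(model_config("desk64"))
  smp <- tiny_samples(3)
  std <- fit_standardizer(t(vapply(smp, `[[`, numeric(15), "labs")))
  hm <- grad_cam(model, smp[[1]], std = std)
  expect_equal(dim(hm$values), dim(smp[[1]]$image))
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  expect_true(max(hm$values) %in% c(0, 1))   # max-normalized unless empty
  # zero classification head -> zero gradients -> all-zero heatmap
  model$fusion$head$W$value <- model$fusion$head$W$value * 0
  model$fusion$head$b$value <- model$fusion$head$b$value * 0
  hm0 <- grad_cam(model, smp[[1]], std = std)
  expect_equal(max(hm0$values), 0)
  expect_error(grad_cam(model, smp[[1]], std = std, layer_tag = "stem"),
               "layer_tag")
  m2 <- build_model(model_config("desk64", modalities = "numeric"))
  expect_error(grad_cam(m2, smp[[1]], std = std), "no image branch")
})

test_that("exported attention rows are normalized with token indices attached", {
  set.seed(61)
  model <- build_model(model_config("desk64"))
  smp <- tiny_samples(3)
  std <- fit_standardizer(t(vapply(smp, `[[`, numeric(15), "labs")))
  ea <- export_attention(model, smp[[1]], std)
  for (L in ea$fusion) {
    for (w in L$windows) {
      expect_true(all(abs(rowSums(w$weights) - 1) < 1e-6))
      expect_true(all(w$tokens >= 1 &
                        w$tokens <= model$fusion$n_tokens))
    }
  }
  for (al in ea$text_alpha) {
    expect_lt(abs(sum(al) - 1), 1e-6)
  }
})

test_that("single-token text yields a unit attention weight", {
  set.seed(62)
  lex <- load_lexicon()
  br <- text_branch(length(lex) + 2L, d_embed = 16, h_per_dir = 8,
                    d_out = 8, max_len = 16)
  r <- text_forward(br, 5L)
  expect_equal(r$alpha, 1)
})

test_that("occlusion contributions are normalized, non-negative, order-invariant", {
  set.seed(63)
  model <- build_model(model_config("desk64"))
  smp <- tiny_samples(4)
  std <- fit_standardizer(t(vapply(smp, `[[`, numeric(15), "labs")))
  mc <- suppressWarnings(modality_contribution(model, smp[1:15], std))
  expect_lt(abs(sum(mc$fractions) - 1), 1e-6)
  expect_true(all(mc$fractions >= 0))
  expect_equal(mc$method, "occlusion")
  # arithmetic identity with the recorded accuracies
  delta <- pmax(mc$accuracy_full - mc$accuracy_without, 0)
  if (sum(delta) > 0) {
    expect_equal(unname(mc$fractions), unname(delta / sum(delta)))
  }
  # occluding in any order: recomputation gives the identical fractions
  mc2 <- suppressWarnings(modality_contribution(model, smp[1:15], std))
  expect_equal(mc$fractions, mc2$fractions)
})

test_that("masking dropped tokens renormalizes attention over the rest", {
  set.seed(64)
  # dense attention restricted to a subset equals softmax renormalization
  H <- matrix(rnorm(6 * 4), 6, 4)
  wq <- matrix(rnorm(16), 4, 4); wk <- matrix(rnorm(16), 4, 4)
  wv <- diag(4)
  keep <- c(1, 2, 4, 5, 6)
  full_S <- (H %*% wq) %*% t(H %*% wk) / 2
  A_manual <- softmax_rows(full_S[keep, keep])
  got <- window_attention(H[keep, ], wq, wk, wv, M = 8, heads = 1)
  expect_equal(got, A_manual %*% H[keep, ] %*% wv, tolerance = 1e-10)
})
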
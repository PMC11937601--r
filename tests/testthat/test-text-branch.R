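# Text branch: positional encoding closed form, attention pooling, and the
# encoder forward contract.

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(4, 4)
  expect_equal(pe[1, ], c(0, 1, 0, 1))                    # position 0
  expect_equal(pe[2, 1:2], c(sin(1), cos(1)))
  expect_equal(pe[2, 1], 0.84147, tolerance = 1e-5)
  expect_equal(pe[2, 2], 0.54030, tolerance = 1e-5)
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 4)))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 5), "even")
  # reproducible bit-exactly and injective over positions
  pe512 <- positional_encoding(512, 16)
  expect_identical(pe512, positional_encoding(512, 16))
  expect_equal(anyDuplicated(as.data.frame(pe512)), 0)
})

test_that("attention pooling normalizes and pools as a weighted sum", {
  H <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  W <- matrix(rnorm(3), 3, 1)
  r <- attention_pool(H, W)
  expect_equal(r$alpha, rep(0.25, 4))        # identical rows -> uniform
  expect_equal(r$pooled, c(1, 2, 3))
  # zero scores
  r2 <- attention_pool(matrix(c(1, 0, 0, 1), 2, 2), matrix(0, 2, 1))
  expect_equal(r2$alpha, c(0.5, 0.5))
  # hand softmax of scores (1, 2, 3)
  H3 <- diag(3)
  W3 <- matrix(c(1, 2, 3), 3, 1)   # scores = (1, 2, 3)
  r3 <- attention_pool(H3, W3)
  expect_equal(r3$alpha, exp(1:3) / sum(exp(1:3)))
  expect_equal(r3$alpha, c(0.0900, 0.2447, 0.6652), tolerance = 1e-3)
  pooled_oracle <- numeric(3)
  for (t in 1:3) pooled_oracle <- pooled_oracle + r3$alpha[t] * H3[t, ]
  expect_equal(r3$pooled, pooled_oracle)
  expect_error(attention_pool(matrix(0, 0, 3), W), "empty")
})

test_that("alpha stays on the simplex for random (T, H, W) draws", {
  set.seed(10)
  for (i in 1:1000) {
    T_ <- sample(1:12, 1); d <- sample(2:6, 1)
    r <- attention_pool(matrix(rnorm(T_ * d, sd = 5), T_, d),
                        matrix(rnorm(d), d, 1))
    expect_true(all(r$alpha >= 0))
    expect_lt(abs(sum(r$alpha) - 1), 1e-6)
  }
})

test_that("text encoder honors mode, length, and position sensitivity", {
  set.seed(11)
  lex <- load_lexicon()
  vb <- length(lex) + 2L
  br <- text_branch(vb, d_embed = 16, h_per_dir = 8, d_out = 8,
                    dropout = 0.3, max_len = 32)
  toks <- sample(length(lex), 10)
  # single-token sequence: alpha = 1
  r1 <- text_forward(br, toks[1])
  expect_equal(r1$alpha, 1)
  # eval mode deterministic; dropout mode stochastic
  a <- text_forward(br, toks)$embedding
  b <- text_forward(br, toks)$embedding
  expect_identical(a, b)
  set.seed(1); d1 <- br$forward(matrix(toks, 1), 10, train = TRUE)
  set.seed(2); d2 <- br$forward(matrix(toks, 1), 10, train = TRUE)
  expect_false(isTRUE(all.equal(d1, d2)))
  # position sensitivity from the sinusoidal encoding
  base <- text_forward(br, toks)$embedding
  changed <- 0
  for (k in 1:20) {
    p <- sample(10)
    if (identical(p, 1:10)) next
    e <- text_forward(br, toks[p])$embedding
    if (max(abs(e - base)) > 1e-8) changed <- changed + 1
  }
  expect_gte(changed, 19)
  # errors and truncation
  expect_error(text_forward(br, c(1, vb + 1)), "lexicon")
  expect_warning(br$forward(matrix(rep(1L, 40), 1), 40), "truncating")
})

test_that("clinical and report branches never share parameter storage", {
  set.seed(12)
  m <- build_model(model_config("desk64"))
  for (p in m$clinical$params) {
    for (q in m$report$params) {
      expect_false(identical(p, q))
    }
  }
})
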
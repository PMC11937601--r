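# Image branch: first-layer weight-sum adaptation, depthwise-separable
# factorization, GCSA attention, and the backbone forward contract.

test_that("adapt_conv1 sums input-channel kernels exactly", {
  k <- array(1, c(4, 3, 5, 5))
  expect_equal(adapt_conv1(k), array(3, c(4, 1, 5, 5)))
  a <- array(rnorm(4 * 5 * 5), c(4, 1, 5, 5))
  canc <- array(0, c(4, 3, 5, 5))
  canc[, 1, , ] <- a[, 1, , ]; canc[, 2, , ] <- -a[, 1, , ]
  expect_equal(adapt_conv1(canc), array(0, c(4, 1, 5, 5)))
  set.seed(1)
  k2 <- array(rnorm(64 * 3 * 7 * 7), c(64, 3, 7, 7))
  ref <- array(0, c(64, 1, 7, 7))
  for (o in 1:64) for (i in 1:7) for (j in 1:7) {
    ref[o, 1, i, j] <- k2[o, 1, i, j] + k2[o, 2, i, j] + k2[o, 3, i, j]
  }
  expect_equal(adapt_conv1(k2), ref)
  expect_error(adapt_conv1(array(0, c(4, 2, 3, 3))), "C_out x 3")
})

test_that("depthwise-separable conv factorizes a dense convolution", {
  set.seed(2)
  # identity factorization: centered delta depthwise + identity pointwise
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  kd <- array(0, c(3, 3, 3)); kd[2, 2, ] <- 1
  kp <- diag(3)
  expect_equal(depthwise_separable_conv(x, kd, kp), x, tolerance = 1e-12)
  # closed-form parameter count
  expect_equal(dsc_param_count(64, 64, 3), 64 * 9 + 64 * 64)
  expect_equal(dsc_param_count(64, 64, 3), 4672)
  expect_lt(dsc_param_count(64, 64, 3), 36864)  # dense 3x3 64->64
  # composition equals the dense conv whose kernel is the outer product
  kd <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  kp <- matrix(rnorm(4 * 3), 4, 3)
  dense <- array(0, c(3, 3, 3, 4))
  for (co in 1:4) for (c in 1:3) dense[, , c, co] <- kp[co, c] * kd[, , c]
  got <- depthwise_separable_conv(x, kd, kp, stride = 1, pad = 1)
  want <- oracle_dense_conv(x, dense, stride = 1, pad = 1)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-5)
  expect_error(depthwise_separable_conv(x, array(0, c(3, 3, 2)), kp),
               "per input channel")
})

test_that("channel shuffle is the reshape-transpose permutation", {
  expect_equal(channel_shuffle_perm(4, 1), 1:4)
  # channels (0,1,2,3), groups 2 -> (0,2,1,3); 1-based: (1,3,2,4)
  expect_equal(channel_shuffle_perm(4, 2), c(1, 3, 2, 4))
  # index-arithmetic oracle: output slot i takes channel
  # (i mod g) * (C/g) + floor(i / g), 0-based
  C <- 12; g <- 3
  perm <- channel_shuffle_perm(C, g)
  i <- 0:(C - 1)
  oracle <- (i %% g) * (C %/% g) + i %/% g + 1
  expect_equal(perm, oracle)
  # applying the transposed-group shuffle restores the original order
  expect_equal(channel_shuffle_perm(C, C %/% g)[perm], 1:C)
  expect_error(channel_shuffle_perm(10, 4), "divide")
})

test_that("GCSA preserves shape, attenuates, and gates in (0,1)", {
  set.seed(3)
  g <- gcsa_block(8, reduction = 2, shuffle_groups = 2)
  for (i in 1:100) {
    x <- array(rnorm(5 * 5 * 8 * 1, sd = runif(1, 0.5, 3)), c(5, 5, 8, 1))
    out <- g$forward(x)
    expect_equal(dim(out), dim(x))
    expect_lte(max(abs(out)), max(abs(x)))  # sigmoid gates only attenuate
  }
  st <- g$state
  expect_true(all(st$channel_weights > 0 & st$channel_weights < 1))
  expect_true(all(st$spatial_weights > 0 & st$spatial_weights < 1))
  expect_error(gcsa_block(8, shuffle_groups = 3), "divide")
  # functional wrapper on a single map
  f <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  r <- gcsa(g, f)
  expect_equal(dim(r$out), dim(f))
  expect_named(r$state, c("channel_avg", "channel_max", "channel_weights",
                          "spatial_weights", "shuffle_groups"))
})

test_that("the image branch emits deterministic finite tokens and embeddings", {
  set.seed(4)
  br <- image_branch(input_size = 64, stem_channels = 8, stem_kernel = 5,
                     widths = c(16, 32), strides = c(2, 2),
                     dsc_stages = c(FALSE, TRUE), blocks = c(1, 1),
                     reduction = 4)
  z <- matrix(0, 64, 64)
  o1 <- image_forward(br, z)
  o2 <- image_forward(br, z)
  expect_true(all(is.finite(o1$embedding)) && all(is.finite(o1$tokens)))
  expect_identical(o1, o2)
  expect_equal(dim(o1$tokens), c(br$n_tokens, br$out_channels))
  expect_error(image_forward(br, matrix(0, 32, 32)), "expected 64x64")
  # batching is order-preserving
  x <- array(runif(64 * 64 * 1 * 3), c(64, 64, 1, 3))
  ob <- br$forward(x)
  xp <- x[, , , c(3, 1, 2), drop = FALSE]
  op <- br$forward(xp)
  expect_equal(op$pooled[1, ], ob$pooled[3, ])
  expect_equal(op$tokens[2, , ], ob$tokens[1, , ])
})

test_that("a local patch change moves the aligned token the most", {
  set.seed(6)
  br <- image_branch(input_size = 224, stem_channels = 8, stem_kernel = 7,
                     widths = c(8, 16, 32, 64), strides = c(1, 2, 2, 2),
                     dsc_stages = c(FALSE, FALSE, TRUE, TRUE),
                     blocks = c(1, 1, 1, 1), reduction = 4)
  expect_equal(br$n_tokens, 49)
  img <- matrix(runif(224 * 224), 224, 224)
  img2 <- img
  # perturb a 32x32 patch centered on token (4, 4)'s receptive-field center
  # (pixel 97: inverting the stride chain 2-2-2-2-2 maps token u to pixel
  # 32u - 31 at the first tap, i.e. centers at 97 for u = 4)
  rows <- 81 + 1:32; cols <- 81 + 1:32
  img2[rows, cols] <- runif(32 * 32)
  t1 <- image_forward(br, img)$tokens
  t2 <- image_forward(br, img2)$tokens
  delta <- sqrt(rowSums((t1 - t2)^2))
  # token index for grid (4,4), h-fastest layout over the 7x7 map
  expect_equal(which.max(delta), 3 * 7 + 4)
})

test_that("replacing dense stage convolutions with DSC reduces parameters", {
  set.seed(7)
  n_params <- function(dsc) {
    br <- image_branch(input_size = 64, stem_channels = 8, stem_kernel = 5,
                       widths = c(16, 32), strides = c(2, 2),
                       dsc_stages = c(FALSE, dsc), blocks = c(1, 1),
                       reduction = 4)
    profile_model(br)$params_exact
  }
  expect_lt(n_params(TRUE), n_params(FALSE))
})
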
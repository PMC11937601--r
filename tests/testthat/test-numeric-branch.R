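# Numeric branch: standardization and the residual MLP.

test_that("standardizer computes population moments and guards degeneracy", {
  s <- fit_standardizer(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(s$mean), 2)
  expect_equal(unname(s$sd), sqrt(2 / 3))
  expect_equal(unname(s$sd), 0.8165, tolerance = 1e-4)
  z <- apply_standardizer(s, matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence up to tolerance
  s2 <- fit_standardizer(z)
  expect_equal(unname(s2$mean), 0, tolerance = 1e-12)
  expect_equal(unname(s2$sd), 1, tolerance = 1e-12)
  # constant columns are an error naming the column
  m <- cbind(WBC = c(1, 2, 3), CRP = c(4, 4, 4))
  expect_error(fit_standardizer(m), "CRP")
  expect_error(fit_standardizer(matrix(1, 1, 3)), "at least 2 rows")
  # provenance tag travels with the parameters (leakage audit)
  s3 <- fit_standardizer(matrix(rnorm(30), 10, 3), fitted_on = "fold-2")
  expect_equal(s3$fitted_on, "fold-2")
})

test_that("the residual MLP evaluates its closed form exactly", {
  set.seed(14)
  br <- numeric_branch()
  x <- rnorm(15)
  # residual path isolation: zero the MLP weights
  snap <- params_snapshot(br$params)
  for (p in list(br$fc1$W, br$fc1$b, br$fc2$W, br$fc2$b, br$fc3$W,
                 br$fc3$b)) {
    p$value <- p$value * 0
  }
  y <- numeric_forward(br, x)
  expect_equal(y, as.vector(x %*% br$res$W$value))
  expect_equal(numeric_forward(br, rep(0, 15)), rep(0, 32))
  params_restore(br$params, snap)
  # full equation against the loop oracle
  y2 <- numeric_forward(br, x)
  want <- oracle_residual_mlp(
    x, t(br$fc1$W$value), br$fc1$b$value, t(br$fc2$W$value), br$fc2$b$value,
    t(br$fc3$W$value), br$fc3$b$value, t(br$res$W$value))
  expect_equal(y2, want, tolerance = 1e-6)
  expect_length(y2, 32)
  expect_error(numeric_forward(br, rnorm(10)), "expected input length 15")
})

test_that("shapes follow the stated layer plan (64, 32 hidden; 32 out)", {
  set.seed(15)
  br <- numeric_branch()
  expect_equal(dim(br$fc1$W$value), c(15, 64))
  expect_equal(dim(br$fc2$W$value), c(64, 32))
  expect_equal(dim(br$fc3$W$value), c(32, 32))
  expect_equal(dim(br$res$W$value), c(15, 32))
})

test_that("gradient reaches the residual projection when hidden paths are dead", {
  set.seed(16)
  br <- numeric_branch()
  for (p in list(br$fc1$W, br$fc2$W, br$fc3$W)) p$value <- p$value * 0
  zero_grads(br$params)
  x <- matrix(rnorm(15), 1)
  y <- br$forward(x)
  br$backward(matrix(rnorm(32), 1))
  expect_gt(max(abs(br$res$W$grad)), 0)
})

test_that("eval forward is piecewise linear: directional derivatives match", {
  set.seed(17)
  for (rep in 1:100) {
    br <- numeric_branch(d_in = 5, hidden = c(6, 4), d_out = 4)
    x <- rnorm(5); v <- rnorm(5); v <- v / sqrt(sum(v^2))
    eps <- 1e-6
    fd <- (br$forward(matrix(x + eps * v, 1)) -
             br$forward(matrix(x - eps * v, 1))) / (2 * eps)
    zero_grads(br$params)
    y <- br$forward(matrix(x, 1))
    # analytic Jacobian-vector product by backprop over each output dim
    jv <- numeric(4)
    for (k in 1:4) {
      dy <- matrix(0, 1, 4); dy[k] <- 1
      dx <- br$backward(dy)
      jv[k] <- sum(dx * v)
    }
    expect_equal(as.vector(fd), jv, tolerance = 1e-4)
  }
})
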
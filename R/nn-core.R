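# Minimal trainable-layer framework: every layer is an environment exposing
# forward(x, train)/backward(dy) with a single cached call, plus a flat list of
# parameter environments consumed by the AdamW optimizer. Backward passes are
# hand-derived per layer; there is no tape.

#' @useDynLib pneumodal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

pf_param <- function(value, no_decay = FALSE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$no_decay <- no_decay
  class(p) <- "pf_param"
  p
}

new_layer <- function() {
  l <- new.env(parent = emptyenv())
  l$params <- list()
  class(l) <- "pf_layer"
  l
}

# ---- elementary layers -------------------------------------------------------

nn_linear <- function(d_in, d_out, bias = TRUE, init_sd = sqrt(2 / d_in),
                      no_decay = FALSE) {
  l <- new_layer()
  l$W <- pf_param(matrix(stats::rnorm(d_in * d_out, 0, init_sd), d_in, d_out),
                  no_decay = no_decay)
  l$b <- if (bias) pf_param(numeric(d_out), no_decay = TRUE)
  l$params <- c(list(l$W), if (bias) list(l$b))
  l$forward <- function(x, train = FALSE) {
    l$x <- x
    y <- x %*% l$W$value
    if (!is.null(l$b)) y <- y + rep(l$b$value, rep.int(nrow(y), ncol(y)))
    y
  }
  l$backward <- function(dy) {
    l$W$grad <- l$W$grad + crossprod(l$x, dy)
    if (!is.null(l$b)) l$b$grad <- l$b$grad + colSums(dy)
    tcrossprod(dy, l$W$value)
  }
  l
}

nn_conv2d <- function(c_in, c_out, k, stride = 1, pad = (k - 1) %/% 2,
                      bias = FALSE) {
  l <- new_layer()
  sd <- sqrt(2 / (k * k * c_in))
  l$W <- pf_param(array(stats::rnorm(k * k * c_in * c_out, 0, sd),
                        c(k, k, c_in, c_out)))
  l$b <- if (bias) pf_param(numeric(c_out), no_decay = TRUE)
  l$stride <- stride; l$pad <- pad
  l$params <- c(list(l$W), if (bias) list(l$b))
  l$forward <- function(x, train = FALSE) {
    l$x <- x
    y <- cpp_conv2d_forward(x, l$W$value, l$stride, l$pad)
    if (!is.null(l$b)) {
      d <- dim(y)
      y <- y + rep(rep(l$b$value, rep.int(d[1] * d[2], d[3])), d[4])
      dim(y) <- d
    }
    y
  }
  l$backward <- function(dy) {
    g <- cpp_conv2d_backward(l$x, l$W$value, dy, l$stride, l$pad)
    l$W$grad <- l$W$grad + g$dw
    if (!is.null(l$b)) {
      d <- dim(dy)
      m <- matrix(dy, d[1] * d[2], d[3] * d[4])
      l$b$grad <- l$b$grad + rowSums(matrix(colSums(m), d[3], d[4]))
    }
    g$dx
  }
  l
}

nn_dwconv <- function(c_in, k, stride = 1, pad = (k - 1) %/% 2) {
  l <- new_layer()
  sd <- sqrt(2 / (k * k))
  l$W <- pf_param(array(stats::rnorm(k * k * c_in, 0, sd), c(k, k, c_in)))
  l$stride <- stride; l$pad <- pad
  l$params <- list(l$W)
  l$forward <- function(x, train = FALSE) {
    l$x <- x
    cpp_dwconv_forward(x, l$W$value, l$stride, l$pad)
  }
  l$backward <- function(dy) {
    g <- cpp_dwconv_backward(l$x, l$W$value, dy, l$stride, l$pad)
    l$W$grad <- l$W$grad + g$dw
    g$dx
  }
  l
}

nn_batchnorm2d <- function(c_n, momentum = 0.1, eps = 1e-5) {
  l <- new_layer()
  l$gamma <- pf_param(rep(1, c_n), no_decay = TRUE)
  l$beta <- pf_param(numeric(c_n), no_decay = TRUE)
  l$running_mean <- numeric(c_n)
  l$running_var <- rep(1, c_n)
  l$eps <- eps; l$momentum <- momentum
  l$params <- list(l$gamma, l$beta)
  l$forward <- function(x, train = FALSE) {
    d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    m <- matrix(x, hw, C * N)
    l$train_mode <- train
    if (train) {
      mu <- rowMeans(matrix(colMeans(m), C, N))
      ex2 <- rowMeans(matrix(colMeans(m * m), C, N))
      v <- pmax(ex2 - mu * mu, 0)
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
    } else {
      mu <- l$running_mean
      v <- l$running_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    cmu <- rep(mu, N); cis <- rep(invstd, N)
    xhat <- sweep(sweep(m, 2, cmu, "-"), 2, cis, "*")
    y <- sweep(sweep(xhat, 2, rep(l$gamma$value, N), "*"), 2,
               rep(l$beta$value, N), "+")
    l$xhat <- xhat; l$invstd <- invstd; l$d <- d
    dim(y) <- d
    y
  }
  l$backward <- function(dy) {
    d <- l$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    dym <- matrix(dy, hw, C * N)
    s1 <- rowSums(matrix(colSums(dym), C, N))
    s2 <- rowSums(matrix(colSums(dym * l$xhat), C, N))
    l$beta$grad <- l$beta$grad + s1
    l$gamma$grad <- l$gamma$grad + s2
    if (l$train_mode) {
      M <- hw * N
      coef <- l$gamma$value * l$invstd
      dx <- sweep(dym, 2, rep(s1 / M, N), "-") -
        sweep(l$xhat, 2, rep(s2 / M, N), "*")
      dx <- sweep(dx, 2, rep(coef, N), "*")
    } else {
      dx <- sweep(dym, 2, rep(l$gamma$value * l$invstd, N), "*")
    }
    dim(dx) <- d
    dx
  }
  l
}

nn_layernorm <- function(d_model, eps = 1e-5) {
  l <- new_layer()
  l$gamma <- pf_param(rep(1, d_model), no_decay = TRUE)
  l$beta <- pf_param(numeric(d_model), no_decay = TRUE)
  l$eps <- eps
  l$params <- list(l$gamma, l$beta)
  l$forward <- function(x, train = FALSE) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- xc * invstd
    l$xhat <- xhat; l$invstd <- invstd
    sweep(xhat, 2, l$gamma$value, "*") +
      rep(l$beta$value, rep.int(nrow(x), ncol(x)))
  }
  l$backward <- function(dy) {
    D <- ncol(dy)
    l$beta$grad <- l$beta$grad + colSums(dy)
    l$gamma$grad <- l$gamma$grad + colSums(dy * l$xhat)
    dxhat <- sweep(dy, 2, l$gamma$value, "*")
    (dxhat - rowMeans(dxhat) - l$xhat * rowMeans(dxhat * l$xhat)) * l$invstd
  }
  l
}

nn_relu <- function() {
  l <- new_layer()
  l$forward <- function(x, train = FALSE) {
    l$mask <- x > 0
    x * l$mask
  }
  l$backward <- function(dy) dy * l$mask
  l
}

nn_dropout <- function(p) {
  l <- new_layer()
  l$p <- p
  l$forward <- function(x, train = FALSE) {
    if (train && l$p > 0) {
      l$mask <- (stats::runif(length(x)) >= l$p) / (1 - l$p)
      dim(l$mask) <- dim(x)
      x * l$mask
    } else {
      l$mask <- NULL
      x
    }
  }
  l$backward <- function(dy) if (is.null(l$mask)) dy else dy * l$mask
  l
}

nn_embedding <- function(vocab, d, init_sd = 0.1) {
  l <- new_layer()
  l$W <- pf_param(matrix(stats::rnorm(vocab * d, 0, init_sd), vocab, d),
                  no_decay = TRUE)
  l$params <- list(l$W)
  l$forward <- function(ids, train = FALSE) {
    # ids: N x T integer matrix (1-based); returns array (N, T, d)
    l$ids <- as.vector(ids)
    out <- l$W$value[l$ids, , drop = FALSE]
    array(out, c(nrow(ids), ncol(ids), ncol(l$W$value)))
  }
  l$backward <- function(dy) {
    d3 <- dim(dy)
    dym <- matrix(dy, d3[1] * d3[2], d3[3])
    agg <- rowsum(dym, group = l$ids)
    rows <- as.integer(rownames(agg))
    l$W$grad[rows, ] <- l$W$grad[rows, ] + agg
    NULL
  }
  l
}

nn_maxpool <- function(k = 2, stride = k) {
  l <- new_layer()
  l$forward <- function(x, train = FALSE) {
    l$xdim <- dim(x)
    r <- cpp_maxpool_forward(x, k, stride)
    l$idx <- r$idx
    r$out
  }
  l$backward <- function(dy) cpp_maxpool_backward(dy, l$idx, l$xdim)
  l
}

# Sequential composite over layers that share the (x, train) protocol.
nn_sequential <- function(...) {
  l <- new_layer()
  l$layers <- list(...)
  l$params <- unlist(lapply(l$layers, function(s) s$params), recursive = FALSE)
  l$forward <- function(x, train = FALSE) {
    for (s in l$layers) x <- s$forward(x, train)
    x
  }
  l$backward <- function(dy) {
    for (s in rev(l$layers)) dy <- s$backward(dy)
    dy
  }
  l
}

# ---- losses and math helpers -------------------------------------------------

#' Row-wise numerically stable softmax
#'
#' @param m numeric matrix; softmax is taken over each row.
#' @return matrix of the same shape with rows on the probability simplex.
#' @export
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Mean cross-entropy over a batch; returns loss and dlogits.
ce_loss <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n)
}

# Bilinear resize of a 2-D matrix (used by the image generator and Grad-CAM).
pf_resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

# ---- optimizer ---------------------------------------------------------------

# AdamW with decoupled weight decay; decay skips biases and norm parameters
# (their pf_param carries no_decay = TRUE).
adamw_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  b1t <- 1 - beta1^step
  b2t <- 1 - beta2^step
  for (p in params) {
    if (is.null(p$m)) {
      p$m <- p$value * 0
      p$v <- p$value * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad * p$grad
    if (!isTRUE(p$no_decay)) p$value <- p$value - lr * weight_decay * p$value
    p$value <- p$value - lr * (p$m / b1t) / (sqrt(p$v / b2t) + eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(NULL)
}

clip_global_norm <- function(params, max_norm) {
  tot <- sum(vapply(params, function(p) sum(p$grad^2), numeric(1)))
  nrm <- sqrt(tot)
  if (is.finite(nrm) && nrm > max_norm) {
    sc <- max_norm / (nrm + 1e-12)
    for (p in params) p$grad <- p$grad * sc
  }
  nrm
}

# Snapshot / restore parameter values (checkpointing).
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snap) {
  stopifnot(length(params) == length(snap))
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(NULL)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
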
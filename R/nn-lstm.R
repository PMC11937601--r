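# Bidirectional LSTM with hand-derived backpropagation through time.
# Sequences are arrays (N, T, d); the layer concatenates forward and backward
# hidden states per position into (N, T, 2h).

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_cell <- function(d_in, h) {
  l <- new_layer()
  sdx <- sqrt(1 / d_in); sdh <- sqrt(1 / h)
  l$Wx <- pf_param(matrix(stats::rnorm(d_in * 4 * h, 0, sdx), d_in, 4 * h))
  l$Wh <- pf_param(matrix(stats::rnorm(h * 4 * h, 0, sdh), h, 4 * h))
  b0 <- numeric(4 * h)
  b0[(h + 1):(2 * h)] <- 1  # forget-gate bias init
  l$b <- pf_param(b0, no_decay = TRUE)
  l$h <- h
  l$params <- list(l$Wx, l$Wh, l$b)

  # x: (N, T, d_in); returns (N, T, h); caches per-step activations
  l$forward <- function(x, train = FALSE) {
    d <- dim(x); N <- d[1]; T_ <- d[2]; h <- l$h
    hs <- array(0, c(N, T_, h))
    l$cache <- vector("list", T_)
    hp <- matrix(0, N, h); cp <- matrix(0, N, h)
    bmat <- rep(l$b$value, rep.int(N, 4 * h))
    for (t in seq_len(T_)) {
      xt <- matrix(x[, t, ], N)
      z <- xt %*% l$Wx$value + hp %*% l$Wh$value + bmat
      i <- sigmoid(z[, 1:h, drop = FALSE])
      f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
      g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
      o <- sigmoid(z[, (3 * h + 1):(4 * h), drop = FALSE])
      ct <- f * cp + i * g
      tc <- tanh(ct)
      ht <- o * tc
      l$cache[[t]] <- list(xt = xt, hp = hp, cp = cp, i = i, f = f, g = g,
                           o = o, tc = tc)
      hs[, t, ] <- ht
      hp <- ht; cp <- ct
    }
    l$NT <- c(N, T_, dim(x)[3])
    hs
  }

  l$backward <- function(dhs) {
    N <- l$NT[1]; T_ <- l$NT[2]; din <- l$NT[3]; h <- l$h
    dx <- array(0, c(N, T_, din))
    dh_next <- matrix(0, N, h); dc_next <- matrix(0, N, h)
    dWx <- l$Wx$grad * 0; dWh <- l$Wh$grad * 0; db <- l$b$grad * 0
    for (t in rev(seq_len(T_))) {
      cc <- l$cache[[t]]
      dh <- matrix(dhs[, t, ], N) + dh_next
      do <- dh * cc$tc
      dct <- dh * cc$o * (1 - cc$tc^2) + dc_next
      di <- dct * cc$g
      df <- dct * cc$cp
      dg <- dct * cc$i
      dc_next <- dct * cc$f
      dz <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do * cc$o * (1 - cc$o))
      dWx <- dWx + crossprod(cc$xt, dz)
      dWh <- dWh + crossprod(cc$hp, dz)
      db <- db + colSums(dz)
      dx[, t, ] <- tcrossprod(dz, l$Wx$value)
      dh_next <- tcrossprod(dz, l$Wh$value)
    }
    l$Wx$grad <- l$Wx$grad + dWx
    l$Wh$grad <- l$Wh$grad + dWh
    l$b$grad <- l$b$grad + db
    dx
  }
  l
}

nn_bilstm <- function(d_in, h_per_dir) {
  l <- new_layer()
  l$fwd <- lstm_cell(d_in, h_per_dir)
  l$bwd <- lstm_cell(d_in, h_per_dir)
  l$h <- h_per_dir
  l$params <- c(l$fwd$params, l$bwd$params)
  l$forward <- function(x, train = FALSE) {
    T_ <- dim(x)[2]
    rev_idx <- rev(seq_len(T_))
    hf <- l$fwd$forward(x, train)
    hb <- l$bwd$forward(x[, rev_idx, , drop = FALSE], train)
    l$T_ <- T_
    out <- array(0, c(dim(x)[1], T_, 2 * l$h))
    out[, , 1:l$h] <- hf
    out[, , (l$h + 1):(2 * l$h)] <- hb[, rev_idx, , drop = FALSE]
    out
  }
  l$backward <- function(dy) {
    rev_idx <- rev(seq_len(l$T_))
    dhf <- dy[, , 1:l$h, drop = FALSE]
    dhb <- dy[, rev_idx, (l$h + 1):(2 * l$h), drop = FALSE]
    dxf <- l$fwd$backward(dhf)
    dxb <- l$bwd$backward(dhb)
    dxf + dxb[, rev_idx, , drop = FALSE]
  }
  l
}
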
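# Independent brute-force oracles used across the test files. These stay
# deliberately naive (nested loops, dense algebra) and never call the code
# paths they check.

# dense 2-D convolution by direct summation; x (H,W,C), w (kh,kw,C,Cout)
oracle_dense_conv <- function(x, w, stride = 1, pad = 0) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, c(Ho, Wo, Co))
  for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    for (c in 1:C) for (dh in 1:kh) for (dw in 1:kw) {
      hs <- (ho - 1) * stride - pad + dh
      ws <- (wo - 1) * stride - pad + dw
      if (hs >= 1 && hs <= H && ws >= 1 && ws <= W) {
        acc <- acc + w[dh, dw, c, co] * x[hs, ws, c]
      }
    }
    out[ho, wo, co] <- acc
  }
  out
}

# full self-attention with a plain loop softmax; H (N x d), one head
oracle_dense_attention <- function(H, wq, wk, wv) {
  Q <- H %*% wq; K <- H %*% wk; V <- H %*% wv
  S <- Q %*% t(K) / sqrt(ncol(wq))
  A <- t(apply(S, 1, function(r) { r <- r - max(r); exp(r) / sum(exp(r)) }))
  A %*% V
}

# Eq-by-eq residual MLP: Y = W3 relu(W2 relu(W1 x + b1) + b2) + b3 + Wr x
oracle_residual_mlp <- function(x, W1, b1, W2, b2, W3, b3, Wr) {
  relu <- function(v) pmax(v, 0)
  h1 <- relu(W1 %*% x + b1)
  h2 <- relu(W2 %*% h1 + b2)
  as.vector(W3 %*% h2 + b3 + Wr %*% x)
}
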
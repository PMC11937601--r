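# Fusion core: per-modality linear projection into a shared 96-dim token
# space, a stack of window / shifted-window multi-head self-attention layers
# with feedforward sublayers and residual additions, and a mean-pool +
# linear + softmax classification head.
#
# Token layout: ordered image tokens, pooled clinical token, pooled report
# token, numeric token; windows are contiguous runs of M tokens over this 1-D
# sequence, padded (and masked) to a multiple of M. Batched matrices stack
# samples with rows (sample-major, position fastest).

#' Window-based multi-head self-attention (functional form)
#'
#' Computes `softmax(Q K^T / sqrt(d_k)) V` independently within each window of
#' `M` consecutive tokens. The sequence is zero-padded to a multiple of `M`;
#' pad positions are masked out of every softmax. With `M >= nrow(H)` and one
#' head this is exactly full self-attention.
#'
#' @param H token matrix `N x D`.
#' @param w_q,w_k,w_v projection matrices `D x (heads * d_k)`.
#' @param M window length (tokens per window).
#' @param heads number of attention heads; `ncol(w_q)` must be `heads * d_k`.
#' @return matrix `N x (heads * d_k)` of concatenated per-head outputs.
#' @export
window_attention <- function(H, w_q, w_k, w_v, M, heads = 1) {
  N <- nrow(H); D <- ncol(w_q)
  if (D %% heads != 0) {
    stop("window_attention: heads (", heads, ") must divide the projection ",
         "width (", D, ")")
  }
  dk <- D %/% heads
  Np <- ceiling(N / M) * M
  Hp <- rbind(H, matrix(0, Np - N, ncol(H)))
  valid <- c(rep(TRUE, N), rep(FALSE, Np - N))
  Q <- Hp %*% w_q; K <- Hp %*% w_k; V <- Hp %*% w_v
  out <- matrix(0, Np, D)
  for (w in seq_len(Np %/% M)) {
    rows <- (w - 1) * M + seq_len(M)
    ok <- valid[rows]
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dk)
      S[, !ok] <- -Inf
      S[!ok, ] <- 0
      A <- softmax_rows(S)
      out[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  out[seq_len(N), , drop = FALSE]
}

# Batched windowed MSA layer over padded token matrices.
# X: (B*Np) x D with rows (b-1)*Np + i; mask: logical B*Np (TRUE = real).
nn_wmsa <- function(D, heads, dk, M) {
  if (heads * dk != D) {
    stop("window attention: heads * d_k (", heads * dk,
         ") must equal the token dimension (", D, ")")
  }
  l <- new_layer()
  sd <- sqrt(1 / D)
  l$Wq <- pf_param(matrix(stats::rnorm(D * D, 0, sd), D, D))
  l$Wk <- pf_param(matrix(stats::rnorm(D * D, 0, sd), D, D))
  l$Wv <- pf_param(matrix(stats::rnorm(D * D, 0, sd), D, D))
  l$Wo <- pf_param(matrix(stats::rnorm(D * D, 0, sd), D, D))
  l$heads <- heads; l$dk <- dk; l$M <- M
  l$params <- list(l$Wq, l$Wk, l$Wv, l$Wo)

  l$forward <- function(X, mask, B, Np, train = FALSE) {
    M <- l$M; nw <- Np %/% M
    Q <- X %*% l$Wq$value; K <- X %*% l$Wk$value; V <- X %*% l$Wv$value
    O <- matrix(0, nrow(X), D)
    cache <- list()
    grp <- rep(seq_len(B), each = M)
    for (w in seq_len(nw)) {
      idx <- as.vector(outer((w - 1) * M + seq_len(M), (seq_len(B) - 1) * Np, "+"))
      mk <- mask[idx]
      for (h in seq_len(l$heads)) {
        cols <- (h - 1) * l$dk + seq_len(l$dk)
        Qw <- Q[idx, cols, drop = FALSE]
        Kw <- K[idx, cols, drop = FALSE]
        Vw <- V[idx, cols, drop = FALSE]
        S <- matrix(0, B * M, M)
        for (j in seq_len(M)) {
          rj <- seq(j, B * M, by = M)
          S[, j] <- rowSums(Qw * Kw[rj[grp], , drop = FALSE]) / sqrt(l$dk)
          S[!mk[rj][grp], j] <- -Inf
        }
        S[!mk, ] <- 0  # pad query rows: keep softmax finite; outputs unused
        A <- softmax_rows(S)
        Ow <- matrix(0, B * M, l$dk)
        for (j in seq_len(M)) {
          rj <- seq(j, B * M, by = M)
          Ow <- Ow + A[, j] * Vw[rj[grp], , drop = FALSE]
        }
        O[idx, cols] <- Ow
        cache[[length(cache) + 1]] <-
          list(w = w, h = h, idx = idx, A = A, mk = mk)
      }
    }
    l$cache <- list(X = X, Q = Q, K = K, V = V, O = O, wins = cache,
                    B = B, Np = Np, grp = grp)
    out <- O %*% l$Wo$value
    l$last_attention <- cache
    out
  }

  l$backward <- function(dy) {
    cc <- l$cache; M <- l$M; B <- cc$B; grp <- cc$grp
    l$Wo$grad <- l$Wo$grad + crossprod(cc$O, dy)
    dO <- tcrossprod(dy, l$Wo$value)
    dQ <- cc$Q * 0; dK <- cc$K * 0; dV <- cc$V * 0
    for (ca in cc$wins) {
      cols <- (ca$h - 1) * l$dk + seq_len(l$dk)
      idx <- ca$idx
      Qw <- cc$Q[idx, cols, drop = FALSE]
      Kw <- cc$K[idx, cols, drop = FALSE]
      Vw <- cc$V[idx, cols, drop = FALSE]
      dOw <- dO[idx, cols, drop = FALSE]
      dOw[!ca$mk, ] <- 0
      A <- ca$A
      dA <- matrix(0, B * M, M)
      dVw <- Vw * 0
      for (j in seq_len(M)) {
        rj <- seq(j, B * M, by = M)
        dA[, j] <- rowSums(dOw * Vw[rj[grp], , drop = FALSE])
        dVw[rj, ] <- dVw[rj, ] + rowsum(A[, j] * dOw, grp)
      }
      dS <- A * (dA - rowSums(dA * A)) / sqrt(l$dk)
      dQw <- Qw * 0; dKw <- Kw * 0
      for (j in seq_len(M)) {
        rj <- seq(j, B * M, by = M)
        dQw <- dQw + dS[, j] * Kw[rj[grp], , drop = FALSE]
        dKw[rj, ] <- dKw[rj, ] + rowsum(dS[, j] * Qw, grp)
      }
      dQ[idx, cols] <- dQ[idx, cols] + dQw
      dK[idx, cols] <- dK[idx, cols] + dKw
      dV[idx, cols] <- dV[idx, cols] + dVw
    }
    X <- cc$X
    l$Wq$grad <- l$Wq$grad + crossprod(X, dQ)
    l$Wk$grad <- l$Wk$grad + crossprod(X, dK)
    l$Wv$grad <- l$Wv$grad + crossprod(X, dV)
    tcrossprod(dQ, l$Wq$value) + tcrossprod(dK, l$Wk$value) +
      tcrossprod(dV, l$Wv$value)
  }
  l
}

#' Construct one shifted-window transformer layer
#'
#' Residual additions wrap both the windowed multi-head attention and the
#' feedforward sublayer (each with a pre-normalization):
#' `H' = H + WMSA(LN(H))`, `H'' = H' + FFN(LN(H'))`. Shifted layers rotate the
#' token sequence by `shift` positions before windowing and unrotate after, so
#' consecutive layers exchange information across window boundaries.
#'
#' @param D token dimension; `heads * d_k` must equal `D`.
#' @param heads,dk attention heads and per-head key dimension.
#' @param M window length.
#' @param shifted logical; apply the rotation.
#' @param shift rotation offset (default `M %/% 2`).
#' @param ffn_hidden feedforward hidden width.
#' @return a layer with `forward(X, mask, B, Np, train)` / `backward(dy)`.
#' @export
swin_layer <- function(D = 96, heads = 3, dk = 32, M = 13, shifted = FALSE,
                       shift = M %/% 2, ffn_hidden = 2 * D) {
  l <- new_layer()
  l$ln1 <- nn_layernorm(D)
  l$msa <- nn_wmsa(D, heads, dk, M)
  l$ln2 <- nn_layernorm(D)
  l$fc1 <- nn_linear(D, ffn_hidden)
  l$relu <- nn_relu()
  l$fc2 <- nn_linear(ffn_hidden, D)
  l$shifted <- shifted; l$shift <- shift
  l$params <- c(l$ln1$params, l$msa$params, l$ln2$params, l$fc1$params,
                l$fc2$params)

  rot_idx <- function(Np, B, s) {
    pos <- ((seq_len(Np) - 1 + s) %% Np) + 1
    as.vector(outer(pos, (seq_len(B) - 1) * Np, "+"))
  }

  l$forward <- function(X, mask, B, Np, train = FALSE) {
    if (l$shifted && l$shift %% Np != 0) {
      ridx <- rot_idx(Np, B, l$shift)
      X <- X[ridx, , drop = FALSE]
      mask <- mask[ridx]
      l$ridx <- ridx
      l$unrot <- rot_idx(Np, B, -l$shift)
    } else {
      l$ridx <- NULL
    }
    a <- l$msa$forward(l$ln1$forward(X, train), mask, B, Np, train)
    a[!mask, ] <- 0
    h1 <- X + a
    f <- l$fc2$forward(l$relu$forward(l$fc1$forward(
      l$ln2$forward(h1, train), train), train), train)
    f[!mask, ] <- 0
    h2 <- h1 + f
    l$mask <- mask
    if (!is.null(l$ridx)) h2[l$unrot, , drop = FALSE] else h2
  }

  l$backward <- function(dy) {
    if (!is.null(l$ridx)) dy <- dy[l$ridx, , drop = FALSE]
    df <- dy
    df[!l$mask, ] <- 0
    dh1 <- dy + l$ln2$backward(l$fc1$backward(l$relu$backward(
      l$fc2$backward(df))))
    da <- dh1
    da[!l$mask, ] <- 0
    dX <- dh1 + l$ln1$backward(l$msa$backward(da))
    if (!is.null(l$ridx)) dX[l$unrot, , drop = FALSE] else dX
  }
  l
}

#' Classify a fused token sequence
#'
#' Mean-pools the tokens, applies a linear map to the class logits, and
#' normalizes with softmax.
#'
#' @param h_l token matrix `N x D` (the final fusion-layer output).
#' @param head_params list with `W` (`D x n_classes`) and `b`
#'   (length `n_classes`).
#' @return list with `logits`, `probabilities` (sums to 1) and `label`
#'   (1-based argmax class index).
#' @export
classify <- function(h_l, head_params) {
  pooled <- colMeans(h_l)
  logits <- as.vector(pooled %*% head_params$W + head_params$b)
  p <- as.vector(softmax_rows(matrix(logits, 1)))
  list(logits = logits, probabilities = p, label = which.max(logits))
}

#' Construct the multimodal fusion core
#'
#' Projects each modality's embedding(s) into a shared `D`-dimensional token
#' space (one learned linear map per modality, plus a learned modality-type
#' embedding added to every token), concatenates the streams into one ordered
#' token sequence (image tokens, clinical token, report token, numeric
#' token), pads to a multiple of the window length with masked tokens, runs
#' `n_layers` alternating regular/shifted window-attention layers, and
#' classifies from the mean-pooled sequence.
#'
#' @param dims named list of per-modality input dims:
#'   `image` (channel width of the image tokens), `clinical`, `report`,
#'   `numeric`.
#' @param n_image_tokens number of image tokens entering the sequence.
#' @param D shared token dimension.
#' @param heads,dk attention heads and per-head key dim (`heads*dk == D`).
#' @param M window length; `shift` the shifted-layer offset.
#' @param n_layers number of attention layers (even layers regular, odd
#'   shifted).
#' @param n_classes output classes.
#' @param modalities character subset of
#'   `c("image", "clinical", "report", "numeric")` actually fused.
#' @param ffn_hidden feedforward width inside each layer.
#' @return fusion object with `forward`/`backward`, `params`, and the token
#'   layout (`n_tokens`, `n_padded`).
#' @export
fusion_core <- function(dims, n_image_tokens, D = 96, heads = 3, dk = 32,
                        M = 13, shift = M %/% 2, n_layers = 4, n_classes = 5,
                        modalities = c("image", "clinical", "report",
                                       "numeric"),
                        ffn_hidden = 2 * D) {
  if (length(modalities) == 0) {
    stop("fusion_core: all modalities masked; at least one token required")
  }
  modalities <- match.arg(modalities, several.ok = TRUE)
  l <- new_layer()
  l$D <- D; l$M <- M; l$modalities <- modalities
  l$proj <- list()
  for (m in modalities) {
    l$proj[[m]] <- nn_linear(dims[[m]], D, bias = FALSE,
                             init_sd = sqrt(1 / dims[[m]]))
  }
  te <- matrix(stats::rnorm(4 * D, 0, 0.02), 4, D,
               dimnames = list(c("image", "clinical", "report", "numeric"),
                               NULL))
  l$type_emb <- pf_param(te, no_decay = TRUE)
  l$n_tokens <- (if ("image" %in% modalities) n_image_tokens else 0) +
    sum(c("clinical", "report", "numeric") %in% modalities)
  l$n_padded <- ceiling(l$n_tokens / M) * M
  l$n_image_tokens <- if ("image" %in% modalities) n_image_tokens else 0
  l$layers <- lapply(seq_len(n_layers), function(i) {
    swin_layer(D, heads, dk, M, shifted = (i %% 2 == 0), shift = shift,
               ffn_hidden = ffn_hidden)
  })
  l$final_ln <- nn_layernorm(D)
  l$head <- nn_linear(D, n_classes, init_sd = 0.01)
  l$params <- c(unlist(lapply(l$proj, function(p) p$params),
                       recursive = FALSE),
                list(l$type_emb),
                unlist(lapply(l$layers, function(s) s$params),
                       recursive = FALSE),
                l$final_ln$params, l$head$params)

  type_row <- function(m) l$type_emb$value[m, ]

  # branch_outputs: list(image = (B,S,C) tokens, clinical = B x d,
  #                      report = B x d, numeric = B x d)
  # drop: modalities occluded at inference (tokens removed, not zeroed)
  l$forward <- function(branch_outputs, train = FALSE, drop = character(0)) {
    active <- setdiff(l$modalities, drop)
    if (!length(active)) stop("fusion_core: all modalities masked")
    B <- if ("image" %in% active) dim(branch_outputs$image)[1]
         else nrow(branch_outputs[[active[1]]])
    Nt <- (if ("image" %in% active) n_image_tokens else 0) +
      sum(c("clinical", "report", "numeric") %in% active)
    Np <- ceiling(Nt / l$M) * l$M
    l$active <- active
    X <- matrix(0, B * Np, l$D)
    mask <- rep(c(rep(TRUE, Nt), rep(FALSE, Np - Nt)), B)
    pos <- 0
    l$B <- B; l$Np_cur <- Np; l$Nt_cur <- Nt
    if ("image" %in% active) {
      S <- dim(branch_outputs$image)[2]
      ti <- matrix(branch_outputs$image,
                   B * S, dim(branch_outputs$image)[3])
      pi_ <- l$proj$image$forward(ti, train)
      pi_ <- pi_ + rep(type_row("image"), rep.int(B * S, l$D))
      # rows of ti are (b, s) with b fastest; X rows are sample-major
      xrows <- rep((seq_len(B) - 1) * Np, times = S) +
        rep(seq_len(S), each = B)
      X[xrows, ] <- pi_
      pos <- S
      l$img_rows <- xrows; l$img_S <- S
    }
    for (m in c("clinical", "report", "numeric")) {
      if (!(m %in% active)) next
      pm <- l$proj[[m]]$forward(branch_outputs[[m]], train)
      pm <- pm + rep(type_row(m), rep.int(B, l$D))
      rows <- (seq_len(B) - 1) * Np + pos + 1
      X[rows, ] <- pm
      l[[paste0(m, "_rows")]] <- rows
      pos <- pos + 1
    }
    for (s in l$layers) X <- s$forward(X, mask, B, Np, train)
    # normalize, then mean-pool valid tokens per sample
    l$mask <- mask
    Xn <- l$final_ln$forward(X, train)
    Xv <- Xn * mask
    pooled <- rowsum(Xv, rep(seq_len(B), each = Np)) / Nt
    logits <- l$head$forward(pooled, train)
    l$X_final <- X
    logits
  }

  l$backward <- function(dlogits) {
    B <- l$B; Np <- l$Np_cur; Nt <- l$Nt_cur
    dpooled <- l$head$backward(dlogits)
    dXn <- (dpooled / Nt)[rep(seq_len(B), each = Np), , drop = FALSE] * l$mask
    dX <- l$final_ln$backward(dXn)
    for (s in rev(l$layers)) dX <- s$backward(dX)
    out <- list()
    if ("image" %in% l$active) {
      dti <- dX[l$img_rows, , drop = FALSE]
      l$type_emb$grad["image", ] <- l$type_emb$grad["image", ] + colSums(dti)
      dimg <- l$proj$image$backward(dti)
      out$image <- array(dimg, c(B, l$img_S, ncol(dimg)))
    }
    for (m in c("clinical", "report", "numeric")) {
      if (!(m %in% l$active)) next
      dm <- dX[l[[paste0(m, "_rows")]], , drop = FALSE]
      l$type_emb$grad[m, ] <- l$type_emb$grad[m, ] + colSums(dm)
      out[[m]] <- l$proj[[m]]$backward(dm)
    }
    out
  }
  l
}

#' Project modality embeddings into the fused token sequence
#'
#' Functional view of the assembly step of [fusion_core()]: applies each
#' modality's projection and type embedding and returns the ordered token
#' sequence for one sample (no attention layers, no padding).
#'
#' @param fusion a [fusion_core()] object.
#' @param branch_outputs list with `image` (`S x C` token matrix),
#'   `clinical`, `report`, `numeric` (vectors), for the modalities the core
#'   fuses.
#' @return matrix `N x D` of fused input tokens (`H^0`).
#' @export
project_and_assemble <- function(fusion, branch_outputs) {
  rows <- list()
  if ("image" %in% fusion$modalities) {
    ti <- branch_outputs$image
    p <- ti %*% fusion$proj$image$W$value
    rows$image <- sweep(p, 2, fusion$type_emb$value["image", ], "+")
  }
  for (m in c("clinical", "report", "numeric")) {
    if (!(m %in% fusion$modalities)) next
    p <- matrix(branch_outputs[[m]], 1) %*% fusion$proj[[m]]$W$value
    rows[[m]] <- sweep(p, 2, fusion$type_emb$value[m, ], "+")
  }
  do.call(rbind, rows)
}
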
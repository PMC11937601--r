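# Text branch: token embedding + sinusoidal positional encoding, a
# bidirectional LSTM, attention pooling over positions, and a fully connected
# projection with dropout. Instantiated twice (clinical notes, radiology
# reports) with independent parameters.

#' Sinusoidal positional encoding table
#'
#' Builds the fixed table `PE[pos, 2i] = sin(pos / 10000^(2i/d_model))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d_model))` (dimension indices 0-based),
#' giving every position a unique, bounded encoding.
#'
#' @param len number of positions (rows); positions are `0 .. len-1`.
#' @param d_model embedding dimension; must be even.
#' @return a `len x d_model` matrix with entries in `[-1, 1]`.
#' @examples
#' pe <- positional_encoding(4, 4)
#' pe[1, ]          # position 0: sin terms 0, cos terms 1
#' pe[2, 1:2]       # (sin 1, cos 1)
#' @export
positional_encoding <- function(len, d_model) {
  stopifnot(len >= 1)
  if (d_model %% 2 != 0) {
    stop("positional_encoding: d_model must be even, got ", d_model)
  }
  pos <- 0:(len - 1)
  i <- 0:(d_model / 2 - 1)
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, len, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Attention pooling over a sequence of hidden states
#'
#' Scores each position with a learned map `W`, normalizes the scores with a
#' (max-subtracted) softmax into weights `alpha`, and returns the
#' alpha-weighted sum of hidden states.
#'
#' @param H numeric matrix `T x d_h` of per-position hidden states.
#' @param W numeric matrix `d_h x 1` scoring map.
#' @return list with `alpha` (length `T`, sums to 1) and `pooled`
#'   (length `d_h`).
#' @export
attention_pool <- function(H, W) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  if (nrow(H) < 1) stop("attention_pool: empty sequence")
  s <- as.vector(H %*% W)
  s <- s - max(s)
  a <- exp(s) / sum(exp(s))
  list(alpha = a, pooled = as.vector(crossprod(H, a)))
}

# Batched attention-pool layer with position masking.
nn_attnpool <- function(d_h) {
  l <- new_layer()
  l$W <- pf_param(matrix(stats::rnorm(d_h, 0, sqrt(1 / d_h)), d_h, 1))
  l$params <- list(l$W)
  # H: (N, T, d_h); mask: N x T logical (TRUE = real token)
  l$forward <- function(H, mask, train = FALSE) {
    d <- dim(H); N <- d[1]; T_ <- d[2]
    Hm <- matrix(H, N * T_, d[3])
    s <- matrix(Hm %*% l$W$value, N, T_)
    s[!mask] <- -Inf
    a <- softmax_rows(s)
    pooled <- matrix(0, N, d[3])
    for (t in seq_len(T_)) pooled <- pooled + a[, t] * matrix(H[, t, ], N)
    l$H <- H; l$Hm <- Hm; l$a <- a; l$d <- d
    list(pooled = pooled, alpha = a)
  }
  l$backward <- function(dpooled) {
    d <- l$d; N <- d[1]; T_ <- d[2]
    dH <- array(0, d)
    da <- matrix(0, N, T_)
    for (t in seq_len(T_)) {
      Ht <- matrix(l$H[, t, ], N)
      da[, t] <- rowSums(dpooled * Ht)
      dH[, t, ] <- l$a[, t] * dpooled
    }
    ds <- l$a * (da - rowSums(da * l$a))
    l$W$grad <- l$W$grad + crossprod(l$Hm, as.vector(ds))
    dH_scores <- tcrossprod(as.vector(ds), l$W$value)
    dH + array(dH_scores, d)
  }
  l
}

#' Construct a text-branch encoder
#'
#' @param vocab_size lexicon size including the padding and unknown ids.
#' @param d_embed token embedding dimension (even; positional encoding is
#'   added to it).
#' @param h_per_dir LSTM hidden size per direction (`d_h = 2 * h_per_dir`).
#' @param d_out output embedding dimension of the fully connected layer.
#' @param dropout dropout rate applied after the fully connected layer.
#' @param max_len maximum sequence length; longer inputs are truncated
#'   tail-first with a warning.
#' @return a branch object with `forward`/`backward` and a `params` list.
#' @export
text_branch <- function(vocab_size, d_embed = 32, h_per_dir = 32, d_out = 32,
                        dropout = 0.3, max_len = 128) {
  l <- new_layer()
  l$emb <- nn_embedding(vocab_size, d_embed)
  l$pe <- positional_encoding(max_len, d_embed)
  l$lstm <- nn_bilstm(d_embed, h_per_dir)
  l$pool <- nn_attnpool(2 * h_per_dir)
  l$fc <- nn_linear(2 * h_per_dir, d_out)
  l$drop <- nn_dropout(dropout)
  l$max_len <- max_len
  l$vocab_size <- vocab_size
  l$d_out <- d_out
  l$params <- c(l$emb$params, l$lstm$params, l$pool$params, l$fc$params)

  # ids: N x T (1-based token ids, 0 = padding); lengths: integer N
  l$forward <- function(ids, lengths, train = FALSE) {
    if (any(ids > l$vocab_size)) {
      stop("text branch: token id outside the lexicon (max ",
           l$vocab_size, ")")
    }
    if (ncol(ids) > l$max_len) {
      warning("text branch: sequence longer than max_len (", ncol(ids),
              " > ", l$max_len, "); truncating tail")
      ids <- ids[, seq_len(l$max_len), drop = FALSE]
      lengths <- pmin(lengths, l$max_len)
    }
    if (any(lengths < 1)) stop("text branch: empty sequence")
    N <- nrow(ids); T_ <- ncol(ids)
    mask <- outer(lengths, seq_len(T_), ">=")
    ids_pad <- ids
    ids_pad[ids_pad == 0L] <- l$vocab_size  # padding id row
    E <- l$emb$forward(ids_pad, train)
    E <- E + outer(rep(1, N), l$pe[seq_len(T_), , drop = FALSE])
    H <- l$lstm$forward(E, train)
    pl <- l$pool$forward(H, mask, train)
    out <- l$fc$forward(pl$pooled, train)
    out <- l$drop$forward(out, train)
    l$last_alpha <- pl$alpha
    l$last_states <- H
    out
  }
  l$backward <- function(dy) {
    dy <- l$drop$backward(dy)
    dpooled <- l$fc$backward(dy)
    dH <- l$pool$backward(dpooled)
    dE <- l$lstm$backward(dH)
    l$emb$backward(dE)
    invisible(NULL)
  }
  l
}

#' Run a text branch over one token sequence
#'
#' Embeds the ids, adds positional encoding, encodes with the bidirectional
#' LSTM, pools with attention, and applies the fully connected + dropout head.
#' In eval mode (`train = FALSE`) the output is deterministic.
#'
#' @param branch a [text_branch()] object.
#' @param tokens integer vector of token ids (1-based).
#' @param train logical; enables dropout.
#' @return list with `embedding` (length `d_out`), `alpha` (attention weights
#'   over positions, sums to 1), and `states` (`T x d_h` hidden states used as
#'   the pre-pooling representation).
#' @export
text_forward <- function(branch, tokens, train = FALSE) {
  ids <- matrix(as.integer(tokens), nrow = 1)
  out <- branch$forward(ids, lengths = length(tokens), train = train)
  list(embedding = as.vector(out),
       alpha = as.vector(branch$last_alpha),
       states = matrix(branch$last_states[1, , ], ncol = dim(branch$last_states)[3]))
}
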
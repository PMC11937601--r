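# Numeric branch: standardization of the 15-indicator lab panel and a
# residual two-hidden-layer perceptron
#   Y = W3 ReLU(W2 ReLU(W1 X + b1) + b2) + b3 + Wr X
# with hidden sizes 64 and 32, output 32, dropout 0.3 after each hidden ReLU
# and none on the residual path.

#' Fit a feature standardizer on training rows
#'
#' Computes per-column mean and population standard deviation, used to map
#' each indicator to `(x - mu) / sigma`. Must be fitted on training rows only;
#' the `fitted_on` tag travels with the parameters so leakage can be audited.
#'
#' @param train_labs numeric matrix (rows = samples, columns = indicators);
#'   at least 2 rows.
#' @param fitted_on identifier of the dataset/fold the rows came from.
#' @return object of class `pf_standardizer`: list with `mean`, `sd`
#'   (population), `fitted_on`.
#' @export
fit_standardizer <- function(train_labs, fitted_on = "train") {
  train_labs <- as.matrix(train_labs)
  if (nrow(train_labs) < 2) stop("fit_standardizer: need at least 2 rows")
  mu <- colMeans(train_labs)
  sdp <- sqrt(colMeans(sweep(train_labs, 2, mu)^2))
  zero <- which(sdp <= 0)
  if (length(zero)) {
    nm <- colnames(train_labs)
    lab <- if (is.null(nm)) as.character(zero) else nm[zero]
    stop("fit_standardizer: zero-variance column(s): ",
         paste(lab, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdp, fitted_on = fitted_on),
            class = "pf_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std object from [fit_standardizer()].
#' @param labs numeric vector (length matching the fit) or matrix.
#' @return standardized vector/matrix `(x - mu) / sigma`.
#' @export
apply_standardizer <- function(std, labs) {
  if (is.null(dim(labs))) {
    (labs - std$mean) / std$sd
  } else {
    sweep(sweep(as.matrix(labs), 2, std$mean), 2, std$sd, "/")
  }
}

#' Construct the residual-MLP numeric branch
#'
#' @param d_in input dimension (15 lab indicators).
#' @param hidden hidden layer sizes (two layers).
#' @param d_out output embedding size.
#' @param dropout rate applied after each hidden ReLU (not on the residual
#'   path).
#' @return branch object with `forward`/`backward` and `params`.
#' @export
numeric_branch <- function(d_in = 15, hidden = c(64, 32), d_out = 32,
                           dropout = 0.3) {
  l <- new_layer()
  l$fc1 <- nn_linear(d_in, hidden[1])
  l$fc2 <- nn_linear(hidden[1], hidden[2])
  l$fc3 <- nn_linear(hidden[2], d_out)
  l$res <- nn_linear(d_in, d_out, bias = FALSE, init_sd = 0.05)
  l$relu1 <- nn_relu(); l$relu2 <- nn_relu()
  l$drop1 <- nn_dropout(dropout); l$drop2 <- nn_dropout(dropout)
  l$d_out <- d_out
  l$params <- c(l$fc1$params, l$fc2$params, l$fc3$params, l$res$params)
  l$forward <- function(x, train = FALSE) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    h <- l$drop1$forward(l$relu1$forward(l$fc1$forward(x, train), train), train)
    h <- l$drop2$forward(l$relu2$forward(l$fc2$forward(h, train), train), train)
    l$fc3$forward(h, train) + l$res$forward(x, train)
  }
  l$backward <- function(dy) {
    dx_res <- l$res$backward(dy)
    dh <- l$fc3$backward(dy)
    dh <- l$fc2$backward(l$relu2$backward(l$drop2$backward(dh)))
    dx <- l$fc1$backward(l$relu1$backward(l$drop1$backward(dh)))
    dx + dx_res
  }
  l
}

#' Forward one standardized lab vector through the numeric branch
#'
#' Evaluates the residual MLP in eval mode (dropout off), returning the
#' 32-dimensional modality embedding.
#'
#' @param branch a [numeric_branch()] object.
#' @param x standardized numeric vector of length matching the branch input.
#' @return numeric vector of length `d_out`.
#' @export
numeric_forward <- function(branch, x) {
  if (length(x) != nrow(branch$fc1$W$value)) {
    stop("numeric_forward: expected input length ",
         nrow(branch$fc1$W$value), ", got ", length(x))
  }
  as.vector(branch$forward(matrix(x, nrow = 1), train = FALSE))
}
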
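# Interpretability: Grad-CAM on the image branch, export of fusion and text
# attention weights, and modality-contribution quantification by occlusion.

#' Grad-CAM heatmap for one sample
#'
#' Backpropagates the target-class logit to the attended final feature map of
#' the image branch, pools the gradient per channel over space, forms the
#' rectified gradient-weighted channel sum, upsamples it bilinearly to the
#' input size, and max-normalizes. An all-zero map stays all-zero.
#'
#' @param model a [build_model()] model containing an image branch.
#' @param sample a materialized sample.
#' @param target_class 1-based class index (default: the sample's label).
#' @param std standardizer for the lab panel (from training).
#' @param layer_tag feature map to explain; `"attention"` (the
#'   channel-spatial-attended final map) is the only convolutional target
#'   exposed.
#' @return list with `values` (`H x W` matrix in `[0,1]`), `target_class`,
#'   `layer_tag`.
#' @export
grad_cam <- function(model, sample, target_class = sample$label_id, std,
                     layer_tag = "attention") {
  if (!("image" %in% model$modalities)) {
    stop("grad_cam: model has no image branch")
  }
  if (!identical(layer_tag, "attention")) {
    stop("grad_cam: unknown layer_tag '", layer_tag,
         "'; the attended final convolutional map ('attention') is exposed")
  }
  b <- prepare_batch(list(sample), std, model$modalities)
  logits <- model$forward(b, train = FALSE)
  dl <- matrix(0, 1, ncol(logits))
  dl[1, target_class] <- 1
  zero_grads(model$params)
  model$backward(dl)
  act <- model$image$gcam_act    # (h, w, C, 1)
  grad <- model$image$gcam_grad
  d <- dim(act)
  w <- colMeans(matrix(grad, d[1] * d[2], d[3]))
  cam <- matrix(matrix(act, d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  # upsample with receptive-field alignment: the stride-2 chain (odd
  # kernels, same padding) centers map cell u at input pixel (u-1)*s + 1
  cam <- pf_upsample_aligned(cam, nrow(sample$image), ncol(sample$image))
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  list(values = cam, target_class = target_class, layer_tag = layer_tag)
}

# Bilinear upsampling of a feature-map-sized matrix to image size, sampling
# map cell u at its receptive-field center pixel (u-1)*stride + 1.
pf_upsample_aligned <- function(m, out_h, out_w) {
  sh <- out_h / nrow(m); sw <- out_w / ncol(m)
  us <- (seq_len(out_h) - 1) / sh + 1
  vs <- (seq_len(out_w) - 1) / sw + 1
  u0 <- pmin(pmax(floor(us), 1), nrow(m)); u1 <- pmin(u0 + 1, nrow(m))
  v0 <- pmin(pmax(floor(vs), 1), ncol(m)); v1 <- pmin(v0 + 1, ncol(m))
  fu <- pmin(pmax(us - u0, 0), 1); fv <- pmin(pmax(vs - v0, 0), 1)
  m[u0, v0, drop = FALSE] * outer(1 - fu, 1 - fv) +
    m[u1, v0, drop = FALSE] * outer(fu, 1 - fv) +
    m[u0, v1, drop = FALSE] * outer(1 - fu, fv) +
    m[u1, v1, drop = FALSE] * outer(fu, fv)
}

#' Fraction of heatmap mass inside a mask
#'
#' @param heatmap from [grad_cam()].
#' @param mask logical matrix of the same shape (e.g. the generator's lesion
#'   mask).
#' @return `sum(values[mask]) / sum(values)` (0 if the map is all zero).
#' @export
heatmap_mass_in_mask <- function(heatmap, mask) {
  tot <- sum(heatmap$values)
  if (tot == 0) return(0)
  sum(heatmap$values[mask]) / tot
}

#' Modality contributions by occlusion
#'
#' For each fused modality `m`, measures the accuracy drop when `m`'s tokens
#' are removed from the fusion sequence (occlusion by removal, not zeroing),
#' floors the drops at zero and normalizes them to fractions summing to 1.
#' If no occlusion changes accuracy the contributions are reported uniform
#' with a warning.
#'
#' @param model trained model.
#' @param samples labelled evaluation samples.
#' @param std training-fitted standardizer.
#' @param batch_size evaluation batch size.
#' @return list with `fractions` (named, sums to 1), `accuracy_full`,
#'   `accuracy_without` (named), `method = "occlusion"`.
#' @export
modality_contribution <- function(model, samples, std, batch_size = 64) {
  mods <- model$modalities
  acc <- function(drop = character(0)) {
    n <- length(samples); good <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1, n)
      b <- prepare_batch(samples[idx], std, mods)
      pr <- model$predict(b, drop = drop)
      good <- good + sum(pr$labels == b$labels)
    }
    good / n
  }
  full <- acc()
  without <- vapply(mods, function(m) acc(drop = m), numeric(1))
  delta <- pmax(full - without, 0)
  if (sum(delta) == 0) {
    warning("modality_contribution: no occlusion changed accuracy; ",
            "reporting uniform contributions")
    fractions <- stats::setNames(rep(1 / length(mods), length(mods)), mods)
  } else {
    fractions <- delta / sum(delta)
  }
  list(fractions = fractions, accuracy_full = full,
       accuracy_without = without, method = "occlusion")
}

#' Export attention weights for one sample
#'
#' Runs the model in eval mode and collects every attention distribution:
#' the per-layer, per-head, per-window fusion attention matrices (rows sum
#' to 1 over the window's real tokens) with their token indices, and the
#' attention-pooling weights of both text branches.
#'
#' @param model a [build_model()] model.
#' @param sample a materialized sample.
#' @param std training-fitted standardizer.
#' @return list with `fusion` (nested layer/window/head list) and
#'   `text_alpha` (per text branch).
#' @export
export_attention <- function(model, sample, std) {
  b <- prepare_batch(list(sample), std, model$modalities)
  invisible(model$forward(b, train = FALSE))
  fus <- model$fusion
  Np <- fus$Np_cur; Nt <- fus$Nt_cur; M <- fus$M
  layers <- list()
  for (li in seq_along(fus$layers)) {
    sl <- fus$layers[[li]]
    shift <- if (sl$shifted) sl$shift else 0
    pos_order <- ((seq_len(Np) - 1 + shift) %% Np) + 1
    wins <- list()
    for (ca in sl$msa$last_attention) {
      rows <- (ca$w - 1) * M + seq_len(M)
      tok <- pos_order[rows]
      keep <- tok <= Nt
      A <- ca$A[seq_len(M), , drop = FALSE][keep, keep, drop = FALSE]
      A <- A / rowSums(A)  # renormalize over real tokens after pad removal
      wins[[length(wins) + 1]] <-
        list(window = ca$w, head = ca$h, tokens = tok[keep], weights = A)
    }
    layers[[li]] <- list(layer = li, shifted = sl$shifted, windows = wins)
  }
  ta <- list()
  for (tb in c("clinical", "report")) {
    if (!(tb %in% model$modalities)) next
    ta[[tb]] <- as.vector(model[[tb]]$last_alpha)
  }
  list(fusion = layers, text_alpha = ta)
}
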
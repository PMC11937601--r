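# Training engine: AdamW with decoupled weight decay, cosine annealing with
# warm restarts, early stopping on validation loss, and stratified 5-fold
# cross-validation. Runs are fully reproducible given the config seed.

#' Build a training configuration
#'
#' Defaults follow the reference regime: AdamW with learning rate 1e-3 and
#' weight decay 1e-4, batch size 32, an 80-epoch budget with early-stopping
#' patience 10, cosine annealing with warm restarts (first period 10 epochs,
#' period multiplier 2) down to a 1e-6 floor.
#'
#' @param lr,weight_decay,batch_size,epochs,early_stop_patience,lr_min
#'   optimizer and schedule parameters.
#' @param t0,t_mult warm-restart first period (epochs) and period multiplier.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param augment apply horizontal-flip image augmentation to training
#'   batches (lesion motifs are mirror-invariant).
#' @param mixed_precision flag kept for interface parity; computation is
#'   double precision on CPU and the flag must remain `FALSE`.
#' @param cv_mode `"holdout_80_20"` or `"fivefold"`.
#' @param seed RNG seed governing batch order and dropout.
#' @return list of class `pf_train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-4, batch_size = 32,
                         epochs = 80, early_stop_patience = 10,
                         lr_min = 1e-6, t0 = 10, t_mult = 2, grad_clip = 5,
                         augment = TRUE, mixed_precision = FALSE,
                         cv_mode = c("holdout_80_20", "fivefold"), seed = 1) {
  stopifnot(lr > lr_min, lr_min > 0, early_stop_patience >= 1, epochs >= 1)
  if (isTRUE(mixed_precision)) {
    stop("train_config: mixed precision is not available on the CPU path")
  }
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, epochs = epochs,
                 early_stop_patience = early_stop_patience, lr_min = lr_min,
                 t0 = t0, t_mult = t_mult, grad_clip = grad_clip,
                 augment = augment, mixed_precision = FALSE,
                 cv_mode = match.arg(cv_mode), seed = seed),
            class = "pf_train_config")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Within a cycle of length `T_i` the rate decays from `lr` to `lr_min` along
#' a half cosine, then restarts at `lr`; cycle lengths grow by `t_mult`
#' (`T_0, T_0*t_mult, ...`).
#'
#' @param epoch 0-based epoch index.
#' @param lr,lr_min peak and floor learning rates.
#' @param t0 first cycle length in epochs; `t_mult` the multiplier.
#' @return learning rate at `epoch`.
#' @export
cosine_warm_restart_lr <- function(epoch, lr = 1e-3, lr_min = 1e-6, t0 = 10,
                                   t_mult = 2) {
  ti <- t0
  e <- epoch
  while (e >= ti) {
    e <- e - ti
    ti <- ti * t_mult
  }
  lr_min + (lr - lr_min) * (1 + cos(pi * e / ti)) / 2
}

pf_eval_split <- function(model, samples, std, batch_size = 64) {
  mods <- model$modalities
  n <- length(samples)
  losses <- numeric(0); preds <- integer(n); labs <- integer(n)
  probs <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- prepare_batch(samples[idx], std, mods)
    logits <- model$forward(b, train = FALSE)
    l <- ce_loss(logits, b$labels)
    losses <- c(losses, l$loss * length(idx))
    preds[idx] <- max.col(logits, ties.method = "first")
    labs[idx] <- b$labels
    probs <- rbind(probs, softmax_rows(logits))
  }
  cm <- confusion_counts(labs, preds)
  met <- suppressWarnings(classification_metrics(cm))
  list(loss = sum(losses) / n, accuracy = met$accuracy, metrics = met,
       confusion = cm, auc = ovr_auc(labs, probs),
       predictions = preds, labels = labs, probabilities = probs)
}

#' Train the multimodal model
#'
#' Mini-batch AdamW over the training samples with per-epoch validation.
#' Stops at the epoch budget or when validation loss has not improved for
#' `early_stop_patience` consecutive epochs; returns the parameters of the
#' best (lowest validation loss) epoch. The standardizer is fitted on the
#' training rows only.
#'
#' @param model a [build_model()] model (modified in place; also returned).
#' @param train_samples,val_samples lists of [materialize_sample()] outputs.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (one row per epoch: losses,
#'   validation metrics, learning rate), `best_epoch`, `best_val`,
#'   `standardizer`.
#' @export
train_model <- function(model, train_samples, val_samples, config,
                        verbose = FALSE) {
  if (!length(train_samples)) stop("train_model: empty training split")
  set.seed(config$seed)
  mods <- model$modalities
  labm <- t(vapply(train_samples, `[[`, numeric(15), "labs"))
  std <- fit_standardizer(labm, fitted_on = "train")
  n <- length(train_samples)
  step <- 0
  best <- list(loss = Inf, epoch = NA, snap = NULL, bn = NULL, val = NULL)
  bad_epochs <- 0
  hist <- list()
  for (epoch in seq_len(config$epochs) - 1L) {
    lr_now <- cosine_warm_restart_lr(epoch, config$lr, config$lr_min,
                                     config$t0, config$t_mult)
    ord <- sample.int(n)
    tr_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      b <- prepare_batch(train_samples[idx], std, mods)
      if (isTRUE(config$augment) && !is.null(b$images)) {
        # horizontal flips (motif semantics are mirror-invariant)
        for (k in which(stats::runif(length(idx)) < 0.5)) {
          b$images[, , 1, k] <- b$images[, rev(seq_len(dim(b$images)[2])),
                                         1, k]
        }
      }
      logits <- model$forward(b, train = TRUE)
      l <- ce_loss(logits, b$labels)
      if (!is.finite(l$loss)) {
        stop("train_model: non-finite loss at epoch ", epoch, ", batch ",
             (start - 1) %/% config$batch_size + 1,
             " (samples ", paste(idx[1:min(3, length(idx))],
                                 collapse = ","), " ...)")
      }
      tr_loss <- tr_loss + l$loss * length(idx)
      zero_grads(model$params)
      model$backward(l$dlogits)
      if (config$grad_clip > 0) clip_global_norm(model$params,
                                                 config$grad_clip)
      step <- step + 1
      adamw_step(model$params, lr = lr_now, step = step,
                 weight_decay = config$weight_decay)
    }
    tr_loss <- tr_loss / n
    ev <- pf_eval_split(model, val_samples, std)
    hist[[length(hist) + 1]] <- data.frame(
      epoch = epoch, train_loss = tr_loss, val_loss = ev$loss,
      val_accuracy = ev$accuracy, val_macro_f1 = ev$metrics$macro$f1,
      lr_now = lr_now)
    if (verbose) {
      message(sprintf(
        "epoch %2d  train %.4f  val %.4f  acc %.3f  lr %.2e",
        epoch, tr_loss, ev$loss, ev$accuracy, lr_now))
    }
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, epoch = epoch,
                   snap = params_snapshot(model$params),
                   bn = pf_bn_state(model), val = ev)
      bad_epochs <- 0
    } else {
      bad_epochs <- bad_epochs + 1
      if (bad_epochs >= config$early_stop_patience) break
    }
  }
  params_restore(model$params, best$snap)
  pf_bn_state(model, best$bn)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best$epoch, best_val = best$val, standardizer = std)
}

#' Stratified 5-fold cross-validation
#'
#' Runs five independently initialized trainings, each holding out one fold
#' as validation (the standardizer is refitted on each training portion),
#' and summarizes per-fold best metrics.
#'
#' @param model_factory zero-argument function returning a fresh model.
#' @param samples list of materialized samples (each carries its `fold`).
#' @param config a [train_config()] with `cv_mode = "fivefold"`.
#' @return list with `folds` (per-fold results), `summary` (mean and sd of
#'   accuracy and macro F1 across folds).
#' @export
crossvalidate <- function(model_factory, samples, config) {
  if (config$cv_mode != "fivefold") {
    stop("crossvalidate: config$cv_mode must be 'fivefold'")
  }
  folds <- vapply(samples, `[[`, 0L, "fold")
  labels <- vapply(samples, `[[`, 1L, "label_id")
  res <- list()
  for (k in 0:4) {
    tr <- samples[folds != k]
    va <- samples[folds == k]
    if (length(unique(vapply(va, `[[`, 1L, "label_id"))) <
        length(unique(labels))) {
      stop("crossvalidate: fold ", k, " is missing a class")
    }
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    set.seed(cfg_k$seed)
    model <- model_factory()
    fit <- train_model(model, tr, va, cfg_k)
    res[[k + 1]] <- list(fold = k, best_epoch = fit$best_epoch,
                         accuracy = fit$best_val$accuracy,
                         macro_f1 = fit$best_val$metrics$macro$f1,
                         val_loss = fit$best_val$loss,
                         history = fit$history)
  }
  acc <- vapply(res, `[[`, 0, "accuracy")
  f1 <- vapply(res, `[[`, 0, "macro_f1")
  list(folds = res,
       summary = list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                      mean_macro_f1 = mean(f1), sd_macro_f1 = stats::sd(f1)))
}

#' Materialize a set of manifest rows
#'
#' @param manifest a [generate_dataset()] manifest.
#' @param rows row indices.
#' @param lexicon tokenization lexicon.
#' @return list of materialized samples.
#' @export
materialize_many <- function(manifest, rows, lexicon = load_lexicon()) {
  lapply(rows, function(i) materialize_sample(manifest, i, lexicon))
}
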
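# Training engine: schedule arithmetic, early stopping, determinism,
# optimizer conventions, and cross-validation bookkeeping.

test_that("the warm-restart cosine schedule evaluates in closed form", {
  lr <- 1e-3; lr_min <- 1e-6
  expect_equal(cosine_warm_restart_lr(0, lr, lr_min, 10, 2), lr)
  # mid-cycle epoch 5 of a 10-epoch cycle
  expect_equal(cosine_warm_restart_lr(5, lr, lr_min, 10, 2),
               lr_min + (lr - lr_min) * (1 + cos(pi * 5 / 10)) / 2)
  expect_equal(cosine_warm_restart_lr(5, lr, lr_min, 10, 2), 5.005e-4,
               tolerance = 1e-7)
  # restart at epoch 10; second cycle is 20 epochs long
  expect_equal(cosine_warm_restart_lr(10, lr, lr_min, 10, 2), lr)
  expect_equal(cosine_warm_restart_lr(20, lr, lr_min, 10, 2),
               lr_min + (lr - lr_min) * (1 + cos(pi * 10 / 20)) / 2)
  # floor is reached asymptotically at each cycle end
  expect_lt(cosine_warm_restart_lr(9.999, lr, lr_min, 10, 2), 1.1e-6)
})

test_that("config invariants are enforced", {
  expect_error(train_config(lr = 1e-6, lr_min = 1e-6), "lr > lr_min")
  expect_error(train_config(early_stop_patience = 0), "patience")
  expect_error(train_config(mixed_precision = TRUE), "mixed precision")
  expect_error(train_model(build_model(model_config("desk64",
                                                    modalities = "numeric")),
                           list(), list(), train_config()),
               "empty training split")
})

test_that("patience-1 stopping halts after two non-improving epochs", {
  smp <- tiny_samples(4)
  tr <- smp[1:12]; va <- smp[13:20]
  set.seed(50)
  model <- build_model(model_config("desk64", modalities = "numeric"))
  # a vanishing learning rate freezes the model, so val loss never improves
  cfg <- train_config(lr = 1e-12, lr_min = 1e-13, epochs = 10,
                      early_stop_patience = 1, seed = 1)
  fit <- train_model(model, tr, va, cfg)
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 0)
})

test_that("identical config and seed reproduce the run exactly", {
  smp <- tiny_samples(4)
  tr <- smp[1:14]; va <- smp[15:20]
  cfg <- train_config(epochs = 2, early_stop_patience = 5, batch_size = 8,
                      seed = 7)
  run <- function() {
    set.seed(99)
    model <- build_model(model_config("desk64", modalities = c("numeric",
                                                               "clinical")))
    train_model(model, tr, va, cfg)$history
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("the returned checkpoint has the lowest validation loss seen", {
  smp <- tiny_samples(5)
  is_tr <- vapply(smp, `[[`, TRUE, "is_train")
  cfg <- train_config(epochs = 4, early_stop_patience = 10, seed = 2)
  set.seed(51)
  model <- build_model(model_config("desk64", modalities = "numeric"))
  fit <- train_model(model, smp[is_tr], smp[!is_tr], cfg)
  expect_equal(fit$best_val$loss, min(fit$history$val_loss))
  expect_true(all(fit$best_val$loss <= fit$history$val_loss))
})

test_that("weight decay spares biases and normalization parameters", {
  decay <- pf_param(matrix(1, 2, 2))
  nodecay <- pf_param(matrix(1, 2, 2), no_decay = TRUE)
  # zero gradients: only the decoupled decay moves parameters
  adamw_step(list(decay, nodecay), lr = 0.1, step = 1, weight_decay = 0.5)
  expect_true(all(decay$value < 1))
  expect_equal(nodecay$value, matrix(1, 2, 2))
})

test_that("five-fold cross-validation is stratified and averages correctly", {
  man <- balanced_manifest(10, seed = 3)
  smp <- materialize_many(man, seq_len(nrow(man)))
  folds <- vapply(smp, `[[`, 0L, "fold")
  for (k in 0:4) {
    va <- smp[folds == k]
    expect_length(va, 10)
    expect_equal(as.vector(table(vapply(va, `[[`, "", "label"))),
                 rep(2L, 5))                      # 2 per class per fold
  }
  cfg <- train_config(epochs = 2, early_stop_patience = 5,
                      cv_mode = "fivefold", seed = 5)
  cv <- crossvalidate(
    function() build_model(model_config("desk64", modalities = "numeric")),
    smp, cfg)
  accs <- vapply(cv$folds, `[[`, 0, "accuracy")
  expect_equal(cv$summary$mean_accuracy, mean(accs))
  expect_equal(cv$summary$sd_accuracy, sd(accs))
  expect_length(cv$folds, 5)
  expect_error(crossvalidate(function() NULL, smp,
                             train_config(cv_mode = "holdout_80_20")),
               "fivefold")
})

test_that("a frozen model shows flat training curves (control)", {
  smp <- tiny_samples(4)
  tr <- smp[1:14]; va <- smp[15:20]
  set.seed(52)
  model <- build_model(model_config("desk64", modalities = "numeric"))
  cfg <- train_config(lr = 1e-12, lr_min = 1e-13, epochs = 3,
                      early_stop_patience = 10, seed = 1)
  fit <- train_model(model, tr, va, cfg)
  expect_lt(diff(range(fit$history$val_loss)), 1e-6)
})
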
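# Shared fixtures. The scaled-down training study (500 samples at 64x64,
# full model + four single-modality ablations) is expensive, so it is run
# once on first use and memoised for the test files that consume it.

pf_test_cache <- new.env(parent = emptyenv())

# package internals exercised directly by the unit tests
nn_wmsa <- pneumodal:::nn_wmsa
pf_arch_new <- pneumodal:::pf_arch_new
pf_linear_entry <- pneumodal:::pf_linear_entry
pf_conv_entry <- pneumodal:::pf_conv_entry
pf_param <- pneumodal:::pf_param
pf_lung_radius <- pneumodal:::pf_lung_radius
params_snapshot <- pneumodal:::params_snapshot
params_restore <- pneumodal:::params_restore
zero_grads <- pneumodal:::zero_grads
adamw_step <- pneumodal:::adamw_step

balanced_manifest <- function(n_per_class, seed = 42, image_size = 64) {
  specs <- default_class_specs(stats::setNames(
    rep(n_per_class, 5),
    c("normal", "tuberculosis", "viral", "bacterial", "covid19")))
  generate_dataset(specs, seed = seed, image_size = image_size)
}

tiny_samples <- function(n_per_class = 6, seed = 42, image_size = 64) {
  key <- sprintf("tiny-%d-%d-%d", n_per_class, seed, image_size)
  if (is.null(pf_test_cache[[key]])) {
    man <- balanced_manifest(n_per_class, seed, image_size)
    pf_test_cache[[key]] <- materialize_many(man, seq_len(nrow(man)))
  }
  pf_test_cache[[key]]
}

# The desk-scale study: 100 samples/class at 64x64, 80/20 split, full model
# trained within a 20-epoch budget, plus the four single-modality runs.
desk_study <- function() {
  if (!is.null(pf_test_cache$desk)) return(pf_test_cache$desk)
  man <- balanced_manifest(100, seed = 42, image_size = 64)
  smp <- materialize_many(man, seq_len(nrow(man)))
  is_tr <- vapply(smp, `[[`, TRUE, "is_train")
  tr <- smp[is_tr]; va <- smp[!is_tr]
  cfg <- train_config(epochs = 20, early_stop_patience = 8, seed = 1)
  set.seed(1)
  full <- build_model(model_config("desk64"))
  fit <- train_model(full, tr, va, cfg)
  single <- list()
  for (m in c("image", "clinical", "report", "numeric")) {
    set.seed(1)
    mod <- build_model(model_config("desk64", modalities = m))
    single[[m]] <- train_model(mod, tr, va, cfg)
  }
  pf_test_cache$desk <- list(manifest = man, train = tr, val = va,
                             fit = fit, single = single,
                             std = fit$standardizer)
  pf_test_cache$desk
}

# The localization study: an image-only model with the higher-resolution
# `loc64` backbone, trained on the same 500-sample dataset, for Grad-CAM
# comparisons against random-weight controls.
loc_study <- function() {
  if (!is.null(pf_test_cache$loc)) return(pf_test_cache$loc)
  st <- desk_study()
  cfg <- train_config(epochs = 30, early_stop_patience = 12, seed = 1)
  set.seed(1)
  model <- build_model(model_config("loc64", modalities = "image"))
  fit <- train_model(model, st$train, st$val, cfg)
  pf_test_cache$loc <- list(fit = fit, val = st$val,
                            std = fit$standardizer)
  pf_test_cache$loc
}
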
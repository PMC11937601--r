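# pneumodal

Multimodal pneumonia classification in R: chest-CT-like images, clinical
notes, radiology reports, and a 15-indicator laboratory panel, fused by a
shifted-window attention transformer into a 5-class prediction (normal,
tuberculosis, viral, bacterial, COVID-19). The package is aimed at
methodologists who want a fully inspectable, CPU-trainable implementation
of this architecture family — every kernel (convolution, BiLSTM, windowed
attention, normalization, AdamW) is implemented in the package and unit
tested against brute-force oracles, with no deep-learning framework
dependency.

## The model

Four branches feed a fusion core:

* **Image**: residual CNN over single-channel input; later stages use
  depthwise-separable convolutions
  (`F_dsc = K_point · (K_depth * F)`, `C·k² + C_out·C` parameters); a
  global channel–spatial attention block (channel MLP gate
  `C_att = σ(MLP(F_avg))`, channel shuffle, spatial gate
  `S_att = σ(Conv7×7[meanᶜ; maxᶜ])`) attends the final map:
  `F_out = (F_dsc ⊙ C_att)_shuffle ⊙ S_att`.
* **Clinical text / radiology report** (independent parameters): embedding
  + sinusoidal positional encoding `PE(pos,2i) = sin(pos/10000^{2i/d})`,
  BiLSTM, attention pooling `α = softmax(HW)`, FC + dropout.
* **Labs**: standardization `(x−μ)/σ` then a residual MLP
  `Y = W₃ReLU(W₂ReLU(W₁X+b₁)+b₂)+b₃+W_rX` (hidden 64/32, output 32,
  dropout 0.3).
* **Fusion**: per-modality projection into a shared `D = 96` token space
  plus modality-type embeddings; alternating regular/shifted window
  multi-head self-attention layers (`softmax(QKᵀ/√d_k)V` within `M`-token
  windows, shift `M/2`), residual + feedforward sublayers; masked mean
  pooling and a softmax head.

A synthetic data generator produces class-conditional image motifs
(peripheral ground-glass for COVID-19, upper-lobe foci for tuberculosis,
central consolidation for bacterial, lower-lobe haze for viral), ~50-word
templated texts over a fixed lexicon, and class-conditional lab panels —
with deliberate per-modality ambiguity so that fusion genuinely helps. A
training engine (AdamW, cosine warm restarts, early stopping, stratified
5-fold CV), an exact parameter/FLOP profiler with reference architecture
tables, Grad-CAM and occlusion-based modality contributions complete the
toolkit. A thin CLI lives at `inst/cli/pneumodal`
(`generate | train | evaluate | profile | explain`).

## Worked example

```r
library(pneumodal)

# exact architecture arithmetic
profile_architecture(build_baseline("vgg16", num_classes = 5))$params_millions
#> [1] 134.28
profile_architecture(build_baseline("resnet50", num_classes = 5))$params_exact
#> [1] 23518277

# a balanced synthetic study: 100 samples/class at 64x64
specs <- default_class_specs(c(normal = 100, tuberculosis = 100,
                               viral = 100, bacterial = 100, covid19 = 100))
man <- generate_dataset(specs, seed = 42, image_size = 64)
smp <- materialize_many(man, seq_len(nrow(man)))
tr  <- smp[vapply(smp, `[[`, TRUE, "is_train")]
va  <- smp[!vapply(smp, `[[`, TRUE, "is_train")]

set.seed(1)
model <- build_model(model_config("desk64"))
fit <- train_model(model, tr, va,
                   train_config(epochs = 20, early_stop_patience = 8,
                                seed = 1),
                   verbose = TRUE)
#> epoch  0  train 1.6133  val 1.5417  acc 0.390  lr 1.00e-03
#> epoch  5  train 0.6713  val 0.5300  acc 0.900  lr 5.01e-04
#> epoch 10  train 0.4225  val 0.4158  acc 0.850  lr 1.00e-03
#> ...
#> epoch 19  train 0.0566  val 0.1057  acc 0.950  lr 5.79e-04
fit$best_val$accuracy
#> [1] 0.95
```

The validation accuracy is the fraction of the 100 held-out samples
classified correctly; the per-epoch lines show the cosine-annealed learning
rate restarting at epoch 10. Training the same split with a single modality
(`model_config("desk64", modalities = "image")`, etc.) plateaus strictly
below the fused model, which is the point of the architecture: each
synthetic modality is individually ambiguous and jointly sufficient.

```r
s <- Filter(function(x) x$label == "covid19", va)[[1]]
hm <- grad_cam(fit$model, s, std = fit$standardizer)
heatmap_mass_in_mask(hm, s$mask)  # fraction of saliency on the lesion
```

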
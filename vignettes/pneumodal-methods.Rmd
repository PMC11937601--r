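---
title: "Methods: multimodal pneumonia classification at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal pneumonia classification at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Distinguishing bacterial, viral, tuberculous and COVID-19 pneumonia from
normal lungs is hard from any single data source: viral and bacterial
disease overlap on imaging, while laboratory panels disambiguate them
(elevated WBC/CRP/PCT in bacterial disease, lymphocytosis in viral disease,
lymphopenia in COVID-19). `pneumodal` implements a four-modality classifier
that mirrors how clinicians integrate evidence:

* **Image branch** — a residual convolutional backbone over single-channel
  CT-like images. Later stages replace dense 3×3 convolutions with
  *depthwise-separable* convolutions (per-channel spatial filter followed by
  a 1×1 cross-channel mix, `C·k² + C_out·C` parameters instead of
  `C_out·C·k²`). A *global channel–spatial attention* (GCSA) block follows
  the final stage: global average pooling to per-channel descriptors, a
  two-layer MLP with sigmoid gate reweighting channels, a channel shuffle
  (reshape–transpose interleaving) to mix channel groups, then a spatial
  gate formed by pooling the reweighted map across channels (mean and max
  maps), concatenating and applying a 7×7 convolution with sigmoid. Both
  gates lie strictly in (0,1), so attention only attenuates.
* **Two text branches** (clinical notes; radiology reports) — independent
  encoders: token embedding plus the sinusoidal positional encoding
  `PE(pos,2i) = sin(pos/10000^{2i/d})`, `PE(pos,2i+1) = cos(·)`, a
  bidirectional LSTM, attention pooling `α = softmax(H W)` with the pooled
  state `αᵀH`, and a fully connected layer with dropout.
* **Numeric branch** — the 15-indicator lab panel, standardized as
  `(x − μ)/σ` with training-fold moments, through a residual MLP
  `Y = W₃ ReLU(W₂ ReLU(W₁X + b₁) + b₂) + b₃ + W_r X` with hidden sizes 64
  and 32, output 32, dropout 0.3 after each hidden ReLU and none on the
  residual path.
* **Fusion core** — each modality is linearly projected into a shared
  `D = 96` token space (image: its 49 or 16 spatial tokens; each text
  branch: its pooled state; labs: the MLP output), a learned modality-type
  embedding is added, and the ordered token sequence is processed by
  alternating regular / shifted window multi-head self-attention layers
  (`softmax(QKᵀ/√d_k)V` within windows of `M` tokens; shifted layers rotate
  the sequence by `M/2` so information crosses window boundaries), each
  wrapped in residual additions with a pre-layer-norm and a feedforward
  sublayer. A final layer norm, masked mean pooling over real tokens, and a
  linear softmax head produce the 5-class prediction.

All network kernels (convolutions, BPTT through the BiLSTM, windowed
attention, batch/layer normalization, AdamW) are implemented in the package
(RcppArmadillo for the convolution inner loops); every backward pass is
hand-derived and verified against finite differences in the test suite.

## Interpreting the equations: the open choices

Several aspects of the architecture admit more than one reading; the package
fixes them as follows.

* **Sum vs sequence fusion.** A literal elementwise sum of modality
  embeddings is undefined when modalities contribute different token
  counts. The projections `W_m` are kept as per-modality linear maps into
  the shared space, and fusion happens by attention over the concatenated
  token sequence — the only reading consistent with window attention over a
  length-`N` sequence. Windows are contiguous runs over the 1-D order
  image → clinical → report → numeric; no 2-D window grid or patch merging
  is used, because the fused sequence mixes non-spatial tokens.
* **Channel attention input.** The channel MLP consumes only the
  average-pooled descriptor (the max descriptor is computed and exposed in
  the attention state, but feeds only the spatial path). The spatial gate's
  stated output shape (`1 × H' × W'`) is obtainable only by pooling *across
  channels*, so the spatial path pools the channel-attended, shuffled map
  into mean and max maps — the CBAM-style resolution of the dimensional
  mismatch.
* **Recurrent text encoder.** The equation-bearing description of the text
  branch is BiLSTM + attention pooling, and that is what is implemented; no
  pretrained language model is involved anywhere (the synthetic reports are
  templated, see below). The fully connected layer sits after pooling. The
  fusion core consumes the pooled text state as one token per branch.
* **Pooling before classification** is the mean over real (non-pad) tokens;
  padding tokens are masked out of every softmax and removed — not zeroed —
  when a modality is ablated or occluded, since zero tokens would still
  attract attention mass and, after layer normalization, carry bias
  content.

## Stabilization choices

Two small, standard additions proved necessary for reliable CPU-scale
optimization and are part of the architecture: a layer normalization between
the last attention layer and the pooled classifier input, and a small-scale
(σ = 0.01) initialization of the classification head so training starts at
the uniform-prediction loss. Gradients are clipped to a global norm of 5.
Softmax is always computed with max subtraction; batch normalization uses
population variance with momentum 0.1 and ε = 1e−5; ties in max-pooling and
argmax take the first index; all arithmetic is double precision, and eval
mode is bit-deterministic. The optimizer is AdamW with decoupled weight
decay that skips biases and normalization parameters.

## Training regime

Defaults: AdamW, learning rate 1e−3 decaying to 1e−6 under cosine annealing
with warm restarts (first period 10 epochs, period multiplier 2 — three
restarts inside an 80-epoch budget), weight decay 1e−4, batch size 32,
early stopping with patience 10 on validation loss, cross-entropy over the
five classes, no class reweighting (the dataset is balanced by
construction). Both an 80/20 stratified holdout and stratified 5-fold
cross-validation are provided; the standardizer is refitted on each
training portion and carries a provenance tag so leakage is auditable.
Training batches apply horizontal-flip image augmentation by default — all
lesion motifs are mirror-invariant, and the small-sample image branch
overfits badly without it. Mixed precision is not available on the CPU
path; the flag exists and errors if enabled.

## The synthetic data generator

No paired multimodal pneumonia dataset is publicly deposited, so the
package generates one with the statistical structure the task needs. The
generator's defaults are the study conditions of the package and are not
tuned per experiment:

* **Classes and counts.** normal 2,013 / tuberculosis 2,034 / viral 2,009 /
  bacterial 2,008 / covid19 2,031 (10,095 total) by default.
* **Images** are parametric phantoms: two elliptical dark lung fields over
  bright soft tissue with smooth plus pixel noise, and class-specific
  lesions — peripheral ground-glass blobs confined to the outer 25% of the
  lung-ellipse radius (covid19), small upper-lobe nodules (tuberculosis), a
  single dense medial consolidation whose mask centroid falls in the
  central third of the image (bacterial), diffuse lower-lobe haze (viral),
  nothing (normal). The lesion mask and lung geometry are returned with the
  image so localization statistics have analytic ground truth.
* **Labs** are Gaussian per indicator, truncated at zero, with
  class-conditional means for the five named indicators (WBC, NEUT%,
  LYMP%, CRP, PCT) and class-neutral distributions for ten biochemistry
  placeholders. The configured ordering encodes the clinical structure:
  bacterial WBC/CRP highest, viral LYMP% highest, COVID-19 lymphopenic.
* **Texts** are sentence templates with slot fillers over a fixed shipped
  lexicon (~580 tokens, whitespace tokenization, ids by lexicon order),
  expanding to 30–70 words with long-run means near 50.
* **Deliberate ambiguity.** Each modality alone is informative but
  imperfect: 15% of disease images render faint lesions, 20% of disease
  texts use a nonspecific template, viral and COVID-19 share symptom
  vocabulary, and tuberculosis and COVID-19 overlap in labs. This
  complementarity — not any single modality — is what the fusion model can
  exploit, which is exactly the property the ablation study measures.

Manifests are produced eagerly (ids, labels, stratified folds, 80/20 flags,
and five per-sample RNG substream seeds); images, labs and texts materialize
lazily and deterministically from their substreams, in any order.

What the generator does **not** emulate: CT physics (no ray artifacts,
windowing, 3-D structure), free clinical language, correlated lab panels,
scanner or site effects, label noise, or class imbalance. Passing the
package's tests therefore demonstrates that the architecture and training
machinery work and that fusion exploits complementary signal — it does not
certify performance on real CT data.

## Problem sizes

The standard study configuration is 500 samples (100 per class) at 64×64
resolution with the `desk64` preset (16 image tokens, fusion window
`M = 10`, 2 attention layers), trained within a 20-epoch budget — the full
four-modality model reaches high validation accuracy in a few minutes on
one CPU, and each single-modality ablation trains the same way. The
`desk224` preset keeps the native 224×224 geometry (49 image tokens,
`M = 13`, 4 layers) for forward-path and localization work; the `paper`
preset instantiates the full-width backbone (stage layout 3-4-6-3) for
profiling. Parameter counts of the reference baselines (VGG16, ResNet50/18,
DenseNet121, Inception v3) are computed from exact layer tables along two
independent counting paths rather than by instantiating the weights.

## Interpretability

Grad-CAM explains the image branch at the GCSA output map (the most
informative target: it is the map the classifier actually consumes):
channel-pooled gradients weight the activations, and the rectified sum is
upsampled and max-normalized. The upsampling is receptive-field aligned —
the stride-2, odd-kernel backbone centers map cell `u` at input pixel
`(u-1)·s + 1`, not `(u-0.5)·s`, and ignoring that half-cell offset
visibly degrades localization statistics at coarse map sizes. The
generator's lesion masks give an analytic localization statistic — the
fraction of heatmap mass inside the mask — which the tests compare between
a trained model and a random-weight control averaged over three random
builds (a single random CNN's saliency is itself high-variance). The
localization study uses the `loc64` preset — an image-only model with a
wider backbone and an 8×8 attended map — because the fused `desk64` model
can lean on text and labs, and a 4×4 map cannot resolve the smaller
lesions: explaining the image branch is only meaningful in a model whose
image branch carries the decision. Modality contributions are quantified
by occlusion
(remove a modality's tokens, record the accuracy drop, floor at zero,
normalize); the upstream contribution percentages reported for such models
in the literature are measurements under unspecified methods, and no
numeric agreement with them is claimed. All attention distributions
(per-layer, per-head, per-window fusion attention and both text branches'
pooling weights) are exportable with token indices.

## Known limitations

The desk-scale widths are far narrower than production backbones; the
BiLSTM processes padded positions in its backward direction (pooling masks
them, but backward-direction states at real positions have passed through
pads); CBAM is available for parameter accounting and forward comparison
but not for training; FLOP counts cover convolution and linear layers only,
under a multiply-accumulate convention, and counting conventions differ
across published tools; and every empirical number in this package is
computed on synthetic data.
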
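# Assembly of the full multimodal classifier: image branch, two independent
# text branches (clinical notes, radiology reports), numeric branch, and the
# shifted-window fusion core with its classification head.

#' Build a model configuration
#'
#' Presets: `"desk64"` (64x64 images, 16 image tokens; the scale used for
#' CPU training experiments), `"desk224"` (224x224 images, 49 image tokens;
#' the default forward configuration), and `"paper"` (full-width backbone
#' with stage layout 3-4-6-3; used for profiling and smoke tests, not CPU
#' training). The fusion dimension is 96 in every preset.
#'
#' Presets: `"loc64"` is the localization-study configuration — an
#' image-only-oriented backbone at 64x64 with more capacity (stem 12,
#' widths 24/48, two blocks per stage) and an 8x8 attended map, used where
#' Grad-CAM needs spatial resolution.
#'
#' @param preset one of `"desk64"`, `"desk224"`, `"paper"`, `"loc64"`.
#' @param modalities modality subset to fuse (token removal for ablations).
#' @param attention image-branch attention block variant.
#' @param ... named overrides of individual fields (e.g. `dropout`).
#' @return nested configuration list for [build_model()].
#' @export
model_config <- function(preset = c("desk64", "desk224", "paper", "loc64"),
                         modalities = c("image", "clinical", "report",
                                        "numeric"),
                         attention = "gcsa", ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk64 = list(
      image = list(input_size = 64, stem_channels = 8, stem_kernel = 5,
                   stem_stride = 2, widths = c(16, 32), strides = c(2, 2),
                   dsc_stages = c(FALSE, TRUE), blocks = c(1, 1),
                   reduction = 4, shuffle_groups = 4),
      text = list(d_embed = 32, h_per_dir = 32, d_out = 32, max_len = 96),
      fusion = list(D = 96, heads = 3, dk = 32, M = 10, n_layers = 2,
                    ffn_hidden = 192)),
    loc64 = list(
      image = list(input_size = 64, stem_channels = 12, stem_kernel = 5,
                   stem_stride = 2, widths = c(24, 48), strides = c(1, 2),
                   dsc_stages = c(FALSE, TRUE), blocks = c(2, 2),
                   reduction = 4, shuffle_groups = 4),
      text = list(d_embed = 32, h_per_dir = 32, d_out = 32, max_len = 96),
      fusion = list(D = 96, heads = 3, dk = 32, M = 10, n_layers = 2,
                    ffn_hidden = 192)),
    desk224 = list(
      image = list(input_size = 224, stem_channels = 8, stem_kernel = 7,
                   stem_stride = 2, widths = c(8, 16, 32, 64),
                   strides = c(1, 2, 2, 2),
                   dsc_stages = c(FALSE, FALSE, TRUE, TRUE),
                   blocks = c(1, 1, 1, 1), reduction = 4,
                   shuffle_groups = 4),
      text = list(d_embed = 32, h_per_dir = 32, d_out = 32, max_len = 128),
      fusion = list(D = 96, heads = 3, dk = 32, M = 13, n_layers = 4,
                    ffn_hidden = 192)),
    paper = list(
      image = list(input_size = 224, stem_channels = 64, stem_kernel = 7,
                   stem_stride = 2, widths = c(64, 128, 256, 512),
                   strides = c(1, 2, 2, 2),
                   dsc_stages = c(FALSE, FALSE, TRUE, TRUE),
                   blocks = c(3, 4, 6, 3), reduction = 16,
                   shuffle_groups = 4),
      text = list(d_embed = 128, h_per_dir = 128, d_out = 128,
                  max_len = 128),
      fusion = list(D = 96, heads = 3, dk = 32, M = 13, n_layers = 4,
                    ffn_hidden = 384)))
  cfg <- c(base, list(
    preset = preset,
    modalities = modalities,
    attention = attention,
    numeric = list(d_in = 15, hidden = c(64, 32), d_out = 32),
    dropout = 0.3,
    n_classes = 5))
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Build the multimodal model
#'
#' Instantiates the configured branches and fusion core with freshly
#' initialized parameters (seed the RNG first for reproducible builds).
#' Masked modalities are not built and contribute no tokens.
#'
#' @param config from [model_config()].
#' @param vocab_size lexicon size + 2 reserved ids (default: shipped
#'   lexicon).
#' @return model object with `forward`, `backward`, `predict`, `params`,
#'   `bn_layers`, and the component branches.
#' @export
build_model <- function(config = model_config(),
                        vocab_size = length(load_lexicon()) + 2L) {
  m <- new_layer()
  m$config <- config
  mods <- config$modalities
  m$modalities <- mods
  dims <- list()
  if ("image" %in% mods) {
    ic <- config$image
    m$image <- image_branch(
      input_size = ic$input_size, stem_channels = ic$stem_channels,
      stem_kernel = ic$stem_kernel, stem_stride = ic$stem_stride,
      widths = ic$widths, strides = ic$strides,
      dsc_stages = ic$dsc_stages, blocks = ic$blocks,
      attention = config$attention, shuffle_groups = ic$shuffle_groups,
      reduction = ic$reduction)
    dims$image <- m$image$out_channels
  }
  for (tb in c("clinical", "report")) {
    if (!(tb %in% mods)) next
    tc <- config$text
    m[[tb]] <- text_branch(vocab_size, d_embed = tc$d_embed,
                           h_per_dir = tc$h_per_dir, d_out = tc$d_out,
                           dropout = config$dropout, max_len = tc$max_len)
    dims[[tb]] <- tc$d_out
  }
  if ("numeric" %in% mods) {
    nc <- config$numeric
    m$numeric <- numeric_branch(d_in = nc$d_in, hidden = nc$hidden,
                                d_out = nc$d_out, dropout = config$dropout)
    dims$numeric <- nc$d_out
  }
  fc <- config$fusion
  m$fusion <- fusion_core(
    dims = dims,
    n_image_tokens = if ("image" %in% mods) m$image$n_tokens else 0,
    D = fc$D, heads = fc$heads, dk = fc$dk, M = fc$M,
    n_layers = fc$n_layers, n_classes = config$n_classes,
    modalities = mods, ffn_hidden = fc$ffn_hidden)
  m$params <- c(if ("image" %in% mods) m$image$params,
                if ("clinical" %in% mods) m$clinical$params,
                if ("report" %in% mods) m$report$params,
                if ("numeric" %in% mods) m$numeric$params,
                m$fusion$params)
  m$bn_layers <- if ("image" %in% mods) m$image$bn_layers else list()

  # batch: list(images (H,W,1,B), clinical_ids/lengths, report_ids/lengths,
  #             labs (B x 15, standardized), labels (B))
  m$forward <- function(batch, train = FALSE, drop = character(0)) {
    active <- setdiff(mods, drop)
    bo <- list()
    if ("image" %in% active) {
      io <- m$image$forward(batch$images, train)
      bo$image <- io$tokens
    }
    if ("clinical" %in% active) {
      bo$clinical <- m$clinical$forward(batch$clinical_ids,
                                        batch$clinical_len, train)
    }
    if ("report" %in% active) {
      bo$report <- m$report$forward(batch$report_ids, batch$report_len,
                                    train)
    }
    if ("numeric" %in% active) {
      bo$numeric <- m$numeric$forward(batch$labs, train)
    }
    m$fusion$forward(bo, train, drop = drop)
  }

  m$backward <- function(dlogits) {
    dbo <- m$fusion$backward(dlogits)
    if ("image" %in% mods) m$image$backward(dbo$image)
    if ("clinical" %in% mods) m$clinical$backward(dbo$clinical)
    if ("report" %in% mods) m$report$backward(dbo$report)
    if ("numeric" %in% mods) m$numeric$backward(dbo$numeric)
    invisible(NULL)
  }

  m$predict <- function(batch, drop = character(0)) {
    logits <- m$forward(batch, train = FALSE, drop = drop)
    p <- softmax_rows(logits)
    list(logits = logits, probabilities = p,
         labels = max.col(logits, ties.method = "first"))
  }
  m
}

#' Assemble a training batch from materialized samples
#'
#' Pads the token sequences, stacks the images, and standardizes the labs
#' with the supplied (training-fitted) standardizer.
#'
#' @param samples list of [materialize_sample()] outputs.
#' @param std a [fit_standardizer()] object.
#' @param modalities modalities to include.
#' @return batch list consumable by the model's `forward`.
#' @export
prepare_batch <- function(samples, std,
                          modalities = c("image", "clinical", "report",
                                         "numeric")) {
  B <- length(samples)
  out <- list(labels = vapply(samples, `[[`, 1L, "label_id"))
  if ("image" %in% modalities) {
    sz <- nrow(samples[[1]]$image)
    imgs <- array(0, c(sz, sz, 1, B))
    for (b in seq_len(B)) imgs[, , 1, b] <- samples[[b]]$image
    out$images <- imgs
  }
  for (tb in c("clinical", "report")) {
    if (!(tb %in% modalities)) next
    toks <- lapply(samples, function(s) s[[tb]]$tokens)
    lens <- vapply(toks, length, integer(1))
    Tm <- max(lens)
    ids <- matrix(0L, B, Tm)
    for (b in seq_len(B)) ids[b, seq_len(lens[b])] <- toks[[b]]
    out[[paste0(tb, "_ids")]] <- ids
    out[[paste0(tb, "_len")]] <- lens
  }
  if ("numeric" %in% modalities) {
    labs <- t(vapply(samples, `[[`, numeric(15), "labs"))
    out$labs <- apply_standardizer(std, labs)
  }
  out
}
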
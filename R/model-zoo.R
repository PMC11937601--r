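# Reference architecture tables and the parameter/FLOP profiler.
#
# Baselines are represented as exact layer tables (one row per parameterized
# layer, with both a closed-form parameter count and the parameter array
# shapes), so architecture-determined numbers are reproduced without
# instantiating hundreds of millions of weights. FLOPs are counted as
# multiply-accumulate pairs of convolution and linear layers at the stated
# input resolution (normalization, pooling and activations are not counted);
# the convention travels with the profile.

pf_arch_new <- function(name, num_classes, in_channels, input_size) {
  structure(list(name = name, num_classes = num_classes,
                 in_channels = in_channels, input_size = input_size,
                 layers = list()),
            class = "pf_architecture")
}

pf_arch_add <- function(arch, name, type, count, shapes, macs = 0) {
  arch$layers[[length(arch$layers) + 1]] <-
    list(name = name, type = type, count = count, shapes = shapes,
         macs = macs)
  arch
}

# conv: kh x kw, cin -> cout at output spatial ho x wo
pf_conv_entry <- function(arch, name, kh, kw, cin, cout, ho, wo,
                          bias = FALSE, bn = TRUE) {
  cnt <- kh * kw * cin * cout + if (bias) cout else 0
  shp <- list(c(kh, kw, cin, cout))
  if (bias) shp <- c(shp, list(cout))
  arch <- pf_arch_add(arch, name, "conv", cnt, shp,
                      macs = kh * kw * cin * cout * ho * wo)
  if (bn) {
    arch <- pf_arch_add(arch, paste0(name, ".bn"), "batchnorm", 2 * cout,
                        list(cout, cout))
  }
  arch
}

pf_linear_entry <- function(arch, name, d_in, d_out, bias = TRUE) {
  cnt <- d_in * d_out + if (bias) d_out else 0
  shp <- list(c(d_in, d_out))
  if (bias) shp <- c(shp, list(d_out))
  pf_arch_add(arch, name, "linear", cnt, shp, macs = d_in * d_out)
}

# ---- VGG16 -------------------------------------------------------------------

pf_arch_vgg16 <- function(num_classes = 5, in_channels = 3,
                          input_size = 224) {
  cfg <- list(c(64, 64), c(128, 128), c(256, 256, 256),
              c(512, 512, 512), c(512, 512, 512))
  a <- pf_arch_new("vgg16", num_classes, in_channels, input_size)
  cin <- in_channels
  s <- input_size
  li <- 0
  for (blk in seq_along(cfg)) {
    for (cout in cfg[[blk]]) {
      li <- li + 1
      a <- pf_conv_entry(a, sprintf("conv%d", li), 3, 3, cin, cout, s, s,
                         bias = TRUE, bn = FALSE)
      cin <- cout
    }
    s <- s %/% 2
  }
  a <- pf_linear_entry(a, "fc1", 512 * s * s, 4096)
  a <- pf_linear_entry(a, "fc2", 4096, 4096)
  a <- pf_linear_entry(a, "fc3", 4096, num_classes)
  a
}

# ---- ResNet ------------------------------------------------------------------

pf_arch_resnet <- function(depth = c("resnet50", "resnet18"),
                           num_classes = 5, in_channels = 3,
                           input_size = 224) {
  depth <- match.arg(depth)
  bottleneck <- depth == "resnet50"
  layers <- if (bottleneck) c(3, 4, 6, 3) else c(2, 2, 2, 2)
  expansion <- if (bottleneck) 4 else 1
  a <- pf_arch_new(depth, num_classes, in_channels, input_size)
  s <- input_size %/% 2
  a <- pf_conv_entry(a, "conv1", 7, 7, in_channels, 64, s, s)
  s <- s %/% 2
  cin <- 64
  for (st in 1:4) {
    planes <- 64 * 2^(st - 1)
    stride <- if (st == 1) 1 else 2
    for (b in seq_len(layers[st])) {
      bs <- if (b == 1) stride else 1
      so <- if (b == 1) s %/% stride else s
      nm <- sprintf("layer%d.%d", st, b - 1)
      if (bottleneck) {
        a <- pf_conv_entry(a, paste0(nm, ".conv1"), 1, 1, cin, planes, so, so)
        a <- pf_conv_entry(a, paste0(nm, ".conv2"), 3, 3, planes, planes,
                           so, so)
        a <- pf_conv_entry(a, paste0(nm, ".conv3"), 1, 1, planes,
                           planes * 4, so, so)
      } else {
        a <- pf_conv_entry(a, paste0(nm, ".conv1"), 3, 3, cin, planes, so, so)
        a <- pf_conv_entry(a, paste0(nm, ".conv2"), 3, 3, planes, planes,
                           so, so)
      }
      if (b == 1 && (bs != 1 || cin != planes * expansion)) {
        a <- pf_conv_entry(a, paste0(nm, ".downsample"), 1, 1, cin,
                           planes * expansion, so, so)
      }
      cin <- planes * expansion
      if (b == 1) s <- so
    }
  }
  pf_linear_entry(a, "fc", cin, num_classes)
}

# ---- DenseNet121 -------------------------------------------------------------

pf_arch_densenet121 <- function(num_classes = 5, in_channels = 3,
                                input_size = 224) {
  growth <- 32; bn_size <- 4
  blocks <- c(6, 12, 24, 16)
  a <- pf_arch_new("densenet121", num_classes, in_channels, input_size)
  s <- input_size %/% 2
  a <- pf_conv_entry(a, "conv0", 7, 7, in_channels, 64, s, s)
  s <- s %/% 2
  cin <- 64
  for (bl in seq_along(blocks)) {
    for (d in seq_len(blocks[bl])) {
      nm <- sprintf("block%d.layer%d", bl, d)
      # bn is part of conv entries (bn-relu-conv order; counts identical)
      a <- pf_conv_entry(a, paste0(nm, ".conv1"), 1, 1, cin,
                         bn_size * growth, s, s, bn = FALSE)
      a <- pf_arch_add(a, paste0(nm, ".norm1"), "batchnorm", 2 * cin,
                       list(cin, cin))
      a <- pf_conv_entry(a, paste0(nm, ".conv2"), 3, 3, bn_size * growth,
                         growth, s, s, bn = FALSE)
      a <- pf_arch_add(a, paste0(nm, ".norm2"), "batchnorm",
                       2 * bn_size * growth,
                       list(bn_size * growth, bn_size * growth))
      cin <- cin + growth
    }
    if (bl < length(blocks)) {
      a <- pf_arch_add(a, sprintf("transition%d.norm", bl), "batchnorm",
                       2 * cin, list(cin, cin))
      a <- pf_conv_entry(a, sprintf("transition%d.conv", bl), 1, 1, cin,
                         cin %/% 2, s, s, bn = FALSE)
      cin <- cin %/% 2
      s <- s %/% 2
    }
  }
  a <- pf_arch_add(a, "norm5", "batchnorm", 2 * cin, list(cin, cin))
  pf_linear_entry(a, "fc", cin, num_classes)
}

# ---- Inception v3 (no auxiliary head) ----------------------------------------

pf_arch_inception_v3 <- function(num_classes = 5, in_channels = 3,
                                 input_size = 299) {
  a <- pf_arch_new("inception_v3", num_classes, in_channels, input_size)
  cv <- function(a, nm, kh, kw, cin, cout, s) {
    pf_conv_entry(a, nm, kh, kw, cin, cout, s, s)
  }
  a <- cv(a, "1a", 3, 3, in_channels, 32, 149)
  a <- cv(a, "2a", 3, 3, 32, 32, 147)
  a <- cv(a, "2b", 3, 3, 32, 64, 147)
  a <- cv(a, "3b", 1, 1, 64, 80, 73)
  a <- cv(a, "4a", 3, 3, 80, 192, 71)
  incA <- function(a, nm, cin, pf, s = 35) {
    a <- cv(a, paste0(nm, ".b1"), 1, 1, cin, 64, s)
    a <- cv(a, paste0(nm, ".b5_1"), 1, 1, cin, 48, s)
    a <- cv(a, paste0(nm, ".b5_2"), 5, 5, 48, 64, s)
    a <- cv(a, paste0(nm, ".b3d_1"), 1, 1, cin, 64, s)
    a <- cv(a, paste0(nm, ".b3d_2"), 3, 3, 64, 96, s)
    a <- cv(a, paste0(nm, ".b3d_3"), 3, 3, 96, 96, s)
    cv(a, paste0(nm, ".pool"), 1, 1, cin, pf, s)
  }
  a <- incA(a, "5b", 192, 32)
  a <- incA(a, "5c", 256, 64)
  a <- incA(a, "5d", 288, 64)
  # reduction (288 -> 768, 35 -> 17)
  a <- cv(a, "6a.b3", 3, 3, 288, 384, 17)
  a <- cv(a, "6a.b3d_1", 1, 1, 288, 64, 35)
  a <- cv(a, "6a.b3d_2", 3, 3, 64, 96, 35)
  a <- cv(a, "6a.b3d_3", 3, 3, 96, 96, 17)
  incC <- function(a, nm, c7, s = 17) {
    a <- cv(a, paste0(nm, ".b1"), 1, 1, 768, 192, s)
    a <- cv(a, paste0(nm, ".b7_1"), 1, 1, 768, c7, s)
    a <- cv(a, paste0(nm, ".b7_2"), 1, 7, c7, c7, s)
    a <- cv(a, paste0(nm, ".b7_3"), 7, 1, c7, 192, s)
    a <- cv(a, paste0(nm, ".b7d_1"), 1, 1, 768, c7, s)
    a <- cv(a, paste0(nm, ".b7d_2"), 7, 1, c7, c7, s)
    a <- cv(a, paste0(nm, ".b7d_3"), 1, 7, c7, c7, s)
    a <- cv(a, paste0(nm, ".b7d_4"), 7, 1, c7, c7, s)
    a <- cv(a, paste0(nm, ".b7d_5"), 1, 7, c7, 192, s)
    cv(a, paste0(nm, ".pool"), 1, 1, 768, 192, s)
  }
  a <- incC(a, "6b", 128)
  a <- incC(a, "6c", 160)
  a <- incC(a, "6d", 160)
  a <- incC(a, "6e", 192)
  # reduction (768 -> 1280, 17 -> 8)
  a <- cv(a, "7a.b3_1", 1, 1, 768, 192, 17)
  a <- cv(a, "7a.b3_2", 3, 3, 192, 320, 8)
  a <- cv(a, "7a.b7_1", 1, 1, 768, 192, 17)
  a <- cv(a, "7a.b7_2", 1, 7, 192, 192, 17)
  a <- cv(a, "7a.b7_3", 7, 1, 192, 192, 17)
  a <- cv(a, "7a.b7_4", 3, 3, 192, 192, 8)
  incE <- function(a, nm, cin, s = 8) {
    a <- cv(a, paste0(nm, ".b1"), 1, 1, cin, 320, s)
    a <- cv(a, paste0(nm, ".b3_1"), 1, 1, cin, 384, s)
    a <- cv(a, paste0(nm, ".b3_2a"), 1, 3, 384, 384, s)
    a <- cv(a, paste0(nm, ".b3_2b"), 3, 1, 384, 384, s)
    a <- cv(a, paste0(nm, ".b3d_1"), 1, 1, cin, 448, s)
    a <- cv(a, paste0(nm, ".b3d_2"), 3, 3, 448, 384, s)
    a <- cv(a, paste0(nm, ".b3d_3a"), 1, 3, 384, 384, s)
    a <- cv(a, paste0(nm, ".b3d_3b"), 3, 1, 384, 384, s)
    cv(a, paste0(nm, ".pool"), 1, 1, cin, 192, s)
  }
  a <- incE(a, "7b", 1280)
  a <- incE(a, "7c", 2048)
  pf_linear_entry(a, "fc", 2048, num_classes)
}

#' Build a reference baseline architecture
#'
#' Returns the exact layer table of a standard architecture with only the
#' final classifier resized to `num_classes`, for use with
#' [profile_architecture()]. `densenet` and `inception` alias the canonical
#' densenet121 / inception_v3 (without auxiliary head) variants.
#'
#' @param name one of `resnet50`, `resnet18`, `vgg16`, `densenet121`,
#'   `inception_v3` (aliases `densenet`, `inception`).
#' @param num_classes classifier width.
#' @param in_channels input channels (3 = replicated-grayscale CT).
#' @param input_size input spatial side for the FLOP count.
#' @return object of class `pf_architecture`.
#' @export
build_baseline <- function(name, num_classes = 5, in_channels = 3,
                           input_size = NULL) {
  name <- switch(name, densenet = "densenet121", inception = "inception_v3",
                 name)
  switch(name,
    vgg16 = pf_arch_vgg16(num_classes, in_channels,
                          input_size %||% 224),
    resnet50 = pf_arch_resnet("resnet50", num_classes, in_channels,
                              input_size %||% 224),
    resnet18 = pf_arch_resnet("resnet18", num_classes, in_channels,
                              input_size %||% 224),
    densenet121 = pf_arch_densenet121(num_classes, in_channels,
                                      input_size %||% 224),
    inception_v3 = pf_arch_inception_v3(num_classes, in_channels,
                                        input_size %||% 299),
    stop("build_baseline: unknown architecture: ", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameter count of a post-backbone attention block at channel width C
pf_attention_entry <- function(variant, C, reduction = 16) {
  h <- C %/% reduction
  switch(variant,
    none = list(count = 0, shapes = list()),
    sea = list(count = C * h + h + h * C + C,
               shapes = list(c(C, h), h, c(h, C), C)),
    cbam = list(count = C * h + h * C + 7 * 7 * 2 + 1,
                shapes = list(c(C, h), c(h, C), c(7, 7, 2, 1), 1)),
    eca = list(count = 5, shapes = list(5)),
    gcsa = list(count = C * h + h + h * C + C + 7 * 7 * 2 + 1,
                shapes = list(c(C, h), h, c(h, C), C, c(7, 7, 2, 1), 1)),
    stop("swap_attention: unknown variant: ", variant))
}

#' Insert an attention block into a baseline architecture
#'
#' Appends the chosen attention block (`none`, `sea`, `cbam`, `eca`,
#' `gcsa`) at the post-backbone position (before the classifier), at the
#' backbone's final channel width, so variants are compared in a controlled
#' way. For runnable models built with [build_model()], choose the variant
#' through `model_config(attention = ...)` instead.
#'
#' @param arch a [build_baseline()] architecture.
#' @param variant attention block name.
#' @param reduction MLP reduction ratio.
#' @return the architecture with the block inserted.
#' @export
swap_attention <- function(arch, variant, reduction = 16) {
  stopifnot(inherits(arch, "pf_architecture"))
  if (variant == "none") return(arch)
  fc <- arch$layers[[length(arch$layers)]]
  C <- fc$shapes[[1]][1]
  e <- pf_attention_entry(variant, C, reduction)
  arch$layers <- append(arch$layers,
                        list(list(name = paste0("attention.", variant),
                                  type = "attention", count = e$count,
                                  shapes = e$shapes, macs = 0)),
                        after = length(arch$layers) - 1)
  arch$name <- paste0(arch$name, "+", variant)
  arch
}

#' Profile an architecture table
#'
#' Sums trainable parameters along two independent paths — the closed-form
#' per-layer counts and the products of the recorded parameter-array shapes
#' — and errors if they disagree. FLOPs are multiply-accumulates of
#' convolution and linear layers at the architecture's input size.
#'
#' @param arch a [build_baseline()] (optionally [swap_attention()]-modified)
#'   architecture.
#' @return a `ModelProfile` list: `name`, `params_exact`,
#'   `params_millions` (2 dp), `flops_g` (2 dp), `input_spec`,
#'   `num_classes`, `convention`.
#' @export
profile_architecture <- function(arch) {
  counts <- vapply(arch$layers, `[[`, 0, "count")
  shapes <- unlist(lapply(arch$layers, function(l)
    vapply(l$shapes, prod, 0)))
  by_formula <- sum(counts)
  by_shape <- sum(shapes)
  if (by_formula != by_shape) {
    stop("profile_architecture: count paths disagree (", by_formula,
         " vs ", by_shape, ")")
  }
  macs <- sum(vapply(arch$layers, `[[`, 0, "macs"))
  list(name = arch$name,
       params_exact = by_formula,
       params_millions = round(by_formula / 1e6, 2),
       macs_exact = macs,
       flops_g = round(macs / 1e9, 2),
       input_spec = sprintf("%dx%dx%d", arch$in_channels, arch$input_size,
                            arch$input_size),
       num_classes = arch$num_classes,
       convention = "multiply-accumulate pairs; conv and linear layers only")
}

#' Profile a runnable model
#'
#' Counts the trainable parameters of a built model along two independent
#' paths: the summed `length()` of every parameter array and the summed
#' products of their dimensions.
#'
#' @param model a [build_model()] model or any object with a `params` list.
#' @return list with `params_exact`, `params_millions` and `n_arrays`.
#' @export
profile_model <- function(model) {
  by_length <- sum(vapply(model$params, function(p) length(p$value),
                          numeric(1)))
  by_shape <- sum(vapply(model$params, function(p) {
    d <- dim(p$value)
    if (is.null(d)) length(p$value) else prod(d)
  }, numeric(1)))
  if (by_length != by_shape) {
    stop("profile_model: count paths disagree")
  }
  list(params_exact = by_length,
       params_millions = round(by_length / 1e6, 2),
       n_arrays = length(model$params))
}
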
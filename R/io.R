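# Shared I/O: the fixed lexicon and tokenizer, dataset writing/reading
# (8-bit grayscale PNG images, plain-text notes, CSV labs + manifest), YAML
# run configuration, and checkpoint save/load.

pf_env <- new.env(parent = emptyenv())

#' Load the shipped token lexicon
#'
#' One token per line; token ids are assigned by line order. Two reserved ids
#' follow the lexicon: `length(lexicon) + 1` is the unknown-word id,
#' `length(lexicon) + 2` the padding id.
#'
#' @param path lexicon file (defaults to the copy shipped with the package).
#' @return named integer vector mapping token to id.
#' @export
load_lexicon <- function(path = system.file("extdata", "lexicon.txt",
                                            package = "pneumodal")) {
  key <- paste0("lex:", path)
  if (!is.null(pf_env[[key]])) return(pf_env[[key]])
  words <- readLines(path, encoding = "UTF-8")
  words <- words[nzchar(words)]
  lex <- stats::setNames(seq_along(words), words)
  pf_env[[key]] <- lex
  lex
}

#' Unknown-word and padding ids of a lexicon
#' @param lexicon from [load_lexicon()].
#' @return integer id.
#' @export
unk_id <- function(lexicon) length(lexicon) + 1L

#' @rdname unk_id
#' @export
pad_id <- function(lexicon) length(lexicon) + 2L

#' Tokenize free text over the lexicon
#'
#' Lowercases, strips punctuation, splits on whitespace, and maps each word
#' to its lexicon id. In strict mode (default) an out-of-lexicon word is an
#' error; with `permissive = TRUE` it maps to the unknown id.
#'
#' @param text character scalar.
#' @param lexicon from [load_lexicon()].
#' @param permissive map unknown words to `unk_id` instead of erroring.
#' @return integer vector of token ids.
#' @export
tokenize_text <- function(text, lexicon = load_lexicon(),
                          permissive = FALSE) {
  words <- tolower(text)
  words <- gsub("[^a-z0-9%' ]+", " ", words)
  words <- strsplit(trimws(words), "[[:space:]]+")[[1]]
  ids <- unname(lexicon[words])
  if (anyNA(ids)) {
    if (!permissive) {
      stop("tokenize_text: word(s) outside the lexicon: ",
           paste(unique(words[is.na(ids)]), collapse = ", "))
    }
    ids[is.na(ids)] <- unk_id(lexicon)
  }
  as.integer(ids)
}

# ---- dataset on disk ---------------------------------------------------------

#' Write a materialized dataset to a directory
#'
#' Layout: `manifest.csv` (sample_id, label, image_path,
#' clinical_text_path, report_text_path, fold, is_train), `labs.csv` (header
#' row naming the 15 indicators), `images/*.png` (8-bit grayscale),
#' `texts/*.txt`, and a copy of the lexicon.
#'
#' @param manifest a [generate_dataset()] manifest.
#' @param dir output directory (created).
#' @param rows which rows to write (default all).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(manifest, dir, rows = seq_len(nrow(manifest))) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "texts"), showWarnings = FALSE)
  lex <- load_lexicon()
  labm <- matrix(0, length(rows), 15, dimnames = list(NULL, PF_LAB_NAMES))
  recs <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    s <- materialize_sample(manifest, rows[j], lexicon = lex)
    ip <- file.path("images", paste0(s$sample_id, ".png"))
    cp <- file.path("texts", paste0(s$sample_id, "_clinical.txt"))
    rp <- file.path("texts", paste0(s$sample_id, "_report.txt"))
    png::writePNG(s$image, file.path(dir, ip))
    writeLines(s$clinical$text, file.path(dir, cp))
    writeLines(s$report$text, file.path(dir, rp))
    labm[j, ] <- s$labs
    recs[[j]] <- data.frame(sample_id = s$sample_id, label = s$label,
                            image_path = ip, clinical_text_path = cp,
                            report_text_path = rp, fold = s$fold,
                            is_train = s$is_train, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, recs)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cbind(data.frame(sample_id = man$sample_id), labm),
                   file.path(dir, "labs.csv"), row.names = FALSE)
  writeLines(names(lex), file.path(dir, "lexicon.txt"))
  invisible(dir)
}

#' Read a written dataset
#'
#' Loads the manifest and labs eagerly and returns a lazy sample loader;
#' images decode to `[0,1]` grayscale matrices (16-bit PNGs are rescaled by
#' their dtype maximum), texts are tokenized through the directory's lexicon.
#'
#' @param dir dataset directory from [write_dataset()].
#' @return list with `manifest` (data frame), `labs` (matrix), `lexicon`,
#'   and `read_sample(i)`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("read_dataset: no manifest.csv under ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  bad <- setdiff(unique(man$label), PF_CLASSES)
  if (length(bad)) {
    stop("read_dataset: label(s) outside the class set: ",
         paste(bad, collapse = ", "))
  }
  labs <- utils::read.csv(file.path(dir, "labs.csv"), check.names = FALSE)
  labm <- as.matrix(labs[match(man$sample_id, labs$sample_id), -1])
  lex <- load_lexicon(file.path(dir, "lexicon.txt"))
  read_sample <- function(i) {
    row <- man[i, ]
    ip <- file.path(dir, row$image_path)
    if (!file.exists(ip)) {
      stop("read_dataset: missing image for sample ", row$sample_id)
    }
    img <- png::readPNG(ip)
    if (length(dim(img)) == 3) img <- img[, , 1]
    ct <- readLines(file.path(dir, row$clinical_text_path), warn = FALSE)
    rt <- readLines(file.path(dir, row$report_text_path), warn = FALSE)
    list(sample_id = row$sample_id, label = row$label,
         label_id = match(row$label, PF_CLASSES),
         image = img, labs = labm[i, ],
         clinical = list(text = ct, tokens = tokenize_text(ct, lex)),
         report = list(text = rt, tokens = tokenize_text(rt, lex)),
         fold = row$fold, is_train = row$is_train)
  }
  list(manifest = man, labs = labm, lexicon = lex, read_sample = read_sample)
}

# ---- run configuration -------------------------------------------------------

pf_default_config <- function() {
  list(
    seed = 1L,
    data = list(image_size = 64L, n_per_class = 100L),
    model = list(preset = "desk64", fusion_dim = 96L, heads = 3L, dk = 32L,
                 window = 10L, n_layers = 2L, dropout = 0.3,
                 attention = "gcsa", shuffle_groups = 4L),
    training = list(lr = 1e-3, weight_decay = 1e-4, batch_size = 32L,
                    epochs = 80L, early_stop_patience = 10L, lr_min = 1e-6,
                    t0 = 10L, t_mult = 2L, mixed_precision = FALSE,
                    cv_mode = "holdout_80_20", grad_clip = 5))
}

pf_merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("load_config: unknown key(s): ",
         paste(paste0(path, extra), collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- pf_merge_config(defaults[[nm]], user[[nm]],
                                        paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file, fills defaults (learning rate 1e-3, weight decay 1e-4,
#' batch size 32, fusion dimension 96, dropout 0.3), and rejects unknown
#' keys. An empty file yields the full default configuration.
#'
#' @param path YAML file.
#' @return validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pf_merge_config(pf_default_config(), user)
  if (cfg$training$lr <= cfg$training$lr_min) {
    stop("load_config: lr must exceed lr_min")
  }
  cfg
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameter values, the model configuration, and a
#' JSON sidecar records the configuration hash for reproducibility audits.
#'
#' @param model a built model (see [build_model()]).
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly; `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  snap <- params_snapshot(model$params)
  obj <- list(values = snap, config = model$config,
              bn_state = pf_bn_state(model))
  saveRDS(obj, path)
  side <- list(config_hash = pf_config_hash(model$config),
               n_params = sum(vapply(snap, length, numeric(1))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config)
  params_restore(model$params, obj$values)
  pf_bn_state(model, obj$bn_state)
  model
}

pf_config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  # small stable rolling hash; avoids a digest dependency
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

# get/set the batch-norm running statistics of every layer in a model
pf_bn_state <- function(model, state = NULL) {
  bns <- model$bn_layers
  if (is.null(state)) {
    lapply(bns, function(b) list(m = b$running_mean, v = b$running_var))
  } else {
    for (i in seq_along(bns)) {
      bns[[i]]$running_mean <- state[[i]]$m
      bns[[i]]$running_var <- state[[i]]$v
    }
    invisible(NULL)
  }
}
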
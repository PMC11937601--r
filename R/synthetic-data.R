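# Synthetic multimodal dataset generator.
#
# Emulates a five-class pneumonia dataset: class-conditional lung-CT-like
# phantom images (parametric lung fields + lesion motifs), templated clinical
# notes and radiology reports (~50 words) over a fixed shipped lexicon, and a
# 15-indicator laboratory panel with class-conditional Gaussian distributions
# truncated at physiological floors. Manifests are generated eagerly
# (deterministic per-sample RNG substreams); sample content is materialized
# lazily, so composition checks on 10k-sample manifests are instant.

PF_CLASSES <- c("normal", "tuberculosis", "viral", "bacterial", "covid19")

PF_LAB_NAMES <- c("WBC", "NEUT%", "LYMP%", "CRP", "PCT",
                  "ALB", "ALT", "AST", "LDH", "CREA",
                  "UREA", "GLU", "HGB", "PLT", "ESR")

# Class-conditional (mean, sd) for the five named indicators. The remaining
# ten are class-neutral biochemistry placeholders. Values chosen once to
# reflect typical presentations: bacterial -> elevated WBC/NEUT%/CRP/PCT;
# viral -> normal WBC, elevated LYMP%; covid -> lymphopenia with moderate
# CRP; tuberculosis -> mildly raised inflammatory markers.
pf_lab_table <- function() {
  neutral <- list(
    "ALB" = c(42, 4), "ALT" = c(24, 9), "AST" = c(26, 9),
    "LDH" = c(210, 45), "CREA" = c(72, 15), "UREA" = c(5.2, 1.4),
    "GLU" = c(5.6, 1.1), "HGB" = c(138, 14), "PLT" = c(240, 55),
    "ESR" = c(18, 10))
  named <- list(
    normal = list("WBC" = c(6.6, 1.4), "NEUT%" = c(58, 7),
                  "LYMP%" = c(31, 6), "CRP" = c(2.5, 1.8),
                  "PCT" = c(0.04, 0.03)),
    tuberculosis = list("WBC" = c(7.8, 1.9), "NEUT%" = c(66, 7),
                        "LYMP%" = c(24, 6), "CRP" = c(28, 14),
                        "PCT" = c(0.14, 0.10)),
    viral = list("WBC" = c(6.9, 1.6), "NEUT%" = c(54, 8),
                 "LYMP%" = c(42, 7), "CRP" = c(11, 6),
                 "PCT" = c(0.09, 0.05)),
    bacterial = list("WBC" = c(14.5, 3.2), "NEUT%" = c(83, 5),
                     "LYMP%" = c(11, 4), "CRP" = c(96, 32),
                     "PCT" = c(1.9, 0.9)),
    covid19 = list("WBC" = c(5.4, 1.4), "NEUT%" = c(63, 8),
                   "LYMP%" = c(17, 6), "CRP" = c(33, 16),
                   "PCT" = c(0.12, 0.08)))
  lapply(named, function(x) c(x, neutral)[PF_LAB_NAMES])
}

#' Default per-class lab distribution parameters
#'
#' @param label one of the five class labels.
#' @return named list of 15 `(mean, sd)` pairs, in panel order.
#' @export
default_lab_params <- function(label) {
  label <- match.arg(label, PF_CLASSES)
  pf_lab_table()[[label]]
}

#' Construct a class specification
#'
#' @param label class label, one of `normal`, `tuberculosis`, `viral`,
#'   `bacterial`, `covid19`.
#' @param count number of samples to generate for the class (positive).
#' @param image_motif lesion motif identifier (defaults to the label).
#' @param lab_params named list of 15 `(mean, sd)` pairs; sds must be
#'   strictly positive.
#' @param text_templates per-kind template sets (defaults to the shipped
#'   templates for the label).
#' @return object of class `pf_class_spec`.
#' @export
class_spec <- function(label, count, image_motif = label,
                       lab_params = default_lab_params(label),
                       text_templates = NULL) {
  label <- match.arg(label, PF_CLASSES)
  if (!is.numeric(count) || count < 1) {
    stop("class_spec: count must be a positive integer (", label, ")")
  }
  if (length(lab_params) != 15) {
    stop("class_spec: lab_params must have 15 (mean, sd) pairs")
  }
  sds <- vapply(lab_params, function(p) p[2], numeric(1))
  if (any(sds <= 0)) {
    stop("class_spec: lab sds must be strictly positive (",
         paste(names(lab_params)[sds <= 0], collapse = ", "), ")")
  }
  structure(list(label = label, count = as.integer(count),
                 image_motif = image_motif, lab_params = lab_params,
                 text_templates = text_templates),
            class = "pf_class_spec")
}

#' Default class specifications
#'
#' Five balanced classes with per-class counts 2,013 / 2,034 / 2,009 /
#' 2,008 / 2,031 (normal, tuberculosis, viral, bacterial, covid19; 10,095
#' total).
#'
#' @param counts named integer vector of per-class counts.
#' @return list of [class_spec()] objects.
#' @export
default_class_specs <- function(counts = c(normal = 2013, tuberculosis = 2034,
                                           viral = 2009, bacterial = 2008,
                                           covid19 = 2031)) {
  lapply(names(counts), function(lb) class_spec(lb, counts[[lb]]))
}

# ---- images ------------------------------------------------------------------

# Lung-field geometry as fractions of the image side (origin top-left,
# row-major); shared with the analytic band/centroid oracles in the tests.
pf_lung_geometry <- function(size) {
  list(centers = matrix(c(0.30, 0.52, 0.70, 0.52) * size, 2, 2, byrow = TRUE),
       rx = 0.16 * size, ry = 0.30 * size)
}

# Elliptical radial coordinate of every pixel w.r.t. the nearest lung center;
# < 1 inside a lung field.
pf_lung_radius <- function(size, geom = pf_lung_geometry(size)) {
  ys <- matrix(seq_len(size), size, size)          # rows
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  r <- array(Inf, c(size, size))
  for (k in 1:2) {
    rk <- sqrt(((xs - geom$centers[k, 1]) / geom$rx)^2 +
                 ((ys - geom$centers[k, 2]) / geom$ry)^2)
    r <- pmin(r, rk)
  }
  r
}

pf_blob <- function(size, cx, cy, sx, sy, intensity) {
  ys <- seq_len(size); xs <- seq_len(size)
  gy <- exp(-(ys - cy)^2 / (2 * sy^2))
  gx <- exp(-(xs - cx)^2 / (2 * sx^2))
  intensity * outer(gy, gx)
}

pf_smooth_noise <- function(size, coarse = 8, sd = 1) {
  pf_resize_bilinear(matrix(stats::rnorm(coarse^2, 0, sd), coarse, coarse),
                     size, size)
}

#' Render a synthetic chest-CT-like image for a lesion motif
#'
#' Draws two elliptical dark lung fields over bright soft tissue, then adds a
#' class-specific lesion pattern: peripheral ground-glass blobs (`covid19`),
#' upper-lobe nodular foci (`tuberculosis`), a central dense consolidation
#' (`bacterial`), diffuse lower-lobe haze (`viral`), or nothing (`normal`).
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param motif one of the five class labels.
#' @param size image side in pixels.
#' @param faint logical; render an attenuated (ambiguous) lesion.
#' @return list with `image` (`size x size` matrix in `[0,1]`), `mask`
#'   (logical lesion mask, all-`FALSE` for `normal`), and `geometry` (lung
#'   ellipse parameters, for analytic localization checks).
#' @export
render_image <- function(motif, size = 224, faint = FALSE) {
  if (!motif %in% PF_CLASSES) stop("render_image: unknown motif: ", motif)
  geom <- pf_lung_geometry(size)
  r <- pf_lung_radius(size, geom)
  lung <- r < 1
  img <- matrix(0.80, size, size)
  img[lung] <- 0.16
  img <- img + 0.05 * pf_smooth_noise(size) + matrix(
    stats::rnorm(size^2, 0, 0.02), size, size)
  lesion <- matrix(0, size, size)
  add_in_lung <- function(les, field) {
    les + field * lung
  }
  pick_lung <- function() geom$centers[sample(2, 1), ]
  if (motif == "covid19") {
    for (i in seq_len(sample(2:4, 1))) {
      ctr <- pick_lung()
      th <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.88, 0.96)
      cx <- ctr[1] + rad * geom$rx * cos(th)
      cy <- ctr[2] + rad * geom$ry * sin(th)
      # blob axes scale with the lung ellipse so the radial extent (and
      # hence band membership) is direction-independent
      lesion <- add_in_lung(lesion,
        pf_blob(size, cx, cy, max(0.07 * geom$rx, 1.5),
                max(0.07 * geom$ry, 1.5), 0.35))
    }
  } else if (motif == "tuberculosis") {
    for (i in seq_len(sample(3:6, 1))) {
      ctr <- pick_lung()
      cx <- ctr[1] + stats::runif(1, -0.55, 0.55) * geom$rx
      cy <- ctr[2] - stats::runif(1, 0.45, 0.85) * geom$ry
      lesion <- add_in_lung(lesion,
        pf_blob(size, cx, cy, 0.016 * size, 0.016 * size, 0.42))
    }
  } else if (motif == "bacterial") {
    ctr <- pick_lung()
    medial <- sign(size / 2 - ctr[1])
    cx <- ctr[1] + medial * stats::runif(1, 0.32, 0.55) * geom$rx
    cy <- ctr[2] + stats::runif(1, -0.25, 0.25) * geom$ry
    lesion <- add_in_lung(lesion,
      pf_blob(size, cx, cy, 0.055 * size, 0.075 * size, 0.46))
  } else if (motif == "viral") {
    for (k in 1:2) {
      ctr <- geom$centers[k, ]
      cx <- ctr[1] + stats::runif(1, -0.2, 0.2) * geom$rx
      cy <- ctr[2] + stats::runif(1, 0.45, 0.65) * geom$ry
      tex <- 0.5 + 0.5 * pmin(pmax(pf_smooth_noise(size, 6, 0.8) + 1, 0), 2) / 2
      lesion <- add_in_lung(lesion,
        pf_blob(size, cx, cy, 0.10 * size, 0.085 * size, 0.20) * tex)
    }
  }
  if (faint) lesion <- lesion * 0.35
  mask <- lesion > 0.05
  img <- pmin(pmax(img + lesion, 0), 1)
  list(image = img, mask = mask, geometry = geom)
}

# ---- labs --------------------------------------------------------------------

#' Draw one 15-indicator lab vector
#'
#' Gaussian per-indicator draws with the configured class-conditional means
#' and standard deviations, truncated at zero (no negative concentrations).
#' A zero sd yields the mean exactly (degenerate noise); negative sds are a
#' configuration error.
#'
#' @param lab_params named list of 15 `(mean, sd)` pairs.
#' @return named numeric vector of length 15.
#' @export
sample_labs <- function(lab_params) {
  if (length(lab_params) != 15) {
    stop("sample_labs: 15 (mean, sd) pairs required, got ",
         length(lab_params))
  }
  sds <- vapply(lab_params, function(p) p[2], numeric(1))
  if (any(sds < 0)) stop("sample_labs: negative sd is a configuration error")
  mus <- vapply(lab_params, function(p) p[1], numeric(1))
  v <- stats::rnorm(15, mus, sds)
  v <- pmax(v, 0)
  names(v) <- names(lab_params)
  v
}

# ---- text --------------------------------------------------------------------

# A template is a list of sentences; each sentence has an inclusion
# probability and a vector of variants (strings with {slot} placeholders).
pf_sentence <- function(p, ...) list(p = p, variants = c(...))

pf_slot_fillers <- function() {
  list(
    age = c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
            "eighty"),
    sex = c("male", "female"),
    dur = c("two days", "three days", "five days", "one week", "ten days",
            "two weeks"),
    durlong = c("four weeks", "six weeks", "two months", "three months"),
    degree = c("mild", "moderate", "marked", "progressive"),
    side = c("left", "right"))
}

pf_text_templates <- function() {
  intro <- "patient is a {age} year old {sex} presenting with {dur} of"
  clinical <- list(
    normal = list(
      pf_sentence(1, "patient is a {age} year old {sex} attending for a routine health examination"),
      pf_sentence(1, "the patient denies fever cough chest pain or shortness of breath"),
      pf_sentence(1, "examination shows clear breath sounds and normal vital signs"),
      pf_sentence(0.5, "exercise tolerance is excellent and appetite is preserved"),
      pf_sentence(0.5, "past medical history is unremarkable with no regular medications"),
      pf_sentence(0.5, "the patient is a lifelong non smoker with no occupational exposures")),
    bacterial = list(
      pf_sentence(1, paste(intro, "high fever and productive cough")),
      pf_sentence(1, "sputum is purulent and the patient reports {degree} pleuritic chest pain with rigors"),
      pf_sentence(1, "examination reveals coarse crackles and bronchial breathing over the {side} lower zone"),
      pf_sentence(0.5, "the patient appears acutely unwell with tachycardia and tachypnea"),
      pf_sentence(0.5, "past medical history includes hypertension and type two diabetes"),
      pf_sentence(0.4, "no recent travel or sick contacts are reported")),
    viral = list(
      pf_sentence(1, paste(intro, "fever and dry cough")),
      pf_sentence(1, "the patient reports fatigue myalgia and sore throat with gradual onset"),
      pf_sentence(1, "examination shows scattered wheeze and the chest is otherwise clear"),
      pf_sentence(0.5, "several family members have had a similar influenza like illness recently"),
      pf_sentence(0.5, "there is mild rhinorrhea and the patient remains well perfused"),
      pf_sentence(0.4, "no purulent sputum or pleuritic chest pain is reported")),
    covid19 = list(
      pf_sentence(1, paste(intro, "fever and dry cough")),
      pf_sentence(1, "the patient reports fatigue and {degree} shortness of breath on exertion"),
      pf_sentence(1, "examination shows reduced oxygen saturation on room air"),
      pf_sentence(0.5, "the patient describes loss of smell and taste since symptom onset"),
      pf_sentence(0.5, "there is a known exposure to a confirmed coronavirus case"),
      pf_sentence(0.4, "no purulent sputum is reported and chest pain is absent")),
    tuberculosis = list(
      pf_sentence(1, "patient is a {age} year old {sex} presenting with {durlong} of chronic productive cough"),
      pf_sentence(1, "the patient reports drenching night sweats and unintentional weight loss"),
      pf_sentence(1, "examination reveals apical crackles and the patient appears thin"),
      pf_sentence(0.5, "there is a history of hemoptysis with small volume blood streaked sputum"),
      pf_sentence(0.5, "the patient recently arrived from a region with endemic tuberculosis"),
      pf_sentence(0.4, "low grade evening fever has been present for several weeks")),
    vague = list(
      pf_sentence(1, paste(intro, "fever and cough")),
      pf_sentence(1, "symptoms include malaise reduced appetite and intermittent chills"),
      pf_sentence(1, "examination findings are nonspecific with mildly increased respiratory rate"),
      pf_sentence(0.5, "the patient reports fatigue and poor sleep since symptom onset"),
      pf_sentence(0.5, "no clear exposure history is identified at presentation"),
      pf_sentence(0.4, "observation and repeat clinical review are planned")))
  technique <- pf_sentence(1, "computed tomography of the chest was performed")
  report <- list(
    normal = list(
      technique,
      pf_sentence(1, "the lungs are clear without focal consolidation ground glass opacity or pleural effusion"),
      pf_sentence(1, "the cardiomediastinal silhouette and hilar contours are within normal limits"),
      pf_sentence(1, "impression no acute cardiopulmonary abnormality"),
      pf_sentence(0.5, "there is no pneumothorax and the central airways are patent"),
      pf_sentence(0.5, "mild degenerative changes are noted in the thoracic spine"),
      pf_sentence(0.4, "comparison with prior imaging shows no significant interval change")),
    bacterial = list(
      technique,
      pf_sentence(1, "there is dense lobar consolidation in the central portion of the {side} lung"),
      pf_sentence(1, "air bronchograms are present within the consolidation and a small parapneumonic effusion is suspected"),
      pf_sentence(1, "impression findings are most consistent with bacterial lobar pneumonia"),
      pf_sentence(0.5, "the consolidation partially obscures the adjacent cardiac border"),
      pf_sentence(0.5, "no cavitation or significant lymphadenopathy is identified")),
    covid19 = list(
      technique,
      pf_sentence(1, "multifocal ground glass opacities are distributed in the peripheral subpleural regions of both lungs"),
      pf_sentence(1, "the opacities show a {degree} rounded morphology with an early crazy paving pattern"),
      pf_sentence(1, "impression peripheral ground glass opacities suspicious for viral coronavirus pneumonia"),
      pf_sentence(0.5, "no pleural effusion cavitation or lymphadenopathy is present"),
      pf_sentence(0.5, "the central perihilar lung remains relatively spared")),
    viral = list(
      technique,
      pf_sentence(1, "diffuse bilateral interstitial opacities and hazy airspace change predominate in both lower lobes"),
      pf_sentence(1, "there is {degree} peribronchial thickening with scattered patchy opacities",
                     "there is {degree} peribronchial thickening with scattered patchy ground glass change"),
      pf_sentence(1, "impression findings favor a diffuse viral pattern pneumonia without focal lobar consolidation"),
      pf_sentence(0.5, "small bilateral pleural effusions may be present"),
      pf_sentence(0.5, "the upper lobes are relatively spared")),
    tuberculosis = list(
      technique,
      pf_sentence(1, "fibronodular opacities are clustered in the apical and posterior segments of the upper lobes"),
      pf_sentence(1, "a thick walled cavity is suspected in the {side} apex with adjacent satellite nodules"),
      pf_sentence(1, "impression upper lobe cavitary disease highly suggestive of pulmonary tuberculosis"),
      pf_sentence(0.5, "calcified hilar lymph nodes indicate prior granulomatous infection"),
      pf_sentence(0.5, "no pleural effusion is identified on this study")),
    vague = list(
      technique,
      pf_sentence(1, "patchy airspace opacities are present with an indeterminate distribution in both lungs"),
      pf_sentence(1, "the findings are nonspecific and may reflect infection aspiration or edema"),
      pf_sentence(1, "impression indeterminate airspace disease clinical correlation is recommended"),
      pf_sentence(0.5, "follow up imaging after treatment is advised"),
      pf_sentence(0.5, "no large pleural effusion or pneumothorax is seen")))
  list(clinical = clinical, report = report)
}

#' Default text templates
#'
#' Per-class sentence templates for the clinical-note and radiology-report
#' generators, including the deliberately nonspecific variants that make
#' single-modality classification imperfect.
#'
#' @return nested list `templates[[kind]][[label]]`.
#' @export
default_text_templates <- function() pf_text_templates()

# probability that a disease-class text uses the nonspecific template
PF_VAGUE_PROB <- 0.2

pf_fill_slots <- function(s, fillers) {
  for (nm in names(fillers)) {
    pat <- paste0("{", nm, "}")
    while (grepl(pat, s, fixed = TRUE)) {
      s <- sub(pat, sample(fillers[[nm]], 1), s, fixed = TRUE)
    }
  }
  if (grepl("{", s, fixed = TRUE)) {
    stop("render_text: template slot with no filler in: ", s)
  }
  s
}

#' Render a clinical note or radiology report
#'
#' Expands the class's sentence templates (each optional sentence included
#' with its configured probability, slots filled from a fixed filler table)
#' into a 30-70 word text whose long-run mean length is ~50 words. Disease
#' classes draw a nonspecific template with probability 0.2, so text alone
#' does not fully determine the class. Uses the current RNG state.
#'
#' @param templates template set from [default_text_templates()].
#' @param label class label.
#' @param kind `"clinical"` or `"report"`.
#' @param lexicon lexicon for tokenization (see [load_lexicon()]); if `NULL`
#'   only the text is returned.
#' @return list with `text` (single string), `tokens` (integer ids, if a
#'   lexicon was supplied) and `n_words`.
#' @export
render_text <- function(templates = default_text_templates(), label, kind,
                        lexicon = NULL) {
  kind <- match.arg(kind, c("clinical", "report"))
  label <- match.arg(label, PF_CLASSES)
  use <- label
  if (label != "normal" && stats::runif(1) < PF_VAGUE_PROB) use <- "vague"
  tpl <- templates[[kind]][[use]]
  if (is.null(tpl) || !length(tpl)) {
    stop("render_text: no templates for (", label, ", ", kind, ")")
  }
  fillers <- pf_slot_fillers()
  out <- character(0)
  for (s in tpl) {
    if (s$p < 1 && stats::runif(1) >= s$p) next
    v <- if (length(s$variants) > 1) sample(s$variants, 1) else s$variants
    out <- c(out, pf_fill_slots(v, fillers))
  }
  text <- paste(out, collapse = " ")
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  res <- list(text = text, n_words = length(words))
  if (!is.null(lexicon)) res$tokens <- tokenize_text(text, lexicon)
  res
}

# ---- manifest ----------------------------------------------------------------

#' Generate a dataset manifest
#'
#' Builds the full sample table (ids, labels, stratified 5-fold assignment,
#' stratified 80/20 train flag, and one RNG substream seed per sample) for
#' the given class specifications. Content is materialized on demand with
#' [materialize_sample()]; `(specs, seed)` fully determine every sample,
#' independent of materialization order.
#'
#' @param specs list of [class_spec()] objects (unique labels).
#' @param seed master integer seed.
#' @param image_size rendered image side in pixels.
#' @return a `pf_manifest`: data frame with columns `sample_id`, `label`,
#'   `fold` (0-4), `is_train`, `sample_seed`, plus attributes `specs`,
#'   `image_size`, `seed`.
#' @export
generate_dataset <- function(specs, seed, image_size = 224) {
  if (!length(specs)) stop("generate_dataset: specs must be non-empty")
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("generate_dataset: duplicate labels in specs: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  }
  counts <- vapply(specs, function(s) s$count, integer(1))
  if (any(counts < 1)) stop("generate_dataset: counts must be positive")
  total <- sum(counts)
  with_local_seed(seed, {
    sample_seed <- sample.int(.Machine$integer.max - 1L, total)
    fold <- integer(total)
    is_train <- logical(total)
    offset <- 0L
    for (k in seq_along(specs)) {
      n <- counts[k]
      ord <- sample.int(n)
      f <- integer(n)
      f[ord] <- rep(0:4, length.out = n)
      fold[offset + seq_len(n)] <- f
      ntr <- round(0.8 * n)
      tr <- logical(n)
      tr[sample.int(n, ntr)] <- TRUE
      is_train[offset + seq_len(n)] <- tr
      offset <- offset + n
    }
    m <- data.frame(
      sample_id = sprintf("S%05d", seq_len(total)),
      label = rep(labels, counts),
      fold = fold,
      is_train = is_train,
      sample_seed = sample_seed,
      stringsAsFactors = FALSE)
    attr(m, "specs") <- specs
    attr(m, "image_size") <- image_size
    attr(m, "seed") <- seed
    class(m) <- c("pf_manifest", "data.frame")
    m
  })
}

#' Materialize one sample from a manifest
#'
#' Renders the image, lab vector, clinical note, and radiology report of row
#' `i` from its private RNG substream. Repeated calls (in any order) give
#' byte-identical content.
#'
#' @param manifest a [generate_dataset()] manifest.
#' @param i row index.
#' @param lexicon lexicon used to tokenize the texts (default: shipped).
#' @return list: `sample_id`, `label`, `label_id` (1-5 in class order),
#'   `image`, `mask`, `labs`, `clinical` and `report` (each with `text`,
#'   `tokens`, `n_words`), `fold`, `is_train`.
#' @export
materialize_sample <- function(manifest, i, lexicon = load_lexicon()) {
  specs <- attr(manifest, "specs")
  size <- attr(manifest, "image_size")
  row <- manifest[i, ]
  spec <- specs[[match(row$label, vapply(specs, `[[`, "", "label"))]]
  templates <- spec$text_templates
  if (is.null(templates)) templates <- default_text_templates()
  sub <- pf_substreams(row$sample_seed)
  faint <- spec$label != "normal" &&
    with_local_seed(sub[1], stats::runif(1)) < 0.15
  img <- with_local_seed(sub[2],
    render_image(spec$image_motif, size = size, faint = faint))
  labs <- with_local_seed(sub[3], sample_labs(spec$lab_params))
  clin <- with_local_seed(sub[4],
    render_text(templates, spec$label, "clinical", lexicon))
  rep_ <- with_local_seed(sub[5],
    render_text(templates, spec$label, "report", lexicon))
  list(sample_id = row$sample_id, label = row$label,
       label_id = match(row$label, PF_CLASSES),
       image = img$image, mask = img$mask, geometry = img$geometry,
       faint = faint, labs = labs, clinical = clin, report = rep_,
       fold = row$fold, is_train = row$is_train)
}

# Five fixed RNG substream seeds per sample (ambiguity flag, image, labs,
# clinical text, report text), so any component can be materialized alone.
pf_substreams <- function(sample_seed) {
  with_local_seed(sample_seed, sample.int(.Machine$integer.max - 1L, 5))
}

#' Materialize the lab matrix for a manifest
#'
#' Fast path for lab-only consumers (standardizers, separability probes):
#' draws each sample's lab vector from its substream without rendering
#' images or texts.
#'
#' @param manifest a [generate_dataset()] manifest.
#' @param rows row indices (default all).
#' @return numeric matrix `length(rows) x 15` with indicator column names.
#' @export
materialize_labs <- function(manifest, rows = seq_len(nrow(manifest))) {
  specs <- attr(manifest, "specs")
  labels <- vapply(specs, `[[`, "", "label")
  out <- matrix(0, length(rows), 15, dimnames = list(NULL, PF_LAB_NAMES))
  for (j in seq_along(rows)) {
    row <- manifest[rows[j], ]
    spec <- specs[[match(row$label, labels)]]
    sub <- pf_substreams(row$sample_seed)
    out[j, ] <- with_local_seed(sub[3], sample_labs(spec$lab_params))
  }
  out
}
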
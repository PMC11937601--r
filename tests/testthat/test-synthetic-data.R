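# Synthetic data generator: composition, determinism, class-conditional
# structure of labs, texts, and image motifs.

test_that("manifest composition conserves per-class counts and stratifies folds", {
  specs <- default_class_specs(c(normal = 23, tuberculosis = 17, viral = 31,
                                 bacterial = 11, covid19 = 19))
  man <- generate_dataset(specs, seed = 7, image_size = 64)
  expect_equal(nrow(man), 23 + 17 + 31 + 11 + 19)
  expect_equal(as.vector(table(man$label)[c("normal", "tuberculosis",
                                            "viral", "bacterial",
                                            "covid19")]),
               c(23, 17, 31, 11, 19))
  for (lb in unique(man$label)) {
    f <- table(factor(man$fold[man$label == lb], levels = 0:4))
    expect_lte(max(f) - min(f), 1)           # stratified folds
    ntr <- sum(man$is_train[man$label == lb])
    expect_lte(abs(ntr - 0.8 * sum(man$label == lb)), 1)  # 80/20 +- 1
  }
})

test_that("a single-sample spec yields one training sample in fold 0", {
  man <- generate_dataset(list(class_spec("viral", 1)), seed = 3)
  expect_equal(nrow(man), 1)
  expect_equal(man$fold, 0)
  expect_true(man$is_train)
})

test_that("(specs, seed) determine the manifest and samples byte-for-byte", {
  specs <- default_class_specs(c(normal = 4, tuberculosis = 4, viral = 4,
                                 bacterial = 4, covid19 = 4))
  m1 <- generate_dataset(specs, seed = 99, image_size = 64)
  m2 <- generate_dataset(specs, seed = 99, image_size = 64)
  expect_identical(m1, m2)
  s1 <- materialize_sample(m1, 7)
  s2 <- materialize_sample(m2, 7)
  expect_identical(s1, s2)
  # materialization order does not matter
  s3 <- materialize_sample(m1, 3)
  s1b <- materialize_sample(m1, 7)
  expect_identical(s1, s1b)
  # lab-only fast path agrees with full materialization
  expect_equal(unname(materialize_labs(m1, 7)[1, ]), unname(s1$labs))
})

test_that("configuration errors are rejected", {
  expect_error(generate_dataset(list(class_spec("viral", 2),
                                     class_spec("viral", 3)), seed = 1),
               "duplicate")
  expect_error(class_spec("viral", 0), "positive")
  expect_error(render_image("emphysema"), "unknown motif")
  bad <- default_lab_params("viral")
  bad$WBC <- c(7, -1)
  expect_error(class_spec("viral", 5, lab_params = bad), "strictly positive")
  expect_error(sample_labs(replicate(15, c(1, -0.1), simplify = FALSE)),
               "configuration error")
  tpl <- default_text_templates()
  tpl$clinical$viral[[1]]$variants <- "symptoms of {nonexistent} noted"
  set.seed(1)
  expect_error(
    replicate(50, render_text(tpl, "viral", "clinical")),
    "slot with no filler")
})

test_that("lab draws follow the configured class-conditional structure", {
  set.seed(21)
  deg <- lapply(default_lab_params("viral"), function(p) c(p[1], 0))
  v <- sample_labs(deg)
  expect_equal(unname(v),
               unname(vapply(default_lab_params("viral"), `[`, 0, 1)))
  draw_many <- function(lb, n = 1000) {
    p <- default_lab_params(lb)
    t(replicate(n, sample_labs(p)))
  }
  bac <- draw_many("bacterial"); vir <- draw_many("viral")
  expect_gt(mean(bac[, "WBC"]), mean(vir[, "WBC"]))
  expect_gt(mean(vir[, "LYMP%"]), mean(bac[, "LYMP%"]))
  expect_gt(mean(vir[, "LYMP%"]), default_lab_params("normal")$`LYMP%`[1])
  expect_true(all(bac >= 0) && all(vir >= 0))   # physiological floors
})

test_that("rendered texts hit the 30-70 word envelope with ~50-word means", {
  set.seed(5)
  for (kind in c("clinical", "report")) {
    for (lb in c("normal", "tuberculosis", "viral", "bacterial",
                 "covid19")) {
      n <- replicate(200, render_text(label = lb, kind = kind)$n_words)
      expect_gte(min(n), 30)
      expect_lte(max(n), 70)
      expect_gte(mean(n), 45)
      expect_lte(mean(n), 55)
    }
  }
})

test_that("viral clinical notes carry the configured symptom lexemes", {
  set.seed(8)
  for (i in 1:50) {
    txt <- render_text(label = "viral", kind = "clinical")$text
    expect_true(grepl("fever|dry cough|fatigue", txt))
  }
})

test_that("text rendering is deterministic and closed over the lexicon", {
  lex <- load_lexicon()
  set.seed(13); a <- render_text(label = "covid19", kind = "report", lexicon = lex)
  set.seed(13); b <- render_text(label = "covid19", kind = "report", lexicon = lex)
  expect_identical(a, b)
  expect_true(all(a$tokens >= 1 & a$tokens <= length(lex)))
})

test_that("image motifs localize where their pathology localizes", {
  set.seed(31)
  size <- 224
  rad <- pf_lung_radius(size)
  for (i in 1:5) {
    cov <- render_image("covid19", size)
    frac <- sum(cov$mask & rad >= 0.75 & rad <= 1.05) / sum(cov$mask)
    expect_gte(frac, 0.8)   # peripheral band: outer 25% of lung radius
    bac <- render_image("bacterial", size)
    w <- which(bac$mask, arr.ind = TRUE)
    expect_gt(mean(w[, 2]), size / 3)      # centroid in the central third
    expect_lt(mean(w[, 2]), 2 * size / 3)
  }
  nrm <- render_image("normal", size)
  expect_equal(sum(nrm$mask), 0)           # no lesion for normal
  expect_true(all(nrm$image >= 0 & nrm$image <= 1))
  tb <- render_image("tuberculosis", size)
  expect_gt(sum(tb$mask), 0)
  expect_lt(mean(which(tb$mask, arr.ind = TRUE)[, 1]), 0.45 * size)  # upper
  vir <- render_image("viral", size)
  expect_gt(mean(which(vir$mask, arr.ind = TRUE)[, 1]), 0.55 * size) # lower
})

test_that("a multinomial logistic probe separates classes from labs alone", {
  man <- balanced_manifest(200, seed = 5)
  labs <- materialize_labs(man)
  df <- data.frame(labs, y = factor(man$label), check.names = TRUE)
  set.seed(2)
  tr <- sample(nrow(df), 700)
  fit <- nnet::multinom(y ~ ., df[tr, ], trace = FALSE)
  acc <- mean(predict(fit, df[-tr, ]) == df$y[-tr])
  expect_gte(acc, 0.70)
})

test_that("quadrant-intensity probe separates the image motifs above chance", {
  set.seed(9)
  qm <- function(img) {
    h <- nrow(img) %/% 2
    c(mean(img[1:h, 1:h]), mean(img[1:h, -(1:h)]),
      mean(img[-(1:h), 1:h]), mean(img[-(1:h), -(1:h)]))
  }
  labs <- c("normal", "tuberculosis", "viral", "bacterial", "covid19")
  X <- NULL; y <- c()
  for (lb in labs) for (i in 1:30) {
    X <- rbind(X, qm(render_image(lb, 64)$image)); y <- c(y, lb)
  }
  df <- data.frame(X, y = factor(y))
  tr <- sample(nrow(df), 100)
  fit <- nnet::multinom(y ~ ., df[tr, ], trace = FALSE)
  acc <- mean(predict(fit, df[-tr, ]) == df$y[-tr])
  expect_gt(acc, 0.2 + 0.15)   # clearly above the 20% chance level
})
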
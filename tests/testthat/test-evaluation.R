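# Evaluation metrics: confusion tallies, the one-vs-rest formulas, and the
# macro/micro identities.

test_that("confusion matrices tally exactly", {
  cm <- confusion_counts(rep(1:5, each = 2), rep(1:5, each = 2))
  expect_equal(unname(diag(cm)), rep(2L, 5))
  expect_equal(sum(cm), 10)
  cm2 <- confusion_counts(c(1, 2, 3), c(1, 1, 1))
  expect_equal(sum(cm2[, 1]), 3)
  expect_equal(sum(cm2[, -1]), 0)
  # hand tally (0-based labels (0,0,1,1,2) / preds (0,1,1,1,0))
  cm3 <- confusion_counts(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 1))
  expect_equal(cm3[1, 1], 1L)
  expect_equal(cm3[1, 2], 1L)
  expect_equal(cm3[2, 2], 2L)
  expect_equal(cm3[3, 1], 1L)
  expect_equal(sum(cm3), 5)
  expect_error(confusion_counts(1:3, 1:2), "length")
  expect_error(confusion_counts(c(1, 6), c(1, 1)), "outside")
})

test_that("one-vs-rest counts give the stated precision/recall/F1", {
  m <- metrics_from_counts(tp = 8, fp = 2, fn = 1, tn = 9)
  expect_equal(unname(m["precision"]), 0.8)
  expect_equal(unname(m["recall"]), 8 / 9)
  expect_equal(unname(m["recall"]), 0.8889, tolerance = 1e-4)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["f1"]), 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(unname(m["f1"]), 0.8421, tolerance = 1e-4)
  expect_warning(metrics_from_counts(0, 0, 3, 7), "undefined")
})

test_that("perfect predictions give unit metrics", {
  cm <- confusion_counts(1:5, 1:5)
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 1)
  expect_true(all(met$per_class$f1 == 1))
})

test_that("micro-F1 equals accuracy on random confusion matrices", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    cm <- confusion_counts(sample(5, n, TRUE), sample(5, n, TRUE))
    met <- suppressWarnings(classification_metrics(cm))
    expect_equal(met$micro$f1, met$accuracy, tolerance = 1e-12)
    expect_equal(met$micro$precision, met$micro$recall)
    # harmonic-mean bound per class
    pc <- met$per_class
    both <- pc$precision + pc$recall > 0
    expect_true(all(pc$f1[both] >= pmin(pc$precision, pc$recall)[both] - 1e-12))
    expect_true(all(pc$f1[both] <= pmax(pc$precision, pc$recall)[both] + 1e-12))
  }
})

test_that("metrics are invariant under a joint relabeling", {
  set.seed(41)
  t_ <- sample(5, 100, TRUE); p_ <- sample(5, 100, TRUE)
  perm <- sample(5)
  m1 <- suppressWarnings(classification_metrics(confusion_counts(t_, p_)))
  m2 <- suppressWarnings(classification_metrics(
    confusion_counts(perm[t_], perm[p_])))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$macro, m2$macro)
})

test_that("uniform random predictions score ~20% on balanced 5-class data", {
  set.seed(42)
  t_ <- rep(1:5, each = 2000)
  p_ <- sample(5, 10000, TRUE)
  met <- suppressWarnings(
    classification_metrics(confusion_counts(t_, p_)))
  expect_gt(met$accuracy, 0.18)
  expect_lt(met$accuracy, 0.22)
})

test_that("rank-based OVR AUC agrees with the pROC oracle", {
  set.seed(43)
  n <- 300
  t_ <- sample(3, n, TRUE)
  pr <- matrix(runif(n * 3), n, 3) + 0.5 * outer(seq_len(n), 1:3,
    function(i, k) (t_[i] == k))
  pr <- pr / rowSums(pr)
  mine <- ovr_auc(t_, pr)
  ref <- mean(vapply(1:3, function(k)
    as.numeric(pROC::auc(pROC::roc(as.integer(t_ == k), pr[, k],
                                   quiet = TRUE, direction = "<"))),
    numeric(1)))
  expect_equal(mine, ref, tolerance = 1e-10)
})
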
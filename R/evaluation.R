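# Evaluation: confusion matrices and accuracy / precision / recall / F1 /
# specificity with macro and micro averaging for 5-class predictions, plus a
# rank-based one-vs-rest ROC-AUC.

#' Confusion matrix for 5-class predictions
#'
#' @param true_labels,predicted_labels integer vectors (1-based class ids) or
#'   factors/characters over the class labels.
#' @param n_classes number of classes.
#' @return integer matrix `counts[i, j] = #\{true = i, predicted = j\}`, rows
#'   true, columns predicted.
#' @export
confusion_counts <- function(true_labels, predicted_labels, n_classes = 5) {
  to_id <- function(x) {
    if (is.character(x) || is.factor(x)) match(as.character(x), PF_CLASSES)
    else as.integer(x)
  }
  t_ <- to_id(true_labels); p_ <- to_id(predicted_labels)
  if (length(t_) != length(p_)) {
    stop("confusion_counts: label vectors differ in length")
  }
  if (anyNA(t_) || anyNA(p_) || any(t_ < 1 | t_ > n_classes) ||
      any(p_ < 1 | p_ > n_classes)) {
    stop("confusion_counts: labels outside 1..", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = PF_CLASSES[seq_len(n_classes)],
                               predicted = PF_CLASSES[seq_len(n_classes)]))
  for (k in seq_along(t_)) cm[t_[k], p_[k]] <- cm[t_[k], p_[k]] + 1L
  cm
}

#' Binary classification metrics from one-vs-rest counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, `specificity = TN/(TN+FP)`.
#' A zero denominator yields 0 with a warning (reported, not silent).
#'
#' @param tp,fp,fn,tn one-vs-rest counts.
#' @return named numeric vector.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  div <- function(num, den, what) {
    if (den == 0) {
      warning("metrics: ", what, " undefined (0/0); reporting 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    specificity = div(tn, tn + fp, "specificity"))
}

#' Classification metrics report from a confusion matrix
#'
#' Per-class one-vs-rest precision/recall/F1/specificity, their unweighted
#' macro averages, micro averages on the pooled one-vs-rest counts, and the
#' overall accuracy. For single-label multiclass data micro precision, micro
#' recall, micro F1, and accuracy coincide.
#'
#' @param cm confusion matrix from [confusion_counts()].
#' @return list with `accuracy`, `per_class` (data frame), `macro`, `micro`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("classification_metrics: empty confusion matrix")
  k <- nrow(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  per <- t(vapply(seq_len(k), function(i)
    metrics_from_counts(tp[i], fp[i], fn[i], tn[i]), numeric(5)))
  per_df <- data.frame(class = rownames(cm), support = rowSums(cm), per,
                       row.names = NULL)
  macro <- colMeans(per[, c("precision", "recall", "f1", "specificity"),
                        drop = FALSE])
  mi <- metrics_from_counts(sum(tp), sum(fp), sum(fn), sum(tn))
  list(accuracy = sum(tp) / total,
       per_class = per_df,
       macro = as.list(macro),
       micro = list(precision = mi[["precision"]], recall = mi[["recall"]],
                    f1 = mi[["f1"]]))
}

#' One-vs-rest macro ROC-AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class's predicted probability
#' against the rest, macro-averaged over classes present in the truth.
#'
#' @param true_labels integer class ids (1-based).
#' @param probabilities matrix `n x k` of predicted class probabilities.
#' @return macro-averaged AUC in `[0, 1]`.
#' @export
ovr_auc <- function(true_labels, probabilities) {
  k <- ncol(probabilities)
  aucs <- c()
  for (i in seq_len(k)) {
    pos <- true_labels == i
    if (!any(pos) || all(pos)) next
    r <- rank(probabilities[, i])
    n1 <- sum(pos); n0 <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  mean(aucs)
}
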
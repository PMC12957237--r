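#' Confusion matrix from aligned label vectors
#'
#' @param truth,pred Aligned vectors of true and predicted labels.
#' @param classes Class set (default: union of observed labels).
#' @return K x K integer matrix, rows = truth, columns = prediction, of class
#'   `scbam_confusion`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred))
    stop_invalid("truth (%d) and pred (%d) differ in length", length(truth), length(pred))
  classes <- classes %||% sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, pred = classes))
  structure(m, class = c("scbam_confusion", class(m)))
}

#' Classification accuracy from a confusion matrix
#'
#' `trace / total`; for the 2 x 2 case this is exactly
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm Square count matrix (rows = truth).
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)` with observed
#' agreement `P_o = trace / total` and expected agreement
#' `P_e = sum_k row_k * col_k / total^2`.
#'
#' @param cm Square count matrix (rows = truth).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stop_undefined_statistic("expected agreement is 1; kappa undefined")
  (po - pe) / (1 - pe)
}

#' Trial-level label permutation test
#'
#' Shuffles the true trial labels against the fixed predictions `n_perm` times
#' and reports the proportion of permutations whose accuracy meets or exceeds
#' the observed accuracy. `p` carries add-one smoothing
#' `(1 + hits) / (n_perm + 1)` (never exactly zero); the raw proportion is
#' returned alongside.
#'
#' @param true_labels,predicted_labels Aligned trial label vectors.
#' @param n_perm Number of shuffles.
#' @param seed RNG seed for the shuffles.
#' @return List with `p`, `p_raw`, `observed` accuracy, `null_accuracies`.
#' @export
permutation_test <- function(true_labels, predicted_labels, n_perm = 5000,
                             seed = 1L) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("label vectors differ in length")
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  obs <- mean(true_labels == predicted_labels)
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(sample(true_labels) == predicted_labels),
           numeric(1))
  })
  hits <- sum(null_acc >= obs)
  list(p = (1 + hits) / (n_perm + 1), p_raw = hits / n_perm,
       observed = obs, null_accuracies = null_acc)
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Paired t-test between two sets of pairwise accuracies
#'
#' Two-sided paired t-test (n - 1 df) with significance stars at the 0.05 /
#' 0.01 / 0.001 levels.
#'
#' @param acc_a,acc_b Equal-length accuracy vectors (paired by finger pair).
#' @return List with `t`, `df`, `p`, `stars`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2)
    stop_invalid("need two aligned vectors of length >= 2")
  d <- acc_a - acc_b
  if (stats::sd(d) == 0)
    stop_undefined_statistic("zero-variance differences; paired t undefined")
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = significance_stars(tt$p.value))
}

#' Percentile bootstrap confidence interval for a mean accuracy
#'
#' Resamples the per-subject accuracies with replacement and returns the
#' percentile interval of the resampled means.
#'
#' @param subject_accuracies Numeric vector (length >= 2).
#' @param n_boot Number of resamples.
#' @param level Coverage level.
#' @param seed RNG seed.
#' @return List with `lower`, `upper`, `point` (the observed mean).
#' @export
bootstrap_ci <- function(subject_accuracies, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  n <- length(subject_accuracies)
  if (n < 2) stop_invalid("need at least 2 values to bootstrap")
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(subject_accuracies, n, replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1], upper = q[2], point = mean(subject_accuracies))
}

#' ROC points and AUC for a binary classifier
#'
#' Threshold sweep over the positive-class scores (delegated to pROC with a
#' fixed direction so results are deterministic).
#'
#' @param scores Positive-class probabilities or scores.
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive The positive-class label (default: the larger label).
#' @return List with `points` (data.frame `fpr`, `tpr`, monotone) and `auc`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  u <- sort(unique(labels))
  if (length(u) < 2) stop_invalid("both classes must be present")
  positive <- positive %||% u[length(u)]
  resp <- factor(ifelse(labels == positive, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(response = resp, predictor = scores,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  list(points = data.frame(fpr = (1 - r$specificities)[ord],
                           tpr = r$sensitivities[ord]),
       auc = as.numeric(r$auc))
}

#' Export a confusion matrix or ROC points as CSV
#'
#' @param cm A confusion matrix (rows = truth).
#' @param file Output path.
#' @export
export_confusion_csv <- function(cm, file) {
  utils::write.csv(as.data.frame(unclass(cm)), file, row.names = TRUE)
  invisible(file)
}

#' @rdname export_confusion_csv
#' @param roc A [roc_points()] result.
#' @export
export_roc_csv <- function(roc, file) {
  utils::write.csv(roc$points, file, row.names = FALSE)
  invisible(file)
}
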
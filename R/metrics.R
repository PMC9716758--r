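# Multiclass evaluation metrics: balanced accuracy (one-vs-rest), Cohen's
# kappa, macro AUC, and the adjacency-tolerant variant for ordinal classes.

#' Confusion-matrix metrics for ordinal multiclass predictions
#'
#' Per-class balanced accuracy is the one-vs-rest `(recall + specificity)/2`;
#' the mean balanced accuracy averages it over classes present in the truth.
#' Cohen's kappa comes from the full K x K confusion matrix. When class
#' probabilities are supplied, a macro-averaged one-vs-rest AUC is added.
#'
#' @param truth,pred Integer labels in `1..K`.
#' @param K Number of classes.
#' @param prob Optional `length(truth) x K` matrix of predicted class
#'   probabilities for the AUC.
#' @return List with `confusion` (K x K, rows = truth, cols = predicted),
#'   `accuracy`, `per_class_balanced_accuracy`, `mean_balanced_accuracy`,
#'   `kappa`, and `auc` (`NA` without probabilities).
#' @export
confusion_metrics <- function(truth, pred, K, prob = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  if (any(truth < 1L | truth > K) || any(pred < 1L | pred > K))
    stop_bad("labels must lie in 1..K")
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  metrics_from_confusion(cm, prob = prob, truth = truth)
}

# shared core so tests can also drive it straight from a matrix
metrics_from_confusion <- function(cm, prob = NULL, truth = NULL) {
  K <- nrow(cm)
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  bal <- (recall + specificity) / 2
  po <- sum(tp) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (abs(po - 1) < .Machine$double.eps^0.5) 1 else 0
  } else (po - pe) / (1 - pe)
  auc <- NA_real_
  if (!is.null(prob)) {
    if (is.null(truth)) stop_bad("AUC needs per-observation truth labels")
    auc <- macro_auc(truth, prob)
  }
  list(confusion = cm,
       accuracy = po,
       per_class_balanced_accuracy = bal,
       mean_balanced_accuracy = mean(bal, na.rm = TRUE),
       kappa = kappa,
       auc = auc)
}

# macro one-vs-rest AUC via the rank (Mann-Whitney) formulation
macro_auc <- function(truth, prob) {
  prob <- as.matrix(prob)
  K <- ncol(prob)
  aucs <- vapply(seq_len(K), function(k) {
    pos <- truth == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(prob[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Adjacency-tolerant confusion metrics for ordinal labels
#'
#' Because the ordinal categories discretize a continuous quantity, most
#' misclassifications land in a neighboring bin. A prediction within
#' `tolerance` categories of the truth is recoded as correct (assigned the
#' true label) before the confusion metrics are computed; `tolerance = 0`
#' reduces exactly to [confusion_metrics()].
#'
#' @inheritParams confusion_metrics
#' @param tolerance Non-negative integer, default 1.
#' @return As [confusion_metrics()] (no AUC: probabilities are not recoded).
#' @export
adjacency_tolerant_metrics <- function(truth, pred, K, tolerance = 1) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop_bad("`tolerance` must be a non-negative integer")
  truth <- as.integer(truth); pred <- as.integer(pred)
  hit <- abs(truth - pred) <= tolerance
  pred2 <- ifelse(hit, truth, pred)
  confusion_metrics(truth, pred2, K)
}
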
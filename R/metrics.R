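# Multi-class diagnostic metric panel: support-weighted one-vs-rest
# AUROC/AUPRC/precision/F1, accuracy (weighted recall), balanced accuracy
# (macro recall), Cohen's kappa with Landis-Koch bands, and the binary
# one-vs-rest panels with FPR/FNR.

.binary_auroc <- function(pos, score) {
  r <- rank(score)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-interpolated area under the PR curve)
.binary_auprc <- function(pos, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / sum(pos)
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Landis-Koch qualitative band for a kappa value
#'
#' @param kappa Cohen's kappa in \[-1, 1\].
#' @return One of `"no agreement"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost perfect"`.
#' @export
kappa_band <- function(kappa) {
  if (kappa < 0) "no agreement"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa from labels
#'
#' @param y_true,y_pred Label vectors over the same class set.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(y_true, y_pred) {
  lv <- union(unique(as.character(y_true)), unique(as.character(y_pred)))
  cm <- table(factor(as.character(y_true), lv), factor(as.character(y_pred), lv))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Seven-metric multi-class performance panel
#'
#' Computes the full evaluation panel from true labels and a probability
#' matrix: support-weighted one-vs-rest AUROC and AUPRC (average
#' precision), accuracy, balanced accuracy (macro recall),
#' support-weighted precision and F1 of the argmax predictions, Cohen's
#' kappa from the confusion matrix with its Landis-Koch band, and the
#' per-class binary panels.
#'
#' @param y_true Labels (at least two classes present).
#' @param probs Probability matrix with class columns, or a label vector
#'   (then the probability-based metrics AUROC/AUPRC are `NA`).
#' @return List of class `metrics_report`.
#' @export
compute_multiclass_metrics <- function(y_true, probs) {
  y <- as.character(y_true)
  if (length(unique(y)) < 2L)
    stop("AUROC undefined: y_true contains a single class")
  if (is.matrix(probs)) {
    classes <- colnames(probs)
    pred <- classes[max.col(probs, ties.method = "first")]
  } else {
    pred <- as.character(probs)
    classes <- sort(union(unique(y), unique(pred)))
    probs <- NULL
  }
  present <- classes[classes %in% unique(y)]
  support <- vapply(present, function(cl) sum(y == cl), numeric(1))
  wmean <- function(v) sum(v * support) / sum(support)

  per_class <- vapply(present, function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }, numeric(3))

  auroc <- auprc <- NA_real_
  if (!is.null(probs)) {
    auroc <- wmean(vapply(present, function(cl)
      .binary_auroc(y == cl, probs[, cl]), numeric(1)))
    auprc <- wmean(vapply(present, function(cl)
      .binary_auprc(y == cl, probs[, cl]), numeric(1)))
  }
  kap <- cohens_kappa(y, pred)
  out <- list(auroc = auroc, auprc = auprc,
              accuracy = mean(pred == y),
              balanced_accuracy = mean(per_class["recall", ]),
              precision = wmean(per_class["precision", ]),
              f1 = wmean(per_class["f1", ]),
              kappa = kap, kappa_band = kappa_band(kap),
              per_class = lapply(stats::setNames(present, present), function(cl)
                compute_binary_class_metrics(y, pred, cl)))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x[c("auroc", "auprc", "accuracy", "balanced_accuracy",
                  "precision", "f1", "kappa")])
  print(round(v, 4))
  cat("kappa band:", x$kappa_band, "\n")
  invisible(x)
}

#' One-vs-rest binary metric panel for one class
#'
#' Collapses the task to target class vs rest and reports accuracy,
#' balanced accuracy ((sensitivity + specificity)/2), PPV, F1, binary
#' kappa, false positive rate (1 - specificity) and false negative rate
#' (1 - sensitivity).
#'
#' @param y_true,y_pred Label vectors.
#' @param target_class The class collapsed to "positive".
#' @return Named numeric vector.
#' @export
compute_binary_class_metrics <- function(y_true, y_pred, target_class) {
  pos <- as.character(y_true) == as.character(target_class)
  ppos <- as.character(y_pred) == as.character(target_class)
  tp <- sum(pos & ppos); tn <- sum(!pos & !ppos)
  fp <- sum(!pos & ppos); fn <- sum(pos & !ppos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  c(accuracy = (tp + tn) / length(pos),
    balanced_accuracy = (sens + spec) / 2,
    ppv = ppv, f1 = f1,
    kappa = cohens_kappa(pos, ppos),
    fpr = 1 - spec, fnr = 1 - sens)
}
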
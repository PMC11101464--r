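#' Run repeated multi-fold cross-validation of a model factory
#'
#' Every split trains a fresh model on its training rows only and scores
#' the seven-metric panel on its validation rows. The factory contract
#' is `factory(x_train, y_train)` returning a prediction function
#' `function(x_new)` that yields either a probability matrix or a label
#' vector. Splits whose factory call fails are recorded and excluded
#' from the summary.
#'
#' @param model_factory Function of `(x, y)` returning a predictor.
#' @param x Numeric design matrix or `feature_matrix`.
#' @param y Labels.
#' @param plan A `cv_plan`, typically from [build_rmfcv_plan()].
#' @return List with `per_split` (data.frame of metrics per non-failed
#'   split), `summary` (mean and SD per metric), `failed` (failure
#'   count) and `predictions` (long data.frame of per-split validation
#'   predictions, for subgroup analyses).
#' @export
run_rmfcv <- function(model_factory, x, y, plan) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  y <- as.character(y)
  rows <- list(); preds <- list(); failed <- 0L
  for (s in seq_along(plan$splits)) {
    sp <- plan$splits[[s]]
    res <- tryCatch({
      predictor <- model_factory(x[sp$train, , drop = FALSE], y[sp$train])
      out <- predictor(x[sp$validation, , drop = FALSE])
      mr <- compute_multiclass_metrics(y[sp$validation], out)
      pred_lab <- if (is.matrix(out))
        colnames(out)[max.col(out, ties.method = "first")]
      else as.character(out)
      list(metrics = mr, pred = pred_lab)
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      split = s,
      auroc = res$metrics$auroc, auprc = res$metrics$auprc,
      accuracy = res$metrics$accuracy,
      balanced_accuracy = res$metrics$balanced_accuracy,
      precision = res$metrics$precision, f1 = res$metrics$f1,
      kappa = res$metrics$kappa)
    preds[[length(preds) + 1L]] <- data.frame(
      split = s, sample = sp$validation,
      y_true = y[sp$validation], y_pred = res$pred,
      stringsAsFactors = FALSE)
  }
  per_split <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_split), "split")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(per_split[[mc]]), numeric(1)),
    sd = vapply(metric_cols, function(mc) stats::sd(per_split[[mc]]), numeric(1)),
    row.names = NULL)
  list(per_split = per_split, summary = summary, failed = failed,
       predictions = do.call(rbind, preds))
}

#' Per-stratum per-class performance panels
#'
#' Evaluates the one-vs-rest binary panels within demographic strata
#' (sex, age dichotomized at 65 years, race, and sex-by-age cells),
#' aggregated as mean and SD across splits. Samples with absent race are
#' excluded from the race strata only.
#'
#' @param predictions Long data.frame with columns `split`, `sample`,
#'   `y_true`, `y_pred` (as produced by [run_rmfcv()]; a single
#'   evaluation can use `split = 1`).
#' @param cohort A `cohort_table`; rows indexed by the `sample` column.
#' @param strata Subset of `c("sex", "age65", "race", "sex_age")`.
#' @return Data.frame: stratum, class, metric, mean, sd, mean stratum
#'   size. Empty strata are reported with size 0 and `NA` metrics.
#' @export
stratified_performance <- function(predictions, cohort,
                                   strata = c("sex", "age65", "race",
                                              "sex_age")) {
  strata <- match.arg(strata, several.ok = TRUE)
  meta <- cohort[predictions$sample, , drop = FALSE]
  defs <- list()
  if ("sex" %in% strata)
    defs <- c(defs, split(seq_len(nrow(predictions)), paste0("sex:", meta$sex)))
  if ("age65" %in% strata)
    defs <- c(defs, split(seq_len(nrow(predictions)),
                          paste0("age:", ifelse(meta$age >= 65, ">=65", "<65"))))
  if ("race" %in% strata) {
    ok <- !is.na(meta$race)
    defs <- c(defs, split(which(ok), paste0("race:", meta$race[ok])))
  }
  if ("sex_age" %in% strata)
    defs <- c(defs, split(seq_len(nrow(predictions)),
                          paste0("sex_age:", meta$sex, "/",
                                 ifelse(meta$age >= 65, ">=65", "<65"))))
  out <- list()
  metrics <- c("accuracy", "balanced_accuracy", "ppv", "f1", "kappa",
               "fpr", "fnr")
  for (sn in names(defs)) {
    idx <- defs[[sn]]
    sizes <- if (length(idx)) table(predictions$split[idx]) else integer()
    for (cl in core_classes()) {
      if (!length(idx)) {
        out[[length(out) + 1L]] <- data.frame(
          stratum = sn, class = cl, metric = metrics, mean = NA_real_,
          sd = NA_real_, mean_size = 0, stringsAsFactors = FALSE)
        next
      }
      per_split <- vapply(split(idx, predictions$split[idx]), function(ii)
        compute_binary_class_metrics(predictions$y_true[ii],
                                     predictions$y_pred[ii], cl),
        numeric(length(metrics)))
      out[[length(out) + 1L]] <- data.frame(
        stratum = sn, class = cl, metric = metrics,
        mean = apply(per_split, 1, mean, na.rm = TRUE),
        sd = apply(per_split, 1, stats::sd, na.rm = TRUE),
        mean_size = mean(sizes), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# per-sample feature presence: non-zero for binary/categorical features,
# extracted (non-missing) for continuous features
.feature_presence <- function(m) {
  pres <- !m$missing_mask
  nonc <- m$descriptors$kind != "continuous"
  pres[, nonc] <- pres[, nonc, drop = FALSE] &
    (!is.na(m$values[, nonc, drop = FALSE]) & m$values[, nonc, drop = FALSE] != 0)
  pres
}

#' Most frequent features among misclassified samples
#'
#' For each true class, ranks features by the fraction of misclassified
#' samples in which the feature is present, ties broken
#' lexicographically, and reports the per-class error rate (1 -
#' per-class accuracy).
#'
#' @param y_true,y_pred Label vectors.
#' @param m The `feature_matrix` the predictions were made from.
#' @param top_k Ranking depth (default 10).
#' @return Named list per true class: `ranking` (feature, frequency) and
#'   `error_rate`; classes without misclassifications get an empty
#'   ranking.
#' @export
misclassification_features <- function(y_true, y_pred, m, top_k = 10L) {
  y <- as.character(y_true); p <- as.character(y_pred)
  pres <- .feature_presence(m)
  out <- list()
  for (cl in core_classes()) {
    in_class <- y == cl
    mis <- in_class & p != cl
    err <- if (any(in_class)) mean(p[in_class] != cl) else NA_real_
    if (!any(mis)) {
      out[[cl]] <- list(ranking = data.frame(feature = character(),
                                             frequency = numeric()),
                        error_rate = err)
      next
    }
    freq <- colMeans(pres[mis, , drop = FALSE])
    ord <- order(-freq, names(freq))
    top <- ord[seq_len(min(top_k, length(ord)))]
    out[[cl]] <- list(ranking = data.frame(feature = names(freq)[top],
                                           frequency = unname(freq[top]),
                                           stringsAsFactors = FALSE),
                      error_rate = err)
  }
  out
}

#' Highly prevalent features per assigned class, with class-specificity
#'
#' Selects features present in strictly more than `prevalence_cut` of
#' the samples of at least one assigned class (persistently cryptogenic
#' samples excluded) and tests each selected feature's class-specificity
#' with a chi-squared test on the class-by-presence contingency table.
#' Zero-variance features report p = 1.
#'
#' @param assigned_labels Heuristic labels for the samples of `m`.
#' @param m A `feature_matrix`.
#' @param prevalence_cut Prevalence threshold (default 0.5, strict).
#' @return Data.frame: feature, per-class prevalences, `max_prevalence`,
#'   `p_value`.
#' @export
signature_features <- function(assigned_labels, m, prevalence_cut = 0.5) {
  lab <- as.character(assigned_labels)
  keep <- lab != cryptogenic_label()
  lab <- lab[keep]
  if (length(unique(lab)) < 2L)
    stop("need at least 2 assigned classes with samples")
  pres <- .feature_presence(m)[keep, , drop = FALSE]
  classes <- sort(unique(lab))
  prev <- vapply(classes, function(cl)
    colMeans(pres[lab == cl, , drop = FALSE]), numeric(ncol(pres)))
  if (ncol(pres) == 1L) prev <- matrix(prev, nrow = 1L,
                                       dimnames = list(colnames(pres), classes))
  sel <- which(apply(prev, 1, max) > prevalence_cut)
  if (!length(sel))
    return(data.frame(feature = character()))
  pvals <- vapply(sel, function(j) {
    pj <- pres[, j]
    if (length(unique(pj)) < 2L) return(1)
    suppressWarnings(stats::chisq.test(table(lab, pj))$p.value)
  }, numeric(1))
  out <- data.frame(feature = colnames(pres)[sel],
                    prev[sel, , drop = FALSE],
                    max_prevalence = apply(prev[sel, , drop = FALSE], 1, max),
                    p_value = pvals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_value), ]
}

#' Classifier-agnostic univariate feature-importance tests
#'
#' One-vs-rest Kolmogorov-Smirnov and Student's t tests for each feature
#' and each class, two-sided. Cells whose one-vs-rest group has fewer
#' than 2 samples, or degenerate (constant) comparisons for the t test,
#' report `NA` statistics.
#'
#' @param m A complete `feature_matrix` or numeric matrix.
#' @param labels Class labels.
#' @return Long data.frame: feature, class, `ks_D`, `ks_p`, `t_stat`,
#'   `t_p`; sortable by `abs(t_stat)` or `ks_D`.
#' @export
feature_importance_tests <- function(m, labels) {
  x <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
  if (anyNA(x)) stop("feature importance tests require complete features")
  y <- as.character(labels)
  classes <- sort(unique(y))
  out <- list()
  for (cl in classes) {
    ing <- y == cl
    for (j in seq_len(ncol(x))) {
      a <- x[ing, j]; b <- x[!ing, j]
      if (length(a) < 2L || length(b) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          feature = colnames(x)[j], class = cl, ks_D = NA_real_,
          ks_p = NA_real_, t_stat = NA_real_, t_p = NA_real_)
        next
      }
      ks <- suppressWarnings(stats::ks.test(a, b))
      tt <- tryCatch(stats::t.test(a, b),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        feature = colnames(x)[j], class = cl,
        ks_D = unname(ks$statistic), ks_p = ks$p.value,
        t_stat = unname(tt$statistic), t_p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
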
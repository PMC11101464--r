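#' Fit the nine-classifier consensus stroke-etiology model
#'
#' Fits the four tuned base learners (elastic-net multinomial logistic
#' regression, one-vs-rest kernel SVC with balanced class weights, random
#' forest, gradient-boosted trees) on a complete feature matrix, derives
#' the margin-normalized SVC2 calibration from the SVC fit, and bundles
#' them into the consensus meta-classifier: at prediction time the five
#' base probability sources are augmented with the four
#' summary-statistic ensembles (max, min, mean, median) and the nine
#' classifiers vote; the consensus emits labels and vote supports only,
#' never probabilities.
#'
#' @param x A complete `feature_matrix` (discretized, imputed, assembled)
#'   or numeric design matrix.
#' @param y Adjudicated etiology labels in the core set 1-4.
#' @param params Per-algorithm hyperparameter lists (default the
#'   published tuned values, [tuned_parameters()]).
#' @param thresholds Optional `support_thresholds` enabling the certainty
#'   heuristic at prediction time; usually set later via
#'   [calibrate_thresholds()].
#' @param seed Integer seed; fitting is deterministic given data, params
#'   and seed.
#' @return An object of class `stroke_consensus`.
#' @seealso [predict.stroke_consensus()], [calibrate_thresholds()],
#'   [apply_certainty_heuristic()]
#' @examples
#' cfg <- cohort_sim_config(n_per_class = rep(40, 4), missingness = c(
#'   CUI = 0, RAD = 0, HRT = 0, HEX = 0, LAB = 0))
#' sim <- generate_cohort(cfg)
#' m <- discretize_features(sim$features, sex = sim$cohort$sex)
#' xg <- assemble_feature_group(m, sim$cohort, "combn1d.age.sex.v1")
#' fit <- stroke_consensus(xg, sim$cohort$toast,
#'                         params = modifyList(tuned_parameters(),
#'                           list(rf = list(n_estimators = 50, max_depth = 10,
#'                                          criterion = "gini",
#'                                          max_features = "sqrt"),
#'                                xgb = list(n_estimators = 30, max_depth = 4,
#'                                           learning_rate = 0.3, gamma = 0,
#'                                           reg_lambda = 1, reg_alpha = 0,
#'                                           subsample = 1))))
#' table(predict(fit, xg), sim$cohort$toast)
#' @export
stroke_consensus <- function(x, y, params = tuned_parameters(),
                             thresholds = NULL, seed = 1L) {
  cl <- match.call()
  xm <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  y <- factor(as.character(y), levels = core_classes())
  if (anyNA(y)) stop("training labels must be in the core set 1-4")
  models <- list(
    LR  = fit_base_model("lr",  xm, y, params$lr,  seed = seed),
    SVC = fit_base_model("svc", xm, y, params$svc, seed = seed),
    RF  = fit_base_model("rf",  xm, y, params$rf,  seed = seed),
    XGB = fit_base_model("xgb", xm, y, params$xgb, seed = seed))
  structure(list(models = models, params = params,
                 feature_names = colnames(xm),
                 classes = core_classes(),
                 n_train = nrow(xm),
                 class_counts = table(y),
                 thresholds = thresholds,
                 seed = seed, call = cl),
            class = "stroke_consensus")
}

# the nine aligned probability sources for new data
.nine_sources <- function(object, newdata) {
  base <- list(
    LR   = predict_proba(object$models$LR, newdata),
    SVC  = predict_proba(object$models$SVC, newdata),
    SVC2 = {
      s <- svc_decision_scores(object$models$SVC, newdata)
      p <- svc2_probabilities(s)
      if (ncol(p) < length(core_classes())) {
        full <- matrix(0, nrow(p), 4, dimnames = list(rownames(p), core_classes()))
        full[, colnames(p)] <- p
        p <- full
      }
      p
    },
    RF   = predict_proba(object$models$RF, newdata),
    XGB  = predict_proba(object$models$XGB, newdata))
  ids <- if (inherits(newdata, "feature_matrix")) newdata$sample_ids else rownames(newdata)
  base <- lapply(base, function(p) { rownames(p) <- ids; p })
  c(base, list(MAX = summary_ensemble(base, "max"),
               MIN = summary_ensemble(base, "min"),
               MEAN = summary_ensemble(base, "mean"),
               MEDIAN = summary_ensemble(base, "median")))
}

#' Predict from a fitted consensus model
#'
#' @param object A `stroke_consensus` fit.
#' @param newdata `feature_matrix` or numeric matrix with the training
#'   features.
#' @param type `"class"` (consensus winner labels), `"consensus"` (the
#'   full `consensus_result` with votes and supports), `"heuristic"`
#'   (certainty-heuristic labels, abstaining to persistently
#'   cryptogenic; needs calibrated thresholds) or `"sources"` (the nine
#'   aligned probability matrices).
#' @param thresholds Optional `support_thresholds` overriding the ones
#'   stored in the fit.
#' @param ... Unused.
#' @return Per `type`: a factor, a `consensus_result`, or a list of nine
#'   probability matrices.
#' @export
predict.stroke_consensus <- function(object, newdata,
                                     type = c("class", "consensus",
                                              "heuristic", "sources"),
                                     thresholds = NULL, ...) {
  type <- match.arg(type)
  sources <- .nine_sources(object, newdata)
  if (type == "sources") return(sources)
  res <- consensus_predict(sources)
  if (type == "consensus") return(res)
  if (type == "class") return(res$winner)
  thr <- if (!is.null(thresholds)) thresholds else object$thresholds
  if (is.null(thr))
    stop("heuristic prediction needs support thresholds; ",
         "run calibrate_thresholds() first")
  apply_certainty_heuristic(res, thr)
}

#' Calibrate the certainty-heuristic thresholds of a fit
#'
#' Runs the consensus on a calibration cohort (held-out or external
#' validation data) and stores the per-class support quantile thresholds
#' in the model object.
#'
#' @param object A `stroke_consensus` fit.
#' @param newdata Calibration features.
#' @param quantile Support quantile (default 0.25, moderate confidence).
#' @return The updated `stroke_consensus` object.
#' @export
calibrate_thresholds <- function(object, newdata, quantile = 0.25) {
  res <- predict(object, newdata, type = "consensus")
  object$thresholds <- derive_support_thresholds(res, quantile)
  object
}

#' @export
print.stroke_consensus <- function(x, ...) {
  cat("Consensus stroke-etiology classifier (9 voting sources)\n")
  cat("trained on", x$n_train, "samples,", length(x$feature_names),
      "features\n")
  cat("class counts:", paste(names(x$class_counts), x$class_counts,
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$thresholds)) {
    cat("certainty thresholds:",
        paste(names(x$thresholds), as.numeric(x$thresholds), sep = "=",
              collapse = ", "), "\n")
  } else cat("certainty thresholds: not calibrated\n")
  invisible(x)
}

#' @export
summary.stroke_consensus <- function(object, ...) {
  cat("Consensus stroke-etiology classifier\n\n")
  cat("Base learners (tuned hyperparameters):\n")
  for (nm in names(object$models)) {
    m <- object$models[[nm]]
    cat(sprintf("  %-4s %s\n", nm,
                paste(names(m$params), unlist(m$params), sep = "=",
                      collapse = ", ")))
  }
  cat("  SVC2 margin-normalized calibration of the SVC decision scores\n")
  cat("Derived ensembles: MAX, MIN, MEAN, MEDIAN (row-normalized)\n")
  cat("Meta-classifier: majority vote of the 9 sources; abstention",
      "below class support thresholds\n")
  print(object)
  invisible(object)
}
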
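# Backends for the four base-learner families. Each family is an
# algorithm contract (penalized multinomial logistic, one-vs-rest kernel
# SVC with balanced class weights, random forest, gradient-boosted trees)
# fitted by an established engine: glmnet, e1071/libsvm, ranger, xgboost.

#' Fit one base classifier
#'
#' @param algorithm `"lr"`, `"svc"`, `"rf"` or `"xgb"`.
#' @param x Numeric design matrix (samples x features, no missing values).
#' @param y Class labels in the core set (coerced to factor over
#'   [core_classes()]).
#' @param params Named hyperparameter list for the algorithm; defaults to
#'   the published tuned values ([tuned_parameters()]).
#' @param seed Integer seed controlling every stochastic element of the
#'   fit (bootstraps, subsampling); fits are deterministic given the seed.
#' @return An object of class `base_model` carrying the fitted engine,
#'   the training feature names and the fixed class order. SVC models
#'   additionally carry deterministic per-class sigmoid (Platt-type)
#'   probability calibration fitted on the training one-vs-rest decision
#'   scores.
#' @export
fit_base_model <- function(algorithm, x, y, params = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, c("lr", "svc", "rf", "xgb"))
  if (is.null(params)) params <- tuned_parameters()[[algorithm]]
  x <- as.matrix(x)
  if (anyNA(x)) stop("base models require complete (imputed) features")
  lv <- core_classes()
  y <- factor(as.character(y), levels = lv)
  if (anyNA(y)) stop("labels outside the core class set")
  classes <- lv[lv %in% unique(as.character(y))]
  y <- factor(as.character(y), levels = classes)
  fit <- switch(algorithm,
    lr = {
      glmnet::glmnet(x, y, family = "multinomial",
                     alpha = params$l1_ratio,
                     lambda = 1 / (nrow(x) * params$C),
                     standardize = FALSE, maxit = 1e5)
    },
    svc = {
      tab <- table(y)
      cw <- sum(tab) / (length(tab) * tab)  # balanced class weights
      kern <- switch(params$kernel, rbf = "radial", poly = "polynomial",
                     linear = "linear", sigmoid = "sigmoid",
                     stop("unknown kernel: ", params$kernel))
      sv <- e1071::svm(x, y, kernel = kern, cost = params$C,
                       gamma = if (is.null(params$gamma)) 1 / ncol(x) else params$gamma,
                       class.weights = stats::setNames(as.numeric(cw), names(tab)),
                       probability = FALSE, scale = FALSE)
      scores <- .svc_ovr_scores(sv, x, classes)
      calib <- lapply(classes, function(cl) .platt_fit(scores[, cl], y == cl))
      names(calib) <- classes
      list(svm = sv, calibration = calib)
    },
    rf = {
      p <- ncol(x)
      mtry <- switch(params$max_features,
                     sqrt = max(1L, floor(sqrt(p))),
                     log2 = max(1L, floor(log2(p))),
                     stop("unknown max_features: ", params$max_features))
      # backend note: ranger has no entropy splitrule for classification;
      # the criterion axis maps to gini
      ranger::ranger(y = y, x = as.data.frame(x),
                     num.trees = params$n_estimators,
                     max.depth = params$max_depth, mtry = mtry,
                     min.node.size = 2, probability = TRUE,
                     seed = seed, num.threads = 1)
    },
    xgb = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = params$max_depth,
                      eta = params$learning_rate,
                      gamma = params$gamma,
                      lambda = params$reg_lambda,
                      alpha = params$reg_alpha,
                      subsample = params$subsample,
                      nthread = 1),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
    })
  structure(list(algorithm = algorithm, params = params, fit = fit,
                 feature_names = colnames(x), classes = classes,
                 seed = seed),
            class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  cat("base_model:", x$algorithm, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

# one-vs-rest margin scores from libsvm's one-vs-one decision values:
# each class's score is the signed sum of its pairwise decision values
.svc_ovr_scores <- function(sv, x, classes) {
  dv <- attr(stats::predict(sv, x, decision.values = TRUE), "decision.values")
  out <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  for (nm in colnames(dv)) {
    pair <- strsplit(nm, "/", fixed = TRUE)[[1]]
    out[, pair[1]] <- out[, pair[1]] + dv[, nm]
    out[, pair[2]] <- out[, pair[2]] - dv[, nm]
  }
  out
}

# Platt-type sigmoid calibration of a decision score; deterministic
.platt_fit <- function(score, is_class) {
  df <- data.frame(y = as.numeric(is_class), s = score)
  fit <- suppressWarnings(stats::glm(y ~ s, data = df, family = stats::binomial()))
  unname(stats::coef(fit))
}

.platt_apply <- function(coefs, score) {
  co <- ifelse(is.na(coefs), 0, coefs)
  stats::plogis(co[1] + co[2] * score)
}

#' Per-class probability predictions from a base model
#'
#' Columns follow the model's fixed class order; features are aligned by
#' name, so column permutations of the input do not change predictions.
#' Every row is non-negative and sums to 1.
#'
#' @param model A `base_model`.
#' @param x A `feature_matrix` or numeric matrix with the training
#'   features.
#' @return Numeric matrix (samples x classes) of probabilities.
#' @export
predict_proba <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  if (!setequal(colnames(x), model$feature_names) ||
      ncol(x) != length(model$feature_names)) {
    extra <- setdiff(colnames(x), model$feature_names)
    absent <- setdiff(model$feature_names, colnames(x))
    stop("feature mismatch; unexpected: [", paste(extra, collapse = ", "),
         "] missing: [", paste(absent, collapse = ", "), "]")
  }
  x <- x[, model$feature_names, drop = FALSE]
  p <- switch(model$algorithm,
    lr = {
      pr <- stats::predict(model$fit, newx = x, type = "response")
      pr[, , 1]
    },
    svc = {
      scores <- .svc_ovr_scores(model$fit$svm, x, model$classes)
      pr <- vapply(model$classes, function(cl)
        .platt_apply(model$fit$calibration[[cl]], scores[, cl]),
        numeric(nrow(x)))
      if (nrow(x) == 1L) pr <- matrix(pr, nrow = 1L,
                                      dimnames = list(NULL, model$classes))
      pr
    },
    rf = stats::predict(model$fit, data = as.data.frame(x),
                        num.threads = 1)$predictions,
    xgb = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      matrix(pr, ncol = length(model$classes), byrow = TRUE)
    })
  p <- as.matrix(p)
  colnames(p) <- model$classes
  rownames(p) <- rownames(x)
  p <- pmax(p, 0)
  sums <- rowSums(p)
  sums[sums == 0] <- 1
  p <- p / sums
  # models trained without some core class still report 4 columns
  if (length(model$classes) < length(core_classes())) {
    full <- matrix(0, nrow(p), length(core_classes()),
                   dimnames = list(rownames(p), core_classes()))
    full[, model$classes] <- p
    p <- full
  }
  p
}

#' One-vs-rest decision scores of a fitted SVC base model
#'
#' @param model A `base_model` with `algorithm = "svc"`.
#' @param x Feature matrix or numeric matrix.
#' @return Numeric matrix (samples x classes) of margin scores.
#' @export
svc_decision_scores <- function(model, x) {
  stopifnot(model$algorithm == "svc")
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)[, model$feature_names, drop = FALSE]
  .svc_ovr_scores(model$fit$svm, x, model$classes)
}

#' Margin-normalized SVC probabilities (the SVC2 calibration)
#'
#' Converts per-sample per-class decision scores into probabilities by
#' shifting each row so its minimum is zero and dividing by the row sum.
#' Rows with all-equal scores return the uniform distribution.
#'
#' @param scores Numeric matrix (samples x classes) of finite margin
#'   scores.
#' @return Probability matrix with rows summing to 1.
#' @export
svc2_probabilities <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("decision scores must be finite")
  shifted <- scores - apply(scores, 1, min)
  sums <- rowSums(shifted)
  out <- shifted
  uniform <- sums == 0
  out[!uniform, ] <- shifted[!uniform, , drop = FALSE] / sums[!uniform]
  out[uniform, ] <- 1 / ncol(scores)
  out
}

# support-weighted one-vs-rest AUROC used as the grid-search criterion
.weighted_ovr_auroc <- function(y, probs) {
  y <- as.character(y)
  classes <- colnames(probs)
  present <- classes[classes %in% unique(y)]
  w <- vapply(present, function(cl) sum(y == cl), numeric(1))
  aucs <- vapply(present, function(cl) {
    pos <- y == cl
    if (all(pos) || !any(pos)) return(NA_real_)
    r <- rank(probs[, cl])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1))
  sum(w * aucs, na.rm = TRUE) / sum(w[!is.na(aucs)])
}

#' Grid-search hyperparameter optimization for one base learner
#'
#' For every grid point, fits the model on each split's training rows and
#' scores support-weighted one-vs-rest AUROC on the validation rows; the
#' winner is the grid point with the maximal mean validation AUROC across
#' splits (per-split-then-mean), ties broken by the first point in
#' declared grid order. A grid point whose fit raises an unrecoverable
#' error is scored `-Inf` and recorded. The winning configuration is
#' refit on all rows.
#'
#' @param algorithm `"lr"`, `"svc"`, `"rf"` or `"xgb"`.
#' @param x Complete numeric design matrix or `feature_matrix`.
#' @param y Core-class labels.
#' @param plan A `cv_plan` (typically 5 stratified 20% shuffle splits,
#'   seed 1701).
#' @param grid Grid to search; default the full [hpo_grid()] for the
#'   algorithm (subsets are useful for quick studies).
#' @param seed Seed passed to each fit.
#' @return List with `model` (the refit winner), `table` (the grid with a
#'   `mean_auroc` column, one row per grid point) and `winner` (row index).
#' @export
run_hpo <- function(algorithm, x, y, plan, grid = hpo_grid(algorithm),
                    seed = 1L) {
  if (inherits(x, "feature_matrix")) x <- x$values
  x <- as.matrix(x)
  y <- as.character(y)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    split_scores <- vapply(plan$splits, function(sp) {
      tryCatch({
        fit <- fit_base_model(algorithm, x[sp$train, , drop = FALSE],
                              y[sp$train], params, seed = seed)
        pr <- predict_proba(fit, x[sp$validation, , drop = FALSE])
        .weighted_ovr_auroc(y[sp$validation], pr)
      }, error = function(e) -Inf)
    }, numeric(1))
    scores[g] <- mean(split_scores)
  }
  winner <- which.max(scores)  # first maximum in grid order
  tab <- cbind(as.data.frame(grid), mean_auroc = scores)
  model <- fit_base_model(algorithm, x, y,
                          as.list(grid[winner, , drop = FALSE]), seed = seed)
  list(model = model, table = tab, winner = winner)
}
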
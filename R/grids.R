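#' Hyperparameter grids for the four base-learner families
#'
#' Exact grid axes for each algorithm family, enumerated in declared axis
#' order (first axis varying fastest), which also fixes the deterministic
#' tie-break order of the grid search:
#'
#' * `lr` — penalized multinomial logistic regression with elastic net:
#'   13 values of `C` (1e-2..1e10) x 11 values of `l1_ratio` (0..1) =
#'   143 combinations; fixed: elastic-net penalty, 500 max iterations.
#' * `svc` — one-vs-rest kernel SVC with balanced class weights:
#'   13 `C` x 13 `gamma` (1e-9..1e3) x 4 kernels (linear, poly, rbf,
#'   sigmoid) = 676 combinations.
#' * `rf` — random forest: 3 `n_estimators` x 4 `max_depth` x 2
#'   `criterion` x 2 `max_features` = 48 combinations; fixed: minimum
#'   leaf size 2.
#' * `xgb` — gradient-boosted trees: 2 `n_estimators` x 3 `max_depth` x
#'   5 `learning_rate` x 3 `gamma` x 3 `reg_lambda` x 3 `reg_alpha` x
#'   2 `subsample` = 1620 combinations.
#'
#' @param algorithm One of `"lr"`, `"svc"`, `"rf"`, `"xgb"`.
#' @return A `data.frame` of class `hpo_grid`, one row per combination,
#'   with the fixed constants in `attr(, "fixed")`.
#' @export
hpo_grid <- function(algorithm = c("lr", "svc", "rf", "xgb")) {
  algorithm <- match.arg(algorithm)
  g <- switch(algorithm,
    lr = {
      out <- expand.grid(C = 10^seq(-2, 10),
                         l1_ratio = seq(0, 1, by = 0.1),
                         KEEP.OUT.ATTRS = FALSE)
      attr(out, "fixed") <- list(penalty = "elasticnet", max_iter = 500)
      out
    },
    svc = {
      out <- expand.grid(C = 10^seq(-2, 10),
                         gamma = 10^seq(-9, 3),
                         kernel = c("linear", "poly", "rbf", "sigmoid"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      attr(out, "fixed") <- list(decision_function_shape = "ovr",
                                 class_weight = "balanced", max_iter = 1000)
      out
    },
    rf = {
      out <- expand.grid(n_estimators = c(200, 500, 1000),
                         max_depth = c(10, 20, 50, 100),
                         criterion = c("gini", "entropy"),
                         max_features = c("sqrt", "log2"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      attr(out, "fixed") <- list(min_samples_leaf = 2)
      out
    },
    xgb = {
      out <- expand.grid(n_estimators = c(500, 1000),
                         max_depth = c(4, 5, 6),
                         learning_rate = c(0.01, 0.1, 0.3, 0.5, 1),
                         gamma = c(0.0, 5.0, 10.0),
                         reg_lambda = c(0.0, 0.5, 1.0),
                         reg_alpha = c(0.0, 0.5, 1.0),
                         subsample = c(1.0, 0.75),
                         KEEP.OUT.ATTRS = FALSE)
      attr(out, "fixed") <- list()
      out
    })
  attr(g, "algorithm") <- algorithm
  class(g) <- c("hpo_grid", "data.frame")
  g
}

#' Published tuned hyperparameters for the base learners
#'
#' The grid-search optima reported for the derivation cohorts; used as
#' the default base-model parameters when the full grid search is not
#' re-run.
#'
#' @return Named list of per-algorithm parameter lists.
#' @export
tuned_parameters <- function() {
  list(lr  = list(C = 0.01, l1_ratio = 0.0),
       svc = list(C = 1.0, gamma = 0.01, kernel = "rbf"),
       rf  = list(n_estimators = 1000, max_depth = 20, criterion = "gini",
                  max_features = "sqrt"),
       xgb = list(n_estimators = 1000, max_depth = 5, learning_rate = 0.01,
                  gamma = 0.0, reg_lambda = 0.0, reg_alpha = 0.0,
                  subsample = 0.75))
}
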
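#' Chained-equation imputation of a feature matrix
#'
#' Single-dataset multiple-imputation-by-chained-equations sweep.
#' Missing cells are initialized by random draws from each feature's
#' observed marginal, then the sweep visits features in column order for
#' `n_iterations` rounds, regressing each incomplete feature on all other
#' current features:
#'
#' * `pmm` (predictive mean matching, the derivation-cohort strategy):
#'   continuous targets use a linear model, binary targets a logistic
#'   model, multi-band categorical targets a linear model on the band
#'   code; each missing cell receives the *observed* value of one of the
#'   `pmm_donors` donors whose model prediction is nearest, so imputed
#'   values always lie in the observed support.
#' * `forest` (the external-cohort strategy for heavier missingness):
#'   a random forest per target, missing cells replaced by the forest
#'   prediction (majority class for non-continuous targets).
#' * `sample`: random redraw from the observed marginal each sweep.
#'
#' Features whose model cannot be fit in `max_model_failures` consecutive
#' sweeps, or with no observed values at all, are dropped and reported.
#' Observed cells are never altered. Deterministic given `seed`.
#'
#' @param m A `feature_matrix`.
#' @param method `"pmm"`, `"forest"` or `"sample"`.
#' @param n_iterations Number of chained sweeps (default 5).
#' @param pmm_donors Donor pool size for matching (default 5).
#' @param seed Integer seed.
#' @param max_model_failures Consecutive unfittable sweeps before a
#'   feature is dropped (default 3).
#' @return List with `features` (complete `feature_matrix`, mask all
#'   false) and `dropped` (character vector of dropped feature names).
#' @export
impute_features <- function(m, method = c("pmm", "forest", "sample"),
                            n_iterations = 5L, pmm_donors = 5L, seed = 1L,
                            max_model_failures = 3L) {
  method <- match.arg(method)
  stopifnot(n_iterations >= 1, pmm_donors >= 1, max_model_failures >= 1)
  set.seed(seed)
  v <- m$values
  miss <- m$missing_mask
  d <- m$descriptors

  dropped <- d$name[colSums(!miss) == 0]
  keep <- setdiff(colnames(v), dropped)
  v <- v[, keep, drop = FALSE]
  miss <- miss[, keep, drop = FALSE]
  d <- d[d$name %in% keep, , drop = FALSE]
  if (!ncol(v)) stop("all features dropped: no observed values to impute from")
  if (!any(miss)) {
    return(list(features = fm_subset(m, features = keep), dropped = dropped))
  }

  orig <- v
  # initialization: marginal draws from each feature's observed values
  for (j in seq_len(ncol(v))) {
    mj <- miss[, j]
    if (any(mj)) {
      obs <- v[!mj, j]
      v[mj, j] <- if (length(obs) == 1L) obs else sample(obs, sum(mj), replace = TRUE)
    }
  }

  failures <- integer(ncol(v))
  names(failures) <- colnames(v)
  incomplete <- which(colSums(miss) > 0)

  for (iter in seq_len(n_iterations)) {
    for (j in incomplete) {
      nm <- colnames(v)[j]
      if (nm %in% dropped) next
      mj <- miss[, j]
      yobs <- orig[!mj, j]
      if (length(unique(yobs)) < 2L) { # constant observed support
        v[mj, j] <- yobs[1]
        next
      }
      x <- v[, -j, drop = FALSE]
      ok <- tryCatch({
        pred <- .impute_predict(method, x, orig[, j], mj, d$kind[j], seed,
                                iter, j)
        v[mj, j] <- .impute_fill(method, pred, yobs, mj, pmm_donors)
        TRUE
      }, error = function(e) FALSE)
      if (ok) failures[j] <- 0L else {
        failures[j] <- failures[j] + 1L
        if (failures[j] >= max_model_failures) dropped <- c(dropped, nm)
      }
    }
  }

  keep2 <- setdiff(colnames(v), dropped)
  if (!length(keep2)) stop("all features dropped during imputation")
  v <- v[, keep2, drop = FALSE]
  d <- d[d$name %in% keep2, , drop = FALSE]
  # observed cells are restored bit-exactly
  omask <- !miss[, keep2, drop = FALSE]
  v[omask] <- orig[, keep2, drop = FALSE][omask]
  rownames(d) <- NULL
  list(features = feature_matrix(v, d, m$sample_ids), dropped = dropped)
}

# model predictions for all rows of the target feature
.impute_predict <- function(method, x, y_orig, mj, kind, seed, iter, j) {
  if (method == "sample") return(NULL)
  if (method == "forest") {
    df <- as.data.frame(x)
    yobs <- y_orig[!mj]
    if (kind == "continuous") {
      fit <- ranger::ranger(y = yobs, x = df[!mj, , drop = FALSE],
                            num.trees = 100, seed = seed + 7L * iter + j,
                            num.threads = 1)
      stats::predict(fit, df)$predictions
    } else {
      fit <- ranger::ranger(y = factor(yobs), x = df[!mj, , drop = FALSE],
                            num.trees = 100, seed = seed + 7L * iter + j,
                            num.threads = 1)
      as.numeric(as.character(stats::predict(fit, df)$predictions))
    }
  } else { # pmm
    xx <- cbind(1, x)
    if (kind == "binary") {
      yb <- as.numeric(y_orig[!mj] != min(y_orig[!mj]))
      fit <- suppressWarnings(stats::glm.fit(xx[!mj, , drop = FALSE], yb,
                                             family = stats::binomial()))
      co <- fit$coefficients
      co[is.na(co)] <- 0
      stats::plogis(drop(xx %*% co))
    } else {
      fit <- stats::lm.fit(xx[!mj, , drop = FALSE], y_orig[!mj])
      co <- fit$coefficients
      co[is.na(co)] <- 0
      drop(xx %*% co)
    }
  }
}

# turn predictions into imputed values for the missing rows
.impute_fill <- function(method, pred, yobs, mj, pmm_donors) {
  n_missing <- sum(mj)
  if (method == "sample")
    return(sample(yobs, n_missing, replace = TRUE))
  if (method == "forest")
    return(pred[mj])
  # pmm: nearest observed donors by predicted value
  pm <- pred[mj]
  po <- pred[!mj]
  k <- min(pmm_donors, length(po))
  vapply(pm, function(p) {
    ord <- order(abs(po - p))[seq_len(k)]
    yobs[ord[sample.int(k, 1L)]]
  }, numeric(1))
}
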
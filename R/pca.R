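#' Fit a PCA model on training features
#'
#' Centers every feature and (by default) scales only the continuous
#' features to unit variance, then takes the full singular value
#' decomposition. Each loading vector is oriented so that its
#' largest-magnitude entry is positive, making component signs
#' reproducible. Centers and scales are learned on the supplied
#' (training) rows only; held-out data are transformed with these frozen
#' statistics, never their own.
#'
#' @param m A complete `feature_matrix` (no missing values) or a numeric
#'   matrix (then every column is treated as continuous).
#' @param standardize_continuous Scale continuous features to unit sd
#'   (default `TRUE`); binary/categorical features are centered only.
#' @return An object of class `pca_model` with `loadings` (features x
#'   components), `explained_variance_ratio`, `center`, `scale`,
#'   `feature_names` and a `threshold_table` for the standard variance
#'   thresholds (10%...99%).
#' @export
fit_pca <- function(m, standardize_continuous = TRUE) {
  if (inherits(m, "feature_matrix")) {
    if (any(m$missing_mask)) stop("PCA input must have no missing values")
    x <- m$values
    cont <- m$descriptors$kind == "continuous"
  } else {
    x <- as.matrix(m)
    cont <- rep(TRUE, ncol(x))
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  center <- colMeans(x)
  scl <- stats::setNames(rep(1, ncol(x)), colnames(x))
  if (standardize_continuous) {
    s <- apply(x, 2, stats::sd)
    scl[cont] <- ifelse(s[cont] > 0, s[cont], 1)
  }
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  # sign convention: largest-magnitude loading entry positive
  flip <- apply(load, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  thresholds <- c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90,
                  0.95, 0.99)
  model <- structure(list(loadings = load,
                          explained_variance_ratio = evr,
                          center = center, scale = scl,
                          feature_names = colnames(x)),
                     class = "pca_model")
  model$threshold_table <- data.frame(
    threshold = thresholds,
    components = vapply(thresholds, function(t) select_components(model, t),
                        integer(1)))
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", length(x$feature_names), "features,",
      length(x$explained_variance_ratio), "components\n")
  print(x$threshold_table, row.names = FALSE)
  invisible(x)
}

#' Number of components reaching a cumulative variance threshold
#'
#' Returns the smallest component count whose cumulative explained
#' variance ratio reaches the threshold. If the threshold exceeds the
#' attainable cumulative variance, all components are returned with a
#' warning.
#'
#' @param model A `pca_model`.
#' @param threshold Fraction of total variance in (0, 1\].
#' @return Integer component count.
#' @export
select_components <- function(model, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cum <- cumsum(model$explained_variance_ratio)
  hit <- which(cum >= threshold - 1e-9)
  if (!length(hit)) {
    warning("threshold ", threshold, " exceeds attainable cumulative variance; ",
            "returning all components")
    return(length(cum))
  }
  as.integer(hit[1])
}

#' Project data onto fitted principal components
#'
#' Applies the training centers/scales and loadings to new data. Score
#' columns are named `PC0..PC(k-1)` (0-indexed).
#'
#' @param model A `pca_model`.
#' @param m A `feature_matrix` or numeric matrix whose features match the
#'   model's training features.
#' @param k Number of leading components (default: all).
#' @return A `feature_matrix` of PC scores (continuous kind).
#' @export
transform_pca <- function(model, m, k = NULL) {
  x <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
  if (is.null(k)) k <- ncol(model$loadings)
  if (k < 1) stop("k must be at least 1")
  k <- min(k, ncol(model$loadings))
  if (!setequal(colnames(x), model$feature_names) ||
      length(colnames(x)) != length(model$feature_names)) {
    extra <- setdiff(colnames(x), model$feature_names)
    absent <- setdiff(model$feature_names, colnames(x))
    stop("feature mismatch; unexpected: [", paste(extra, collapse = ", "),
         "] missing: [", paste(absent, collapse = ", "), "]")
  }
  x <- x[, model$feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- xs %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k) - 1L)
  ids <- if (inherits(m, "feature_matrix")) m$sample_ids else rownames(x)
  feature_matrix(scores,
                 feature_descriptors(colnames(scores), "HEX", "continuous"),
                 ids)
}

#' Serialize / restore a PCA model as JSON
#' @param model A `pca_model`.
#' @param path File path.
#' @return `write_pca_model` returns `path` invisibly; `read_pca_model`
#'   returns a `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  obj <- list(loadings = model$loadings,
              explained_variance_ratio = model$explained_variance_ratio,
              center = model$center, scale = model$scale,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- as.matrix(obj$loadings)
  rownames(load) <- obj$feature_names
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  model <- structure(list(loadings = load,
                          explained_variance_ratio = obj$explained_variance_ratio,
                          center = stats::setNames(obj$center, obj$feature_names),
                          scale = stats::setNames(obj$scale, obj$feature_names),
                          feature_names = obj$feature_names),
                     class = "pca_model")
  model
}
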
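#' Feature categories used throughout the package
#'
#' The five information categories extracted from discharge summaries plus
#' the two demographic pseudo-categories. CUI features are binary presence
#' indicators of clinical concepts; RAD are binary neuroimaging findings;
#' HRT are cardiac findings; HEX are clinical history and vital signs; LAB
#' are laboratory values.
#'
#' @return Character vector of category codes.
#' @export
feature_categories <- function() c("CUI", "RAD", "HRT", "HEX", "LAB")

#' Core etiology label set
#'
#' TOAST codes used as training labels: 1 large-artery atherosclerosis,
#' 2 cardioembolism, 3 small-vessel disease, 4 other determined etiology.
#' Code 5 (cryptogenic) is accepted as an input label only and
#' `"persistently_cryptogenic"` is an output label only.
#'
#' @return Character vector `c("1","2","3","4")`.
#' @export
core_classes <- function() c("1", "2", "3", "4")

#' Abstention label emitted by the certainty heuristic
#' @return The string `"persistently_cryptogenic"`.
#' @export
cryptogenic_label <- function() "persistently_cryptogenic"

#' Construct a feature descriptor table
#'
#' @param name Feature names (unique).
#' @param category One of `feature_categories()` per feature.
#' @param kind `"binary"`, `"categorical"` or `"continuous"`.
#' @param unit Measurement unit, `""` if none.
#' @param discretization_rule Rule id from [discretization_rules()] or `NA`.
#' @param discretized Logical; whether the feature is already a discretized
#'   band variable.
#' @return A `data.frame` with one row per feature.
#' @export
feature_descriptors <- function(name, category, kind, unit = "",
                                discretization_rule = NA_character_,
                                discretized = FALSE) {
  d <- data.frame(name = as.character(name),
                  category = as.character(category),
                  kind = as.character(kind),
                  unit = rep_len(as.character(unit), length(name)),
                  discretization_rule = rep_len(as.character(discretization_rule), length(name)),
                  discretized = rep_len(as.logical(discretized), length(name)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$name))
    stop("duplicate feature names: ",
         paste(unique(d$name[duplicated(d$name)]), collapse = ", "))
  bad <- !d$category %in% c(feature_categories(), "AGE", "SEX")
  if (any(bad))
    stop("unknown feature category: ", paste(unique(d$category[bad]), collapse = ", "))
  if (!all(d$kind %in% c("binary", "categorical", "continuous")))
    stop("kind must be binary, categorical or continuous")
  binlike <- d$category %in% c("CUI", "RAD")
  if (any(binlike & d$kind != "binary"))
    stop("CUI and RAD features must be binary")
  d
}

#' Construct a sample-by-feature matrix with an explicit missingness mask
#'
#' Values are stored as a numeric matrix with `NA` for missing cells; the
#' missingness mask is maintained alongside and the two are kept
#' consistent (mask true if and only if the value is absent).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param descriptors A descriptor table from [feature_descriptors()]
#'   whose `name` column matches `colnames(values)` in order.
#' @param sample_ids Character sample identifiers; defaults to row names
#'   or `s1..sN`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, descriptors, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("feature matrix needs at least one sample and one feature")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!identical(as.character(descriptors$name), as.character(colnames(values))))
    stop("descriptor names must match value columns in order")
  rownames(values) <- sample_ids
  structure(list(values = values,
                 descriptors = descriptors,
                 sample_ids = as.character(sample_ids),
                 missing_mask = is.na(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  tab <- table(x$descriptors$category)
  cat("categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("missing cells: %.1f%%\n", 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by samples and/or features
#'
#' @param m A `feature_matrix`.
#' @param samples Row index (integer, logical or sample ids); `NULL` keeps all.
#' @param features Column index (integer, logical or feature names); `NULL`
#'   keeps all.
#' @return A `feature_matrix`.
#' @export
fm_subset <- function(m, samples = NULL, features = NULL) {
  v <- m$values
  d <- m$descriptors
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, colnames(v))
    v <- v[, features, drop = FALSE]
    d <- d[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(v))
    v <- v[samples, , drop = FALSE]
  }
  rownames(d) <- NULL
  feature_matrix(v, d, rownames(v))
}

#' Read a delimited feature table against a declared schema
#'
#' Expects a header row naming the features; columns prefixed `meta_` are
#' ignored here (see [read_cohort_table()]). The missingness sentinel is
#' the empty cell by default, with configurable alternates.
#'
#' @param path Path to a CSV (or TSV via `sep`) file.
#' @param schema Descriptor table from [feature_descriptors()].
#' @param na Strings mapped to missing; default the empty string.
#' @param sep Field separator.
#' @param id_column Optional name of a sample-id column.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, schema, na = "", sep = ",",
                                id_column = "sample_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  if (anyDuplicated(header))
    stop("duplicated column name in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"")
  keep <- !startsWith(names(df), "meta_")
  df <- df[, keep, drop = FALSE]
  ids <- if (id_column %in% names(df)) {
    out <- df[[id_column]]
    df[[id_column]] <- NULL
    out
  } else paste0("s", seq_len(nrow(df)))
  unknown <- setdiff(names(df), schema$name)
  if (length(unknown)) stop("columns not in schema: ", paste(unknown, collapse = ", "))
  absent <- setdiff(schema$name, names(df))
  if (length(absent)) stop("schema features missing from file: ",
                           paste(absent, collapse = ", "))
  df <- df[, schema$name, drop = FALSE]
  vals <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    x <- df[[j]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   x[bad[1]], names(df)[j], bad[1]))
    vals[, j] <- num
  }
  feature_matrix(vals, schema, ids)
}

#' Write a feature matrix as RFC-4180 CSV
#'
#' Missing cells are written as the empty string; a `sample_id` column is
#' prepended. Round-trips bit-exactly through [read_feature_matrix()].
#'
#' @param m A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(sample_id = m$sample_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   eol = "\r\n")
  invisible(path)
}

#' Serialize / restore a feature descriptor table as JSON
#'
#' @param schema A descriptor table from [feature_descriptors()].
#' @param path File path.
#' @return `write_feature_schema` returns `path` invisibly;
#'   `read_feature_schema` returns the descriptor `data.frame`.
#' @export
write_feature_schema <- function(schema, path) {
  jsonlite::write_json(schema, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_feature_schema
#' @export
read_feature_schema <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_descriptors(df$name, df$category, df$kind, df$unit,
                      df$discretization_rule, df$discretized)
}

#' Per-category completeness of a feature matrix
#'
#' Fraction of samples carrying at least one non-missing value in each
#' feature category present in the matrix, mirroring the "degree of
#' feature completeness" cohort summary.
#'
#' @param m A `feature_matrix`.
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
compute_completeness <- function(m) {
  cats <- unique(m$descriptors$category)
  cats <- cats[cats %in% feature_categories()]
  out <- vapply(cats, function(cc) {
    cols <- which(m$descriptors$category == cc)
    mean(rowSums(!m$missing_mask[, cols, drop = FALSE]) > 0)
  }, numeric(1))
  out
}

#' MaxInfo per sample
#'
#' The number of the five information categories (CUI, RAD, HRT, HEX, LAB)
#' in which a sample has at least one non-missing value.
#'
#' @param m A `feature_matrix`.
#' @return Integer vector, one entry per sample.
#' @export
maxinfo <- function(m) {
  cats <- intersect(feature_categories(), unique(m$descriptors$category))
  present <- vapply(cats, function(cc) {
    cols <- which(m$descriptors$category == cc)
    rowSums(!m$missing_mask[, cols, drop = FALSE]) > 0
  }, logical(nrow(m$values)))
  if (nrow(m$values) == 1L) present <- matrix(present, nrow = 1L)
  as.integer(rowSums(present))
}

#' Filter samples by MaxInfo completeness
#'
#' Retains samples for which at least `min_categories` of the five
#' information categories carry at least one extracted (non-missing)
#' value.
#'
#' @param m A `feature_matrix`.
#' @param min_categories Minimum category count; default 4.
#' @return A `feature_matrix` restricted to the retained samples.
#' @export
apply_maxinfo_filter <- function(m, min_categories = 4L) {
  if (min_categories > 5L) stop("min_categories cannot exceed the 5 categories")
  keep <- maxinfo(m) >= min_categories
  if (!any(keep)) stop("no samples satisfy the MaxInfo filter")
  fm_subset(m, samples = which(keep))
}
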
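#' Registry of the 24 feature groups
#'
#' The feature-group registry enumerates every training dataset variant
#' used for hyperparameter optimization: the demographic-only groups (raw,
#' binarized and standardized age), each single category (raw and
#' discretized where applicable), the leave-one-category-out combinations,
#' the full feature set with and without discretization, and the
#' discretized full set with MaxInfo filtering and/or PCA. Age enters as
#' raw years (`v1`), binarized at 65 years (`v2`) or standardized
#' (`v3`/PCA groups).
#'
#' @return A `data.frame` with one row per group: `group_id`, `categories`
#'   (plus-separated category spec, `d` suffix selecting the discretized
#'   variant), `age_variant`, `maxinfo`, `pca`.
#' @export
feature_group_registry <- function() {
  g <- function(id, cats, age = "none", mi = FALSE, pca = FALSE)
    data.frame(group_id = id, categories = cats, age_variant = age,
               maxinfo = mi, pca = pca, stringsAsFactors = FALSE)
  full  <- "HEX+LAB+HRT+RAD+CUI"
  fulld <- "HEXd+LABd+HRT+RAD+CUI"
  rbind(
    g("age.sex.v1", "", "raw"),
    g("age.sex.v2", "", "binarized"),
    g("age.sex.v3", "", "standardized"),
    g("hex",  "HEX"),  g("hexd", "HEXd"),
    g("lab",  "LAB"),  g("labd", "LABd"),
    g("hrt",  "HRT"),  g("rad",  "RAD"),  g("cui", "CUI"),
    g("combn1.age.sex.v1", full, "raw"),
    g("combn2.age.sex.v1", "HEX+HRT+RAD+CUI", "raw"),
    g("combn3.age.sex.v1", "LAB+HRT+RAD+CUI", "raw"),
    g("combn4.age.sex.v1", "HEX+LAB+RAD+CUI", "raw"),
    g("combn5.age.sex.v1", "HEX+LAB+HRT+CUI", "raw"),
    g("combn6.age.sex.v1", "HEX+LAB+HRT+RAD", "raw"),
    g("combn1d.age.sex.v1", fulld, "raw"),
    g("combn1d.age.sex.v2", fulld, "binarized"),
    g("combn1d.age.sex.v1.maxinfo", fulld, "raw", mi = TRUE),
    g("combn1d.age.sex.v2.maxinfo", fulld, "binarized", mi = TRUE),
    g("combn1d.age.sex.v1.pca", fulld, "standardized", pca = TRUE),
    g("combn1d.age.sex.v2.pca", fulld, "binarized", pca = TRUE),
    g("combn1d.age.sex.v1.maxinfo.pca", fulld, "standardized", mi = TRUE, pca = TRUE),
    g("combn1d.age.sex.v2.maxinfo.pca", fulld, "binarized", mi = TRUE, pca = TRUE)
  )
}

#' Assemble the design matrix for one feature group
#'
#' Projects a (typically discretized, imputed) feature matrix onto the
#' categories a registered feature group requests and prepends the age
#' and sex demographic columns per the group's age variant. Column order
#' is deterministic: `age`, `sex`, then categories in the declared order
#' (HEX, LAB, HRT, RAD, CUI), name-lexicographic within a category. Sex
#' is encoded male = 1, female = 0; binarized age is the indicator of age
#' >= 65 years; standardized age uses the mean/sd of the supplied rows
#' unless training statistics are passed via `age_stats`.
#'
#' @param m A `feature_matrix` (discretized variants selected by the `d`
#'   suffix in the group's category spec).
#' @param demo A `cohort_table` aligned with `m` (matched by sample id).
#' @param group_id A group id from [feature_group_registry()], or a
#'   one-row registry-style data.frame.
#' @param age_stats Optional `c(mean, sd)` learned on training rows, for
#'   leakage-free standardized-age transforms of held-out data.
#' @return A `feature_matrix` containing exactly the requested columns.
#'   The `maxinfo` and `pca` flags of the registry are *not* applied here;
#'   they are separate pipeline stages.
#' @export
assemble_feature_group <- function(m, demo = NULL, group_id,
                                   age_stats = NULL) {
  reg <- feature_group_registry()
  spec <- if (is.data.frame(group_id)) group_id else {
    row <- reg[reg$group_id == group_id, , drop = FALSE]
    if (!nrow(row)) stop("unknown feature group id: ", group_id)
    row
  }
  d <- m$descriptors
  cats <- if (nzchar(spec$categories)) strsplit(spec$categories, "+", fixed = TRUE)[[1]] else character()
  cols <- integer()
  for (cc in cats) {
    want_disc <- endsWith(cc, "d") && !cc %in% feature_categories()
    base <- if (want_disc) substr(cc, 1, nchar(cc) - 1) else cc
    idx <- which(d$category == base)
    if (!length(idx)) stop("no features available for category ", cc)
    rule_bearing <- !is.na(d$discretization_rule[idx]) | d$discretized[idx]
    if (want_disc && any(rule_bearing & !d$discretized[idx]))
      stop("category ", cc, " requested in discretized form but matrix is not discretized")
    cols <- c(cols, idx[order(d$name[idx])])
  }
  v <- m$values[, cols, drop = FALSE]
  dd <- d[cols, , drop = FALSE]
  if (spec$age_variant != "none") {
    if (is.null(demo)) stop("feature group '", spec$group_id, "' needs cohort demographics")
    demo <- demo[match(m$sample_ids, demo$sample_id), , drop = FALSE]
    age <- switch(spec$age_variant,
      raw = demo$age,
      binarized = as.numeric(demo$age >= 65),
      standardized = {
        st <- if (is.null(age_stats)) c(mean(demo$age), stats::sd(demo$age)) else age_stats
        (demo$age - st[1]) / st[2]
      },
      stop("unknown age variant: ", spec$age_variant))
    sexn <- as.numeric(demo$sex == "male")
    v <- cbind(age = age, sex = sexn, v)
    dd <- rbind(feature_descriptors(c("age", "sex"), c("AGE", "SEX"),
                                    c(if (spec$age_variant == "binarized") "binary" else "continuous",
                                      "binary")),
                dd)
  }
  colnames(v) <- dd$name
  rownames(dd) <- NULL
  feature_matrix(v, dd, m$sample_ids)
}
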
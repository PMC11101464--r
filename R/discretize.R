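#' Registry of clinical discretization rules
#'
#' Cut points for converting continuous clinical history (HEX), laboratory
#' (LAB) and selected cardiac values into clinically relevant bands. Band
#' boundaries belong to the upper band unless stated otherwise, so e.g. an
#' ejection fraction of exactly 40 falls in the ">=40" band. The
#' hematocrit normal band is the half-open interval \[35, 46) and the
#' sex-specific hemoglobin normal bands are closed above (a value equal to
#' the upper normal limit is normal), keeping every band contiguous.
#'
#' Rules: ejection fraction <40 (severely reduced) vs >=40; NIHSS <6
#' (minor stroke) vs >=6; sodium <136 (hyponatremia) vs >=136; BUN >=24 vs
#' <24; ALT and AST <36 vs >=36; white-cell count <11 vs >=11
#' (leukocytosis); hematocrit <35 / 35-45 / >=46; hemoglobin (female)
#' <11.7 / 11.7-15.5 / >15.5 and (male) <13.2 / 13.2-17.1 / >17.1;
#' triglycerides >=200 (hypertriglyceridemia); HDL <40; LDL >=100; TSH
#' <4.2; PTT <30 vs >=30; HbA1c >=6.5 (diabetes).
#'
#' @return Named list of rules; each rule has `breaks`, `closed`
#'   (`"left"`: boundary goes to the upper band; `"right"`: boundary stays
#'   in the lower band) and band `labels`. The hemoglobin rule is
#'   sex-specific, with `female` and `male` sub-rules.
#' @export
discretization_rules <- function() {
  two <- function(cut, lab_lo, lab_hi)
    list(breaks = cut, closed = "left", labels = c(lab_lo, lab_hi))
  list(
    ef       = two(40,  "<40",  ">=40"),
    nihss    = two(6,   "<6",   ">=6"),
    sodium   = two(136, "<136", ">=136"),
    bun      = two(24,  "<24",  ">=24"),
    alt      = two(36,  "<36",  ">=36"),
    ast      = two(36,  "<36",  ">=36"),
    wbc      = two(11,  "<11",  ">=11"),
    hct      = list(breaks = c(35, 46), closed = c("left", "left"),
                    labels = c("<35", "35-45", ">=46")),
    hgb_sex  = list(sex_specific = TRUE,
                    female = list(breaks = c(11.7, 15.5), closed = c("left", "right"),
                                  labels = c("<11.7", "11.7-15.5", ">15.5")),
                    male   = list(breaks = c(13.2, 17.1), closed = c("left", "right"),
                                  labels = c("<13.2", "13.2-17.1", ">17.1"))),
    tg       = two(200, "<200", ">=200"),
    hdl      = two(40,  "<40",  ">=40"),
    ldl      = two(100, "<100", ">=100"),
    tsh      = two(4.2, "<4.2", ">=4.2"),
    ptt      = two(30,  "<30",  ">=30"),
    hba1c    = two(6.5, "<6.5", ">=6.5")
  )
}

# band index (0-based) for a simple (non sex-specific) rule; NA passes through
.apply_bands <- function(x, rule) {
  band <- rep_len(0, length(x))
  for (i in seq_along(rule$breaks)) {
    b <- rule$breaks[i]
    up <- if (rule$closed[min(i, length(rule$closed))] == "left") x >= b else x > b
    band <- band + as.numeric(up)
  }
  band[is.na(x)] <- NA_real_
  band
}

#' Discretize continuous clinical features into bands
#'
#' Replaces each continuous feature that carries a discretization rule id
#' with a categorical band variable (0-based band codes, lowest band 0)
#' named with a `"d"` suffix. Missing values remain missing. Already
#' discretized matrices pass through unchanged, so the operation is
#' idempotent.
#'
#' @param m A `feature_matrix`.
#' @param rules Rule registry; default [discretization_rules()].
#' @param sex Optional per-sample sex vector (`"female"`/`"male"`) for the
#'   sex-specific hemoglobin rule; required only when that rule is used.
#' @return A `feature_matrix` with discretized bands in place of the
#'   targeted continuous features.
#' @export
discretize_features <- function(m, rules = discretization_rules(), sex = NULL) {
  d <- m$descriptors
  v <- m$values
  targets <- which(!is.na(d$discretization_rule) & !d$discretized)
  for (j in targets) {
    rid <- d$discretization_rule[j]
    rule <- rules[[rid]]
    if (is.null(rule)) stop("unknown discretization rule id: ", rid)
    if (d$kind[j] != "continuous")
      stop("rule '", rid, "' targets non-continuous feature '", d$name[j], "'")
    if (isTRUE(rule$sex_specific)) {
      if (is.null(sex)) stop("rule '", rid, "' needs per-sample sex")
      sx <- as.character(sex)
      out <- rep(NA_real_, nrow(v))
      f <- sx == "female"
      out[f]  <- .apply_bands(v[f, j], rule$female)
      out[!f] <- .apply_bands(v[!f, j], rule$male)
      labs <- rule$female$labels
    } else {
      out <- .apply_bands(v[, j], rule)
      labs <- rule$labels
    }
    v[, j] <- out
    d$name[j] <- paste0(d$name[j], "d")
    d$kind[j] <- if (length(labs) == 2L) "binary" else "categorical"
    d$unit[j] <- paste(labs, collapse = "|")
    d$discretized[j] <- TRUE
  }
  colnames(v) <- d$name
  feature_matrix(v, d, m$sample_ids)
}

#' Default discretization rule id for a feature name
#'
#' Matches canonical clinical feature names (case-insensitive) to rule ids
#' in [discretization_rules()]; returns `NA` for names with no rule.
#'
#' @param name Character vector of feature names.
#' @return Character vector of rule ids or `NA`.
#' @export
default_rule_for <- function(name) {
  key <- tolower(name)
  map <- c(ejection_fraction = "ef", nihss = "nihss", sodium = "sodium",
           bun = "bun", alt = "alt", ast = "ast", wbc = "wbc",
           hematocrit = "hct", hemoglobin = "hgb_sex", triglyceride = "tg",
           hdl = "hdl", ldl = "ldl", tsh = "tsh", ptt = "ptt",
           hba1c = "hba1c")
  out <- unname(map[key])
  out[is.na(out)] <- NA_character_
  out
}
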
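#' Fixed order of the nine consensus sources
#'
#' The five base probability sources (tuned logistic regression, tuned
#' SVC with sigmoid calibration, the margin-normalized SVC2 calibration,
#' tuned random forest, tuned gradient boosting) followed by the four
#' summary-statistic ensembles.
#'
#' @return Character vector of nine source names.
#' @export
ensemble_sources <- function() {
  c("LR", "SVC", "SVC2", "RF", "XGB", "MAX", "MIN", "MEAN", "MEDIAN")
}

#' Summary-statistic probability ensemble
#'
#' For each sample, takes the chosen statistic of the base models'
#' probabilities class by class, then renormalizes across the four
#' classes so every row sums to 1. The minimum ensemble is computed
#' symmetrically with the maximum (per-class minimum, then normalize).
#'
#' @param probs_list List of two or more aligned probability matrices
#'   (identical dimensions and class order).
#' @param stat `"mean"`, `"median"`, `"max"` or `"min"`.
#' @return A probability matrix.
#' @export
summary_ensemble <- function(probs_list, stat = c("mean", "median", "max", "min")) {
  stat <- match.arg(stat)
  if (length(probs_list) < 2L) stop("need at least 2 probability sources")
  dims <- lapply(probs_list, dim)
  cls <- lapply(probs_list, colnames)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L ||
      length(unique(vapply(cls, paste, character(1), collapse = "|"))) != 1L)
    stop("probability sources are misaligned")
  arr <- simplify2array(probs_list)          # n x K x B
  fn <- switch(stat, mean = mean, median = stats::median, max = max, min = min)
  agg <- apply(arr, c(1, 2), fn)
  sums <- rowSums(agg)
  sums[sums == 0] <- 1
  out <- agg / sums
  dimnames(out) <- dimnames(probs_list[[1]])
  out
}

#' Majority-vote consensus over the nine classifiers
#'
#' Each of the nine sources votes for its highest-probability class; the
#' per-class support is the number of votes received, and the winner is
#' the class with maximal support. Support ties are broken by the fixed
#' class order (1 < 2 < 3 < 4) and flagged, so downstream consumers (the
#' certainty heuristic abstains on ties; evaluation keeps the
#' deterministic winner) can apply their own tie policy.
#'
#' @param probs_list Named list of exactly nine aligned probability
#'   matrices in [ensemble_sources()] order.
#' @return An object of class `consensus_result` with `votes` (samples x
#'   9 source labels), `supports` (samples x classes vote counts, rows
#'   summing to 9), `winner`, `winner_supports` and `tie`.
#' @export
consensus_predict <- function(probs_list) {
  if (length(probs_list) != 9L) stop("consensus needs exactly 9 sources")
  cls <- colnames(probs_list[[1]])
  n <- nrow(probs_list[[1]])
  for (p in probs_list)
    if (!identical(dim(p), c(n, length(cls))) || !identical(colnames(p), cls))
      stop("probability sources are misaligned")
  if (is.null(names(probs_list))) names(probs_list) <- ensemble_sources()
  votes <- vapply(probs_list, function(p) cls[max.col(p, ties.method = "first")],
                  character(n))
  if (n == 1L) votes <- matrix(votes, nrow = 1L, dimnames = list(NULL, names(probs_list)))
  supports <- t(apply(votes, 1, function(v) tabulate(factor(v, levels = cls),
                                                     nbins = length(cls))))
  colnames(supports) <- cls
  winner_idx <- max.col(supports, ties.method = "first")
  winner_supports <- supports[cbind(seq_len(n), winner_idx)]
  tie <- rowSums(supports == winner_supports) > 1L
  structure(list(votes = votes,
                 supports = supports,
                 winner = factor(cls[winner_idx], levels = cls),
                 winner_supports = as.numeric(winner_supports),
                 tie = tie,
                 sample_ids = rownames(probs_list[[1]])),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result:", length(x$winner), "samples\n")
  print(table(winner = x$winner))
  cat("unanimous (9/9):", sum(x$winner_supports == 9), "; ties:", sum(x$tie), "\n")
  invisible(x)
}

#' Support distribution of a consensus result
#'
#' Bar plot of winning-support counts per predicted class; the visual
#' companion to threshold calibration.
#'
#' @param x A `consensus_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.consensus_result <- function(x, ...) {
  tab <- table(class = x$winner, supports = factor(x$winner_supports, levels = 1:9))
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    xlab = "winning supports (of 9)", ylab = "samples", ...)
  invisible(x)
}

#' Derive per-class support thresholds for the certainty heuristic
#'
#' For each class, the threshold is a quantile (default the first
#' quartile) of the winning supports among calibration samples predicted
#' into that class, using the linear-interpolation quantile convention —
#' which is why thresholds can be fractional (e.g. 7.2) even though
#' supports are integers. A class that received no calibration
#' predictions falls back to the maximal threshold of 9 with a warning.
#'
#' @param calibration A `consensus_result` on a calibration cohort
#'   (typically external validation data).
#' @param quantile Quantile in (0, 1); default 0.25.
#' @return Object of class `support_thresholds`: named numeric vector of
#'   per-class minimum supports in \[0, 9\].
#' @export
derive_support_thresholds <- function(calibration, quantile = 0.25) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be inside (0, 1)")
  cls <- levels(calibration$winner)
  thr <- vapply(cls, function(cl) {
    vals <- calibration$winner_supports[calibration$winner == cl]
    if (!length(vals)) {
      warning("no calibration samples predicted into class ", cl,
              "; threshold falls back to 9")
      return(9)
    }
    unname(stats::quantile(vals, probs = quantile, type = 7))
  }, numeric(1))
  structure(thr, quantile = quantile, class = "support_thresholds")
}

#' @export
print.support_thresholds <- function(x, ...) {
  cat("support thresholds (quantile", attr(x, "quantile"), "):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Published first-quartile support thresholds
#'
#' The reference thresholds derived from the external validation cohort
#' of the original study: 7 supports for class 1, 9 for class 2, 7.2 for
#' class 3 and 7 for class 4. Useful for worked examples; new analyses
#' should calibrate their own thresholds with
#' [derive_support_thresholds()].
#'
#' @return A `support_thresholds` object.
#' @export
reference_thresholds <- function() {
  structure(c("1" = 7, "2" = 9, "3" = 7.2, "4" = 7),
            quantile = 0.25, class = "support_thresholds")
}

#' Apply the certainty heuristic
#'
#' A sample is assigned its consensus winner when the winning support
#' reaches the winner's class threshold; otherwise — including when two
#' classes tie for the vote — the sample is labelled persistently
#' cryptogenic.
#'
#' @param result A `consensus_result`.
#' @param thresholds A `support_thresholds` covering all four classes.
#' @return Factor with levels `c("1","2","3","4",
#'   "persistently_cryptogenic")`.
#' @export
apply_certainty_heuristic <- function(result, thresholds) {
  cls <- levels(result$winner)
  if (!all(cls %in% names(thresholds)))
    stop("thresholds must cover all classes")
  ok <- !result$tie &
    result$winner_supports >= unname(thresholds[as.character(result$winner)])
  out <- ifelse(ok, as.character(result$winner), cryptogenic_label())
  factor(out, levels = c(cls, cryptogenic_label()))
}

#' Summarize a heuristic application over one or more cohorts
#'
#' Tabulates assigned etiologies among cryptogenic inputs per cohort and
#' merged, with percentages to one decimal, and reports the
#' persistently-cryptogenic share among cryptogenic inputs and — when the
#' full cohort size (cryptogenic plus non-cryptogenic) is given — the
#' cryptogenic rate of the full cohort before and after reclassification.
#'
#' @param labels Factor of heuristic labels for the cryptogenic inputs.
#' @param cohort Optional cohort id per sample; merged totals are always
#'   reported.
#' @param full_cohort_size Optional total number of patients in the full
#'   cohort.
#' @return List of class `heuristic_summary` with `table` (counts and
#'   percentages per cohort and merged), `persistent_pct` (share of
#'   cryptogenic inputs remaining cryptogenic) and, when available,
#'   `full_cohort_pct_before` / `full_cohort_pct_after`.
#' @export
summarize_application <- function(labels, cohort = NULL,
                                  full_cohort_size = NULL) {
  if (!length(labels)) stop("labels must be non-empty")
  labels <- as.character(labels)
  lv <- c(core_classes(), cryptogenic_label())
  pct1 <- function(num, den) round(100 * num / den, 1)
  groups <- if (is.null(cohort)) list(merged = seq_along(labels)) else {
    g <- split(seq_along(labels), cohort)
    g$merged <- seq_along(labels)
    g
  }
  tab <- do.call(rbind, lapply(names(groups), function(gn) {
    idx <- groups[[gn]]
    counts <- table(factor(labels[idx], levels = lv))
    data.frame(cohort = gn, class = lv, count = as.integer(counts),
               pct = pct1(as.integer(counts), length(idx)),
               stringsAsFactors = FALSE)
  }))
  n_total <- length(labels)
  n_persistent <- sum(labels == cryptogenic_label())
  out <- list(table = tab,
              n_cryptogenic = n_total,
              n_persistent = n_persistent,
              persistent_pct = pct1(n_persistent, n_total))
  if (!is.null(full_cohort_size)) {
    out$full_cohort_size <- full_cohort_size
    out$full_cohort_pct_before <- pct1(n_total, full_cohort_size)
    out$full_cohort_pct_after <- pct1(n_persistent, full_cohort_size)
  }
  class(out) <- "heuristic_summary"
  out
}

#' @export
print.heuristic_summary <- function(x, ...) {
  cat("certainty-heuristic application:", x$n_cryptogenic,
      "cryptogenic inputs\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("persistently cryptogenic: %d (%.1f%%)\n",
              x$n_persistent, x$persistent_pct))
  if (!is.null(x$full_cohort_size))
    cat(sprintf("full-cohort cryptogenic rate: %.1f%% -> %.1f%% (N = %d)\n",
                x$full_cohort_pct_before, x$full_cohort_pct_after,
                x$full_cohort_size))
  invisible(x)
}
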
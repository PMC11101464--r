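#' Stratified cross-validation plan
#'
#' Builds the ordered train/validation splits used for model selection
#' and evaluation. Two schemes are supported:
#'
#' * `"shuffle-split"` — the grid-search scheme: `n_splits` independent
#'   stratified shuffles, each holding out `val_frac` of every class
#'   (default 5 splits of 20% validation sets, seed 1701).
#' * `"repeated-kfold"` — repeated stratified k-fold; see
#'   [build_rmfcv_plan()] for the standard 300-split composition.
#'
#' @param labels Class labels (values in the core set).
#' @param scheme `"shuffle-split"` or `"repeated-kfold"`.
#' @param n_splits Number of shuffle splits.
#' @param val_frac Validation fraction per split.
#' @param folds,repeats k and repetition count for repeated k-fold.
#' @param seed Integer seed; plans are deterministic given the seed.
#' @return An object of class `cv_plan`: list of `splits`, each with
#'   integer `train` and `validation` indices.
#' @export
make_cv_plan <- function(labels, scheme = c("shuffle-split", "repeated-kfold"),
                         n_splits = 5L, val_frac = 0.2, folds = 5L,
                         repeats = 1L, seed = 1701L) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  splits <- list()
  if (scheme == "shuffle-split") {
    if (any(tab < 2L))
      stop("class too small for stratified shuffle-split: ",
           names(tab)[which(tab < 2L)[1]])
    set.seed(seed)
    for (s in seq_len(n_splits)) {
      val <- integer()
      for (cl in names(tab)) {
        idx <- which(labels == cl)
        n_val <- max(1L, round(val_frac * length(idx)))
        val <- c(val, sample(idx, n_val))
      }
      val <- sort(val)
      splits[[s]] <- list(train = setdiff(seq_along(labels), val),
                          validation = val)
    }
  } else {
    if (any(tab < folds))
      stop("class too small for ", folds, "-fold CV: ",
           names(tab)[which(tab < folds)[1]])
    for (r in seq_len(repeats)) {
      set.seed(seed + r)
      fold_of <- integer(length(labels))
      for (cl in names(tab)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      for (f in seq_len(folds)) {
        val <- which(fold_of == f)
        splits[[length(splits) + 1L]] <-
          list(train = which(fold_of != f), validation = val)
      }
    }
  }
  structure(list(splits = splits, scheme = scheme, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan:", length(x$splits), "splits (", x$scheme, ", seed", x$seed, ")\n")
  invisible(x)
}

#' @export
length.cv_plan <- function(x) length(x$splits)

#' Specification of the repeated multi-fold CV composition
#'
#' The default composition is 2-, 3-, 4-, 5- and 10-fold CV with 30, 20,
#' 15, 12 and 6 repetitions respectively: 60 splits per fold count, 300
#' train/validation splits in total (RMFCV300).
#'
#' @param folds_reps Named integer vector mapping fold count to
#'   repetition count.
#' @param seed Base seed; each repetition r (counted across the whole
#'   composition) uses seed `seed + r`.
#' @return List of class `rmfcv_spec`.
#' @export
rmfcv_spec <- function(folds_reps = c("2" = 30L, "3" = 20L, "4" = 15L,
                                      "5" = 12L, "10" = 6L),
                       seed = 1701L) {
  structure(list(folds_reps = folds_reps, seed = as.integer(seed)),
            class = "rmfcv_spec")
}

#' Build the repeated multi-fold CV plan
#'
#' Concatenates stratified repeated k-fold splits in the declared fold
#' order. Per-repetition seeds are derived deterministically from the
#' base seed via a global repetition counter, so the full plan is
#' reproducible.
#'
#' @param spec An [rmfcv_spec()].
#' @param labels Class labels.
#' @return A `cv_plan` whose split count is `sum(folds * reps)` (300 for
#'   the default composition).
#' @export
build_rmfcv_plan <- function(spec = rmfcv_spec(), labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  kmax <- max(as.integer(names(spec$folds_reps)))
  if (any(tab < kmax))
    stop("class too small for ", kmax, "-fold CV: ",
         names(tab)[which(tab < kmax)[1]])
  splits <- list()
  rep_counter <- 0L
  for (kc in names(spec$folds_reps)) {
    k <- as.integer(kc)
    for (r in seq_len(spec$folds_reps[[kc]])) {
      rep_counter <- rep_counter + 1L
      sub <- make_cv_plan(labels, "repeated-kfold", folds = k, repeats = 1L,
                          seed = spec$seed + rep_counter - 1L)
      splits <- c(splits, sub$splits)
    }
  }
  structure(list(splits = splits, scheme = "repeated-kfold",
                 seed = spec$seed, spec = spec),
            class = "cv_plan")
}
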
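two_sources <- function() {
  list(prob_row(0.7, 0.1, 0.1, 0.1), prob_row(0.1, 0.7, 0.1, 0.1))
}

test_that("summary ensembles compute the printed arithmetic", {
  s <- two_sources()
  expect_equal(summary_ensemble(s, "mean")[1, ],
               c("1" = 0.4, "2" = 0.4, "3" = 0.1, "4" = 0.1))
  expect_equal(summary_ensemble(s, "max")[1, ],
               c("1" = 0.4375, "2" = 0.4375, "3" = 0.0625, "4" = 0.0625))
  expect_equal(summary_ensemble(s, "min")[1, ],
               c("1" = 0.25, "2" = 0.25, "3" = 0.25, "4" = 0.25))
})

test_that("ensemble rows normalize to 1 and agree at the fixed point", {
  set.seed(6)
  sources <- lapply(1:5, function(i) {
    p <- matrix(runif(200), 50, 4, dimnames = list(NULL, core_classes()))
    p / rowSums(p)
  })
  for (stat in c("mean", "median", "max", "min")) {
    out <- summary_ensemble(sources, stat)
    expect_lt(max(abs(rowSums(out) - 1)), 1e-12)
  }
  same <- list(sources[[1]], sources[[1]], sources[[1]])
  for (stat in c("mean", "median", "max", "min"))
    expect_equal(summary_ensemble(same, stat), sources[[1]],
                 tolerance = 1e-12)
  expect_error(summary_ensemble(sources[1], "mean"), "at least 2")
  mis <- sources; colnames(mis[[2]]) <- c("2", "1", "3", "4")
  expect_error(summary_ensemble(mis, "mean"), "misaligned")
})

# nine one-hot sources voting for the given labels
vote_sources <- function(labels) {
  lapply(labels, function(l) {
    p <- prob_row(0.05, 0.05, 0.05, 0.05)
    p[1, as.character(l)] <- 0.85
    p
  })
}

test_that("consensus counts votes and breaks support ties by class order", {
  res <- consensus_predict(vote_sources(c(2, 2, 2, 2, 2, 1, 1, 3, 4)))
  expect_equal(as.character(res$winner), "2")
  expect_equal(res$supports[1, ], c("1" = 2, "2" = 5, "3" = 1, "4" = 1))
  expect_equal(res$winner_supports, 5)
  expect_false(res$tie)

  unan <- consensus_predict(vote_sources(rep(3, 9)))
  expect_equal(unan$winner_supports, 9)

  tied <- consensus_predict(vote_sources(c(1, 1, 1, 1, 2, 2, 2, 2, 3)))
  expect_true(tied$tie)
  expect_equal(as.character(tied$winner), "1")
  expect_error(consensus_predict(vote_sources(rep(1, 8))), "exactly 9")
})

test_that("supports always sum to 9 on random inputs", {
  set.seed(8)
  sources <- lapply(1:9, function(i) {
    p <- matrix(runif(320), 80, 4, dimnames = list(NULL, core_classes()))
    p / rowSums(p)
  })
  res <- consensus_predict(sources)
  expect_true(all(rowSums(res$supports) == 9))
  expect_equal(res$winner_supports,
               apply(res$supports, 1, max))
})

test_that("threshold derivation uses linear-interpolation quantiles", {
  fake <- structure(list(
    winner = factor(c(1, 1, 1, 1, 2, 3), levels = core_classes()),
    winner_supports = c(9, 9, 9, 5, 8, 7),
    tie = rep(FALSE, 6)), class = "consensus_result")
  thr <- suppressWarnings(derive_support_thresholds(fake, 0.25))
  # brute-force linear interpolation oracle: h = (n-1)p + 1 over sorted values
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(unname(thr["1"]), oracle_q(c(9, 9, 9, 5), 0.25))
  expect_equal(unname(thr["1"]), 8)
  expect_warning(thr4 <- derive_support_thresholds(fake, 0.5), "class 4")
  expect_equal(unname(thr4["4"]), 9)
  expect_error(derive_support_thresholds(fake, 0), "inside")

  unan <- structure(list(
    winner = factor(rep(1:4, each = 3), levels = core_classes()),
    winner_supports = rep(9, 12), tie = rep(FALSE, 12)),
    class = "consensus_result")
  expect_true(all(derive_support_thresholds(unan) == 9))
})

test_that("the certainty heuristic assigns or abstains per the thresholds", {
  thr <- reference_thresholds()
  res <- structure(list(
    winner = factor(c(3, 2, 1), levels = core_classes()),
    winner_supports = c(8, 8, 4),
    tie = c(FALSE, FALSE, TRUE)), class = "consensus_result")
  lab <- apply_certainty_heuristic(res, thr)
  expect_equal(as.character(lab),
               c("3", cryptogenic_label(), cryptogenic_label()))
  # 8 >= 7.2 assigns class 3; 8 < 9 abstains for class 2; ties abstain
})

test_that("no assignment ever undercuts its class threshold; monotone in thresholds", {
  set.seed(9)
  n <- 200
  supports <- t(vapply(seq_len(n), function(i) {
    v <- tabulate(sample(1:4, 9, replace = TRUE), 4)
    v
  }, numeric(4)))
  colnames(supports) <- core_classes()
  winner_idx <- max.col(supports, ties.method = "first")
  res <- structure(list(
    winner = factor(core_classes()[winner_idx], levels = core_classes()),
    winner_supports = supports[cbind(seq_len(n), winner_idx)],
    tie = rowSums(supports == supports[cbind(seq_len(n), winner_idx)]) > 1),
    class = "consensus_result")
  thr <- structure(c("1" = 5, "2" = 6, "3" = 5, "4" = 7),
                   quantile = 0.25, class = "support_thresholds")
  lab <- apply_certainty_heuristic(res, thr)
  assigned <- as.character(lab) != cryptogenic_label()
  expect_true(all(res$winner_supports[assigned] >=
                    unname(thr[as.character(lab[assigned])])))
  # raising any class threshold weakly increases abstentions
  for (cl in core_classes()) {
    thr_hi <- thr; thr_hi[cl] <- thr_hi[cl] + 2
    lab_hi <- apply_certainty_heuristic(res, thr_hi)
    expect_gte(sum(lab_hi == cryptogenic_label()),
               sum(lab == cryptogenic_label()))
  }
})

test_that("application summaries report one-decimal percentages", {
  lab <- c(rep("1", 3), rep(cryptogenic_label(), 1))
  s <- summarize_application(lab, full_cohort_size = 16)
  expect_equal(s$persistent_pct, 25)
  expect_equal(s$full_cohort_pct_before, 25)
  expect_equal(s$full_cohort_pct_after, 6.2)
  empty_persistent <- summarize_application(rep("2", 5))
  expect_equal(empty_persistent$persistent_pct, 0)
  expect_error(summarize_application(character()), "non-empty")
})
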
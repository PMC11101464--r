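# a factory ignoring its training data, always voting the given class
constant_factory <- function(cl) {
  function(x, y) {
    function(newx) {
      p <- matrix(0.01, nrow(newx), 4, dimnames = list(NULL, core_classes()))
      p[, cl] <- 0.97
      p / rowSums(p)
    }
  }
}

test_that("repeated CV of a constant predictor recovers the class prevalence", {
  y <- rep(core_classes(), times = c(40, 30, 20, 10))
  x <- matrix(rnorm(length(y) * 3), ncol = 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  plan <- build_rmfcv_plan(rmfcv_spec(folds_reps = c("2" = 3L, "5" = 2L)), y)
  out <- run_rmfcv(constant_factory("1"), x, y, plan)
  expect_equal(out$failed, 0)
  expect_equal(nrow(out$per_split), length(plan$splits))
  acc <- out$summary$mean[out$summary$metric == "accuracy"]
  expect_lt(abs(acc - 0.4), 0.02)  # stratified folds pin the prevalence
  # determinism under the same plan
  out2 <- run_rmfcv(constant_factory("1"), x, y, plan)
  expect_identical(out$summary, out2$summary)
})

test_that("failing splits are excluded and counted", {
  y <- rep(core_classes(), each = 10)
  x <- matrix(rnorm(length(y) * 2), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  plan <- build_rmfcv_plan(rmfcv_spec(folds_reps = c("2" = 2L)), y)
  flaky <- local({
    calls <- 0L
    function(xtr, ytr) {
      calls <<- calls + 1L
      if (calls == 2L) stop("synthetic failure")
      constant_factory("2")(xtr, ytr)
    }
  })
  out <- run_rmfcv(flaky, x, y, plan)
  expect_equal(out$failed, 1)
  expect_equal(nrow(out$per_split), length(plan$splits) - 1)
})

test_that("subgroup panels respect the strata and recover planted effects", {
  set.seed(14)
  n <- 400
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- runif(n, 40, 90)
  y <- sample(core_classes(), n, replace = TRUE)
  # class-3 signal exists only in females: males get class 3 wrong
  pred <- y
  male3 <- sex == "male" & y == "3"
  pred[male3] <- sample(c("1", "2", "4"), sum(male3), replace = TRUE)
  cohort <- cohort_table(paste0("s", 1:n), "siteA", 2018, age, sex,
                         "White", as.integer(y))
  predictions <- data.frame(split = 1L, sample = 1:n, y_true = y,
                            y_pred = pred, stringsAsFactors = FALSE)
  pan <- stratified_performance(predictions, cohort,
                                strata = c("sex", "age65"))
  f_f1 <- pan$mean[pan$stratum == "sex:female" & pan$class == "3" &
                     pan$metric == "f1"]
  m_f1 <- pan$mean[pan$stratum == "sex:male" & pan$class == "3" &
                     pan$metric == "f1"]
  expect_gt(f_f1, m_f1)
  expect_equal(f_f1, 1)
  # sex strata sizes partition the cohort
  sizes <- pan$mean_size[pan$class == "1" & pan$metric == "accuracy" &
                           startsWith(pan$stratum, "sex:")]
  expect_equal(sum(sizes), n)
})

test_that("misclassification rankings count feature presence correctly", {
  desc <- feature_descriptors(c("A", "B"), c("CUI", "CUI"), "binary")
  v <- cbind(A = c(1, 1, 1, 0, 0), B = c(0, 1, 0, 1, 0))
  m <- feature_matrix(v, desc)
  y <- c("1", "1", "1", "1", "2")
  pred <- c("2", "2", "2", "1", "2")   # 3 misclassified class-1 samples, all with A
  out <- misclassification_features(y, pred, m, top_k = 2)
  expect_equal(out[["1"]]$ranking$feature[1], "A")
  expect_equal(out[["1"]]$ranking$frequency[1], 1)
  expect_equal(out[["1"]]$error_rate, 0.75)
  expect_true(all(diff(out[["1"]]$ranking$frequency) <= 0))
  # perfect predictions leave every ranking empty
  perf <- misclassification_features(y, y, m)
  expect_equal(nrow(perf[["1"]]$ranking), 0)
})

test_that("signature extraction selects high-prevalence class-specific features", {
  set.seed(15)
  n <- 200
  lab <- rep(core_classes(), each = 50)
  v <- cbind(marker = as.numeric(lab == "4"),
             exactly_half = rep(c(1, 0), n / 2))
  m <- feature_matrix(v, feature_descriptors(colnames(v), "CUI", "binary"))
  sig <- signature_features(lab, m, 0.5)
  expect_true("marker" %in% sig$feature)
  expect_lt(sig$p_value[sig$feature == "marker"], 1e-10)
  # present in exactly 50% of every class: fails the strict cut
  expect_false("exactly_half" %in% sig$feature)
  # persistent-cryptogenic samples are excluded before testing
  lab2 <- c(rep(cryptogenic_label(), 100), rep(c("1", "2"), each = 50))
  sig2 <- signature_features(lab2, m, 0.5)
  expect_true(is.data.frame(sig2))
})

test_that("univariate importance tests flag planted shifts", {
  set.seed(16)
  n <- 400
  y <- rep(core_classes(), each = 100)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("shifted", "noise",
                                                          "constant")))
  x[y == "2", "shifted"] <- x[y == "2", "shifted"] + 3
  x[, "constant"] <- 1
  out <- feature_importance_tests(x, y)
  hit <- out[out$feature == "shifted" & out$class == "2", ]
  expect_lt(hit$ks_p, 1e-6)
  expect_lt(hit$t_p, 1e-6)
  expect_true(all(out$ks_D >= 0 & out$ks_D <= 1, na.rm = TRUE))
  const <- out[out$feature == "constant" & out$class == "2", ]
  expect_equal(const$ks_D, 0)
  expect_true(is.na(const$t_stat))
})

test_that("longitudinal splits cut strictly at the test year", {
  ct <- cohort_table(paste0("s", 1:12), "siteA", rep(2015:2020, each = 2),
                     70, "female", "White", 1)
  sp <- longitudinal_split(ct, 2020)
  expect_equal(sp$test, c(11, 12))
  expect_equal(sp$train, 1:10)
  expect_setequal(c(sp$train, sp$test),
                  which(ct$admission_year <= 2020))
  expect_error(longitudinal_split(ct, 2014), "no samples")
})
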
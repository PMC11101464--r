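test_that("a fully observed matrix passes through unchanged", {
  sim <- generate_cohort(small_sim(missingness = 0))
  out <- impute_features(sim$features, seed = 1)
  expect_identical(out$features$values, sim$features$values)
  expect_length(out$dropped, 0)
})

test_that("a single observed donor value is the only possible imputation", {
  desc <- feature_descriptors(c("target", "aux"), c("LAB", "LAB"),
                              c("continuous", "continuous"))
  v <- cbind(target = c(2, NA, 2, 2), aux = c(1, 2, 1.5, 1.2))
  m <- feature_matrix(v, desc)
  out <- impute_features(m, seed = 4)
  expect_equal(unname(out$features$values[2, "target"]), 2)
  expect_false(any(out$features$missing_mask))
})

test_that("observed cells survive bit-exactly and pmm stays in the support", {
  sim <- generate_cohort(small_sim(n_per_class = rep(60L, 4),
                                   missingness = 0.3, seed = 21L))
  out <- impute_features(sim$features, seed = 2)
  obs <- !sim$features$missing_mask
  common <- colnames(out$features$values)
  expect_identical(out$features$values[, common][obs[, common]],
                   sim$features$values[, common][obs[, common]])
  expect_false(any(out$features$missing_mask))
  # pmm imputations are drawn from each feature's observed support
  for (j in common) {
    support <- unique(sim$features$values[obs[, j], j])
    expect_true(all(out$features$values[, j] %in% support))
  }
})

test_that("imputation is deterministic given the seed", {
  sim <- generate_cohort(small_sim(missingness = 0.3, seed = 21L))
  a <- impute_features(sim$features, seed = 5)
  b <- impute_features(sim$features, seed = 5)
  expect_identical(a$features$values, b$features$values)
})

test_that("pmm recovers the marginal mean under MCAR on a bivariate Gaussian", {
  # Monte-Carlo oracle: with rho = 0.9 and 20% MCAR, the imputed-column
  # mean stays within 3 standard errors of the observed-column mean
  errs <- vapply(1:5, function(r) {
    set.seed(100 + r)
    n <- 500
    z <- matrix(rnorm(2 * n), n)
    x1 <- z[, 1]
    x2 <- 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2]
    drop <- runif(n) < 0.2
    v <- cbind(a = ifelse(drop, NA, x1), b = x2)
    m <- feature_matrix(v, feature_descriptors(c("a", "b"), "LAB",
                                               "continuous"))
    out <- impute_features(m, seed = r)
    mean(out$features$values[, "a"]) - mean(x1[!drop])
  }, numeric(1))
  se <- 1 / sqrt(500)
  expect_true(all(abs(errs) < 3 * se))
})

test_that("unimputable features are dropped and reported", {
  desc <- feature_descriptors(c("empty", "ok"), c("LAB", "LAB"),
                              c("continuous", "continuous"))
  v <- cbind(empty = c(NA_real_, NA, NA), ok = c(1, 2, NA))
  m <- feature_matrix(v, desc)
  out <- impute_features(m, seed = 1)
  expect_identical(out$dropped, "empty")
  expect_identical(colnames(out$features$values), "ok")

  allna <- feature_matrix(
    matrix(NA_real_, 2, 1, dimnames = list(NULL, "x")),
    feature_descriptors("x", "LAB", "continuous"))
  expect_error(impute_features(allna, seed = 1), "all features dropped")
})

test_that("forest and sample strategies complete the matrix too", {
  sim <- generate_cohort(small_sim(n_per_class = rep(30L, 4),
                                   missingness = 0.3, seed = 8L))
  for (method in c("forest", "sample")) {
    out <- impute_features(sim$features, method = method, n_iterations = 2,
                           seed = 3)
    expect_false(any(out$features$missing_mask))
    obs <- !sim$features$missing_mask
    common <- colnames(out$features$values)
    expect_identical(out$features$values[, common][obs[, common]],
                     sim$features$values[, common][obs[, common]])
  }
})
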
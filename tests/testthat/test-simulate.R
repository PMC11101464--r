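test_that("binary features follow their class-conditional prevalences", {
  cfg <- small_sim(n_per_class = rep(200L, 4), missingness = 0, seed = 11L)
  sim <- generate_cohort(cfg)
  af <- sim$features$values[, "Atrial_fibrillation"]
  cls <- sim$cohort$toast
  spec <- cfg$binary_features
  p2 <- spec$prev2[spec$name == "Atrial_fibrillation"]
  # empirical prevalence within 3 binomial SDs of the configured value
  sd2 <- sqrt(p2 * (1 - p2) / 200)
  expect_lt(abs(mean(af[cls == 2]) - p2), 3 * sd2)
  p1 <- spec$prev1[spec$name == "Atrial_fibrillation"]
  sd1 <- sqrt(p1 * (1 - p1) / 200)
  expect_lt(abs(mean(af[cls == 1]) - p1), 3 * sd1)
})

test_that("zero missingness gives an all-false mask; rates are respected", {
  sim0 <- generate_cohort(small_sim(missingness = 0))
  expect_false(any(sim0$features$missing_mask))
  sim3 <- generate_cohort(small_sim(n_per_class = rep(150L, 4),
                                    missingness = 0.3, seed = 5L))
  rate <- mean(sim3$features$missing_mask)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / length(sim3$features$missing_mask)))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_cohort(small_sim(seed = 42L))
  b <- generate_cohort(small_sim(seed = 42L))
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$cohort, b$cohort)
  c1 <- generate_cryptogenic_mixture(small_sim(seed = 42L))
  c2 <- generate_cryptogenic_mixture(small_sim(seed = 42L))
  expect_identical(c1$features$values, c2$features$values)
  expect_identical(c1$cohort$latent_class, c2$cohort$latent_class)
})

test_that("cryptogenic mixture draws latent classes from the weights", {
  cfg <- cohort_sim_config(n_cryptogenic = 400L,
                           mixture_weights = c(1, 0, 0, 0), seed = 3L)
  cry <- generate_cryptogenic_mixture(cfg)
  expect_true(all(cry$cohort$latent_class == 1L))
  expect_true(all(cry$cohort$toast == 5L))

  cfg_u <- cohort_sim_config(n_cryptogenic = 400L, seed = 3L)
  cry_u <- generate_cryptogenic_mixture(cfg_u)
  counts <- table(factor(cry_u$cohort$latent_class, levels = 1:4))
  # each within 3 multinomial SDs of 100
  expect_true(all(abs(counts - 100) < 3 * sqrt(400 * 0.25 * 0.75)))
})

test_that("exported tables never leak the latent class", {
  cry <- generate_cryptogenic_mixture(small_sim(seed = 9L))
  fpath <- withr::local_tempfile(fileext = ".csv")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(cry$features, fpath)
  write_cohort_table(cry$cohort, cpath)
  expect_false(any(grepl("latent", readLines(fpath, n = 1), ignore.case = TRUE)))
  expect_false(any(grepl("latent", readLines(cpath, n = 1), ignore.case = TRUE)))
})

test_that("degenerate configurations are rejected", {
  expect_error(generate_cohort(cohort_sim_config(n_per_class = rep(0L, 4))),
               "degenerate")
  expect_error(cohort_sim_config(mixture_weights = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(cohort_sim_config(missingness = c(CUI = 1.2, RAD = 0, HRT = 0,
                                                 HEX = 0, LAB = 0)),
               "missingness")
})

test_that("site-conditioned missingness raises rates only at the affected site", {
  cfg <- small_sim(n_per_class = rep(150L, 4), missingness = 0.2, seed = 13L)
  cfg$mar_cohort_effect <- 2
  sim <- generate_cohort(cfg)
  ra <- mean(sim$features$missing_mask[sim$cohort$cohort == "siteA", ])
  rb <- mean(sim$features$missing_mask[sim$cohort$cohort == "siteB", ])
  expect_lt(abs(ra - 0.2), 0.03)
  expect_lt(abs(rb - 0.4), 0.03)
})
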
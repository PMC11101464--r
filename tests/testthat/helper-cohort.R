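# shared fixtures: small synthetic cohorts and fast model parameters

small_sim <- function(n_per_class = rep(40L, 4), missingness = 0.3,
                      separation = "realistic", seed = 7L,
                      n_cryptogenic = 40L) {
  cohort_sim_config(
    n_per_class = n_per_class, n_cryptogenic = n_cryptogenic,
    missingness = c(CUI = missingness, RAD = missingness, HRT = missingness,
                    HEX = missingness, LAB = missingness),
    separation = separation, seed = seed)
}

# a complete, assembled design matrix + labels for model-level tests
prepared_cohort <- function(cfg = small_sim(missingness = 0)) {
  sim <- generate_cohort(cfg)
  d <- discretize_features(sim$features, sex = sim$cohort$sex)
  x <- assemble_feature_group(d, sim$cohort, "combn1d.age.sex.v1")
  list(x = x, y = as.character(sim$cohort$toast), cohort = sim$cohort,
       raw = sim$features)
}

# small, fast hyperparameters for tests that fit all four learners
fast_params <- function() {
  modifyList(tuned_parameters(), list(
    rf = list(n_estimators = 80, max_depth = 10, criterion = "gini",
              max_features = "sqrt"),
    xgb = list(n_estimators = 30, max_depth = 4, learning_rate = 0.3,
               gamma = 0, reg_lambda = 1, reg_alpha = 0, subsample = 1)))
}

# tiny hand-built feature matrix
toy_matrix <- function() {
  desc <- feature_descriptors(
    name = c("cui_a", "cui_b", "rad_a", "hrt_a", "hex_a", "lab_a"),
    category = c("CUI", "CUI", "RAD", "HRT", "HEX", "LAB"),
    kind = c("binary", "binary", "binary", "binary", "continuous",
             "continuous"))
  v <- rbind(c(1, 0, 1, 1, 5,  NA),
             c(0, 1, NA, NA, NA, NA),
             c(1, 1, 0, 1, 12, 140))
  colnames(v) <- desc$name
  feature_matrix(v, desc, c("a", "b", "c"))
}

# aligned probability matrices over the 4 core classes
prob_row <- function(...) {
  m <- matrix(c(...), nrow = 1)
  colnames(m) <- core_classes()
  m
}
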
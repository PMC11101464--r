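#' Default class-conditional binary feature specification
#'
#' Per-feature per-class prevalences for the simulated binary concept
#' (CUI), neuroimaging (RAD) and cardiac (HRT) features. The planted
#' class structure follows the clinically discriminative pattern the
#' method is designed to exploit: atrial fibrillation and cardiac thrombi
#' enriched in cardioembolism (class 2), carotid/MCA occlusion and
#' stenosis in large-artery atherosclerosis (class 1), basal-ganglia and
#' lacunar location in small-vessel disease (class 3), and thrombophilia,
#' PFO and malignancy in other determined etiology (class 4), against a
#' background of common vascular risk factors.
#'
#' @return `data.frame` with `name`, `category` and `prev1..prev4`.
#' @export
default_binary_spec <- function() {
  row <- function(name, cat, p1, p2, p3, p4)
    data.frame(name = name, category = cat, prev1 = p1, prev2 = p2,
               prev3 = p3, prev4 = p4, stringsAsFactors = FALSE)
  rbind(
    row("Atrial_fibrillation", "CUI", 0.10, 0.90, 0.08, 0.10),
    row("Hypertension",        "CUI", 0.85, 0.75, 0.90, 0.55),
    row("Hyperlipidemia",      "CUI", 0.55, 0.30, 0.35, 0.25),
    row("Diabetes",            "CUI", 0.45, 0.35, 0.55, 0.30),
    row("Coronary_artery_disease", "CUI", 0.35, 0.30, 0.20, 0.15),
    row("Thrombophilia",       "CUI", 0.02, 0.02, 0.02, 0.65),
    row("Malignancy",          "CUI", 0.05, 0.08, 0.03, 0.35),
    row("Tobacco_use",         "CUI", 0.45, 0.25, 0.35, 0.30),
    row("Endocarditis",        "CUI", 0.01, 0.10, 0.01, 0.20),
    row("Migraine",            "CUI", 0.08, 0.08, 0.10, 0.25),
    row("ICA_occlusion",       "RAD", 0.80, 0.15, 0.05, 0.10),
    row("MCA_occlusion",       "RAD", 0.55, 0.60, 0.05, 0.25),
    row("Carotid_stenosis",    "RAD", 0.75, 0.10, 0.08, 0.08),
    row("Basal_ganglia",       "RAD", 0.10, 0.10, 0.85, 0.10),
    row("Lacunar_infarct",     "RAD", 0.08, 0.05, 0.90, 0.10),
    row("Frontal",             "RAD", 0.40, 0.45, 0.05, 0.30),
    row("Cortical_infarct",    "RAD", 0.55, 0.65, 0.03, 0.35),
    row("Hemorrhagic_transformation", "RAD", 0.15, 0.25, 0.02, 0.10),
    row("Atrial_dilation",     "HRT", 0.15, 0.70, 0.10, 0.10),
    row("Intracardiac_thrombus", "HRT", 0.02, 0.40, 0.01, 0.05),
    row("Valve_vegetation",    "HRT", 0.01, 0.10, 0.01, 0.25),
    row("Patent_foramen_ovale", "HRT", 0.05, 0.10, 0.05, 0.45),
    row("Sinus_rhythm",        "HRT", 0.80, 0.25, 0.85, 0.75)
  )
}

#' Default class-conditional continuous feature specification
#'
#' Gaussian location/scale per class for the simulated vitals (HEX),
#' laboratory values (LAB) and ejection fraction (HRT). Locations are set
#' so that the clinical discretization rules are informative (e.g.
#' reduced ejection fraction in cardioembolism, higher HbA1c in
#' large-artery and small-vessel disease). Values are truncated at
#' clinically impossible negatives.
#'
#' @return `data.frame` with `name`, `category`, `mean1..mean4`, `sd` and
#'   the discretization `rule` id (or `NA`).
#' @export
default_continuous_spec <- function() {
  row <- function(name, cat, m1, m2, m3, m4, sd, rule = NA_character_)
    data.frame(name = name, category = cat, mean1 = m1, mean2 = m2,
               mean3 = m3, mean4 = m4, sd = sd, rule = rule,
               stringsAsFactors = FALSE)
  rbind(
    row("NIHSS",            "HEX", 9,   13,  3.5, 8,   4,   "nihss"),
    row("Systolic_BP",      "HEX", 155, 145, 168, 135, 18),
    row("Heart_Rate",       "HEX", 78,  96,  75,  82,  12),
    row("Ejection_fraction","HRT", 58,  41,  60,  55,  8,   "ef"),
    row("Sodium",           "LAB", 138, 137, 138, 135, 3,   "sodium"),
    row("BUN",              "LAB", 20,  25,  19,  17,  6,   "bun"),
    row("WBC",              "LAB", 9,   10,  8.5, 11.5, 2.5, "wbc"),
    row("Hematocrit",       "LAB", 41,  39,  42,  36,  4,   "hct"),
    row("Hemoglobin",       "LAB", 13.5, 13, 13.8, 11.8, 1.6, "hgb_sex"),
    row("Triglyceride",     "LAB", 185, 140, 165, 130, 50,  "tg"),
    row("HDL",              "LAB", 38,  48,  43,  50,  10,  "hdl"),
    row("LDL",              "LAB", 125, 95,  112, 100, 25,  "ldl"),
    row("TSH",              "LAB", 2.0, 2.4, 2.0, 2.6, 1.1, "tsh"),
    row("PTT",              "LAB", 29,  31,  29,  37,  5,   "ptt"),
    row("HbA1c",            "LAB", 7.0, 5.9, 6.8, 5.6, 1.0, "hba1c"),
    row("ALT",              "LAB", 30,  32,  29,  35,  12,  "alt"),
    row("AST",              "LAB", 30,  33,  29,  36,  12,  "ast")
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: four etiology
#' strata with class-conditional binary prevalences and continuous
#' locations, a cryptogenic stratum drawn as a mixture of the four
#' etiology models, per-category missing-completely-at-random rates, and
#' class-conditional age. Defaults: 200 samples per etiology class, 200
#' cryptogenic samples with a uniform latent mixture, and 30% per-category
#' missingness (far below the extreme categorical missingness of real
#' extracted EHR features, which is available via `missingness_preset =
#' "ehr"`, so that imputation behaviour stays testable).
#'
#' @param n_per_class Sample counts for classes 1-4.
#' @param n_cryptogenic Cryptogenic stratum size.
#' @param binary_features Binary spec, see [default_binary_spec()].
#' @param continuous_features Continuous spec, see
#'   [default_continuous_spec()].
#' @param age_mean,age_sd Per-class age location/scale in years.
#' @param missingness Named per-category MCAR cell rates in \[0, 1\].
#' @param missingness_preset `"default"` or `"ehr"` (0.919 for every
#'   category, the stress preset).
#' @param separation `"realistic"` (the default class overlap) or
#'   `"strong"`: a well-separated preset that doubles each binary
#'   prevalence on the logit scale and doubles each continuous
#'   class-mean contrast, the regime in which the full pipeline is
#'   expected to recover the planted classes almost perfectly
#'   (parameter-recovery testing).
#' @param mar_cohort_effect Optional multiplier applied to the
#'   missingness rates of cohort `"siteB"`, giving missingness at random
#'   conditioned on site; 1 = pure MCAR.
#' @param mixture_weights Length-4 simplex for the cryptogenic latent
#'   etiology mixture.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_per_class = c(200, 200, 200, 200),
                              n_cryptogenic = 200,
                              binary_features = default_binary_spec(),
                              continuous_features = default_continuous_spec(),
                              age_mean = c(68, 75, 66, 55),
                              age_sd = c(10, 9, 10, 12),
                              missingness = c(CUI = 0.3, RAD = 0.3, HRT = 0.3,
                                              HEX = 0.3, LAB = 0.3),
                              missingness_preset = c("default", "ehr"),
                              separation = c("realistic", "strong"),
                              mar_cohort_effect = 1,
                              mixture_weights = rep(0.25, 4),
                              seed = 1701L) {
  missingness_preset <- match.arg(missingness_preset)
  separation <- match.arg(separation)
  if (separation == "strong") {
    pv <- as.matrix(binary_features[, paste0("prev", 1:4)])
    pv <- stats::plogis(2 * stats::qlogis(pmin(pmax(pv, 0.01), 0.99)))
    binary_features[, paste0("prev", 1:4)] <- pv
    mm <- as.matrix(continuous_features[, paste0("mean", 1:4)])
    ctr <- rowMeans(mm)
    continuous_features[, paste0("mean", 1:4)] <- ctr + 2 * (mm - ctr)
  }
  if (missingness_preset == "ehr")
    missingness <- c(CUI = 0.919, RAD = 0.919, HRT = 0.919, HEX = 0.919,
                     LAB = 0.919)
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 0),
            n_cryptogenic >= 0, length(mixture_weights) == 4)
  prevs <- as.matrix(binary_features[, paste0("prev", 1:4)])
  if (any(prevs < 0 | prevs > 1)) stop("prevalences must be in [0, 1]")
  if (any(missingness < 0 | missingness > 1)) stop("missingness rates must be in [0, 1]")
  if (abs(sum(mixture_weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_cryptogenic = as.integer(n_cryptogenic),
                 binary_features = binary_features,
                 continuous_features = continuous_features,
                 age_mean = age_mean, age_sd = age_sd,
                 missingness = missingness,
                 mar_cohort_effect = mar_cohort_effect,
                 mixture_weights = mixture_weights,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# draw one stratum of samples whose latent etiology classes are `classes`
.draw_samples <- function(cfg, classes, id_prefix) {
  n <- length(classes)
  bs <- cfg$binary_features
  cs <- cfg$continuous_features
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  age <- stats::rnorm(n, cfg$age_mean[classes], cfg$age_sd[classes])
  age <- pmin(pmax(age, 20), 100)
  vb <- matrix(0, n, nrow(bs), dimnames = list(NULL, bs$name))
  prevs <- as.matrix(bs[, paste0("prev", 1:4)])
  for (j in seq_len(nrow(bs)))
    vb[, j] <- as.numeric(stats::runif(n) < prevs[j, classes])
  vc <- matrix(0, n, nrow(cs), dimnames = list(NULL, cs$name))
  means <- as.matrix(cs[, paste0("mean", 1:4)])
  for (j in seq_len(nrow(cs))) {
    x <- stats::rnorm(n, means[j, classes], cs$sd[j])
    if (cs$name[j] == "Hemoglobin") x <- x + ifelse(sex == "male", 1, 0)
    vc[, j] <- pmax(x, 0)
  }
  vals <- cbind(vb, vc)
  desc <- rbind(
    feature_descriptors(bs$name, bs$category, "binary"),
    feature_descriptors(cs$name, cs$category, "continuous",
                        discretization_rule = cs$rule)
  )
  cohort <- ifelse(stats::runif(n) < 0.5, "siteA", "siteB")
  # MCAR cell-wise missingness per category (site multiplier gives MAR)
  rates <- cfg$missingness[desc$category]
  rate_mat <- matrix(rates, n, ncol(vals), byrow = TRUE)
  rate_mat[cohort == "siteB", ] <- pmin(rate_mat[cohort == "siteB", ] *
                                          cfg$mar_cohort_effect, 1)
  vals[stats::runif(length(vals)) < rate_mat] <- NA_real_
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  ct <- cohort_table(sample_id = ids, cohort = cohort,
                     admission_year = sample(2015:2020, n, replace = TRUE),
                     age = age, sex = sex,
                     race = sample(c("White", "Black or African American",
                                     "Others"), n, replace = TRUE,
                                   prob = c(0.72, 0.14, 0.14)),
                     toast = classes)
  list(features = feature_matrix(vals, desc, ids), cohort = ct)
}

#' Generate a synthetic non-cryptogenic cohort
#'
#' Draws the four adjudicated etiology strata class-conditionally per the
#' configuration, then injects per-category missingness. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [cohort_sim_config()].
#' @return List with `features` (a `feature_matrix`) and `cohort` (a
#'   `cohort_table` with `toast` in 1-4).
#' @export
generate_cohort <- function(cfg) {
  if (sum(cfg$n_per_class) == 0) stop("degenerate config: all class counts are 0")
  set.seed(cfg$seed)
  classes <- rep(1:4, times = cfg$n_per_class)
  .draw_samples(cfg, classes, "syn")
}

#' Generate a synthetic cryptogenic stratum as an etiology mixture
#'
#' Each cryptogenic sample is drawn from one latent etiology's feature
#' model, the latent class being sampled from `cfg$mixture_weights`. The
#' adjudicated label is 5 (cryptogenic); the latent class is recorded in
#' the cohort table's `latent_class` column for recovery testing and is
#' never written to exported feature tables.
#'
#' @param cfg A [cohort_sim_config()].
#' @return List with `features` and `cohort` (`toast = 5`,
#'   `latent_class` in 1-4).
#' @export
generate_cryptogenic_mixture <- function(cfg) {
  if (cfg$n_cryptogenic == 0) stop("degenerate config: n_cryptogenic is 0")
  set.seed(cfg$seed + 1L)
  latent <- sample(1:4, cfg$n_cryptogenic, replace = TRUE,
                   prob = cfg$mixture_weights)
  out <- .draw_samples(cfg, latent, "cry")
  out$cohort$toast <- 5L
  out$cohort$latent_class <- as.integer(latent)
  out
}
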
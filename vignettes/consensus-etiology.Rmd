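---
title: "Consensus classification of stroke etiology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus classification of stroke etiology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeconsensus)
```

## The problem and the model

The etiology of an ischemic stroke is recorded with the TOAST scheme:
1 large-artery atherosclerosis, 2 cardioembolism, 3 small-vessel
disease, 4 other determined, 5 undetermined (cryptogenic). The package
treats etiology prediction as 4-class supervised classification on
EHR-derived tabular features and layers two ideas on top of the base
learners:

1. **Summary-statistic ensembling.** Five probability sources — tuned
   logistic regression (LR), kernel SVC with sigmoid-calibrated
   probabilities (SVC), the margin-normalized SVC2 recalibration,
   random forest (RF), gradient boosting (XGB) — are aggregated
   class-wise by mean, median, maximum and minimum, each renormalized
   across the four classes. These four derived classifiers are cheap,
   training-free variants of stacking.
2. **Consensus voting with abstention.** The nine classifiers each
   vote for their argmax class; the per-class vote counts ("supports",
   0–9) are both the prediction (winner = maximal support, ties broken
   toward the lower class code and flagged) and a confidence measure.
   The certainty heuristic assigns the winner only when its support
   reaches a per-class threshold estimated as a quantile (default the
   first quartile) of calibration supports; otherwise the sample is
   declared *persistently cryptogenic*. Tied votes always abstain.

The consensus deliberately emits no probabilities: the vote count is
its confidence currency, which is what makes the abstention rule
simple and auditable.

### Assumptions

* The four etiologies are mutually exclusive and exhaustive for
  non-cryptogenic strokes; cryptogenic strokes are modelled as
  latent members of the same four classes.
* Features are informative after discretization into clinically
  standard bands; the learners never see raw race (metadata only).
* Missingness is ignorable enough for chained-equation imputation
  (MCAR/MAR); imputation happens before, and independently of, model
  fitting.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| grid axes | 143 / 676 / 48 / 1620 points | LR / SVC / RF / XGB search spaces |
| CV for tuning | 5 stratified shuffles, 20% validation, seed 1701 | model selection by weighted one-vs-rest AUCROC |
| RMFCV composition | 2,3,4,5,10 folds × 30,20,15,12,6 reps (= 300 splits) | performance estimation |
| heuristic quantile | 0.25 (support units, 0–9) | per-class abstention thresholds |
| `pmm_donors` | 5 | PMM donor pool |
| imputation sweeps | 5 | chained-equation iterations |
| MaxInfo cutoff | 4 of 5 categories | completeness filter variant |
| PCA thresholds | 10%…99% (11 values) | variance-based component selection |

The tuned base-learner defaults (`tuned_parameters()`) are the
published grid optima (e.g. LR C = 0.01, l1_ratio = 0; SVC C = 1,
RBF γ = 0.01; RF 1000 trees, depth 20; XGB 1000 rounds, depth 5,
η = 0.01, subsample 0.75); re-tuning on new cohorts goes through
`run_hpo()`.

## Numerical and design choices

* **Quantile convention.** Thresholds use the linear-interpolation
  quantile (R type 7). This is the only convention that can produce
  fractional thresholds such as 7.2 from integer supports, and it is
  asserted against a brute-force interpolation oracle in the tests.
* **Minimum ensemble.** The per-class minimum is normalized exactly
  like the maximum (statistic first, then row normalization), keeping
  the four ensembles symmetric.
* **SVC probabilities.** libsvm's built-in Platt scaling draws from a
  process-global C random stream and is not reproducible across
  identical fits. SVC probabilities are therefore produced by
  per-class sigmoid (Platt-type) calibration of the one-vs-rest margin
  scores, fitted deterministically in R; SVC2 applies min-shift /
  sum-normalization to the same scores. One-vs-rest scores are the
  signed sums of the one-vs-one decision values.
* **Backend mapping.** The RF criterion axis (gini/entropy) is
  enumerated in the grid, but the ranger backend supports only gini
  for probability forests, so both values map to gini during fitting.
  Elastic-net `C` maps to `lambda = 1/(n·C)` to align the two
  penalty parameterizations.
* **Ties.** Argmax ties inside a probability row take the first
  class; consensus support ties take the lower class code and set a
  tie flag; the heuristic converts ties into abstentions.
* **Discretization boundaries.** Band edges belong to the upper band
  (EF 40 is "≥40"), except the upper edge of the three-band normal
  ranges (hemoglobin 15.5 is still normal); hematocrit normal is
  [35, 46) so no value is unclassifiable. The printed PTT bands leave
  a 29.9–30 gap; the cut is at 30.
* **Degenerate inputs.** Features with no observed values are dropped
  by imputation and reported; constant features impute to their
  constant; a class absent from calibration falls back to the maximal
  threshold 9 with a warning; zero-variance features get chi-squared
  p = 1 in signature screening.
* **Feature-group registry.** The registry enumerates 24 training
  dataset variants (demographics-only in three age encodings, the
  seven single-category sets, leave-one-category-out combinations,
  and the discretized full set crossed with MaxInfo filtering and
  PCA), so the canonical 4 algorithms × 24 groups = 96 tuning runs.

## The synthetic cohort generator

`cohort_sim_config()` defines the study conditions: four etiology
strata (default 200 samples each) with class-conditional binary
prevalences and Gaussian labs/vitals, a cryptogenic stratum (default
200) drawn as a latent mixture of the four class models (default
uniform weights), class-conditional age, and per-category
missingness. The planted structure mirrors the clinically
discriminative pattern the method exploits: atrial fibrillation,
atrial dilation and intracardiac thrombus enriched in cardioembolism;
carotid/MCA occlusion and stenosis in large-artery disease;
basal-ganglia and lacunar location in small-vessel disease;
thrombophilia, PFO and malignancy in other-determined etiology.

Two regimes are provided. The `"realistic"` default keeps substantial
class overlap and 30% per-category MCAR missingness — a rate chosen
well below the extreme categorical missingness of real extracted EHR
features (available as the `"ehr"` stress preset at 91.9%) so that
imputation behaviour remains observable rather than vacuous. The
`"strong"` preset doubles binary prevalences on the logit scale and
doubles continuous class contrasts; it is the regime used for
parameter-recovery testing, where the full pipeline is expected to
exceed 0.9 held-out accuracy and to recover the latent etiology of
most non-abstained cryptogenic samples.

What the generator does *not* emulate: correlated feature blocks
beyond class structure, informative (MNAR) missingness, site-specific
feature definitions, label noise from adjudication disagreement, and
temporal drift. Passing tests on synthetic cohorts therefore
demonstrate the machinery's correctness and calibration behaviour,
not clinical-grade performance on real EHR data.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
800 non-cryptogenic + 200 cryptogenic samples with ~40 features, the
imputation oracle at n = 500, and oracle-equivalence checks at
n = 200 — sizes chosen so the whole suite exercises every stage in a
few minutes on one core while keeping Monte-Carlo tolerances tight
(3-SD binomial/multinomial bands, 3-SE mean recovery).

## Known limitations

* The consensus reports no class probabilities by design; downstream
  consumers needing calibrated risk should read the MEAN ensemble.
* Chained-equation imputation here returns a single completed dataset
  per call (matching the analysis design it implements); it performs
  no Rubin's-rules pooling across multiple imputations.
* The grid search is exhaustive and expensive at full scale; the
  published optima are provided as defaults so that routine use does
  not require re-running 2,487 grid points.
* Threshold calibration pools all samples predicted into a class,
  not only correctly predicted ones (the choice is configurable at
  the call site by filtering the calibration result).
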
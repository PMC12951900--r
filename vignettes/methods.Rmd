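---
title: "Methods: subgroup-stratified proteomic risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup-stratified proteomic risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Incident myocardial infarction (MI) risk varies strongly across clinical
subgroups, and established clinical risk scores such as SCORE2 stratify
exactly along those lines: sex, age band, smoking status, systolic blood
pressure (SBP) and non-HDL cholesterol.  `score2pro` implements a
subgroup-stratified proteomic prediction framework: instead of one protein
panel for everyone, each side of each stratification variable gets its own
Cox screen, its own importance ranking, its own forward-selected panel and
its own validated model, all compared against a clinical comparator on the
same held-out rows.

The package is organized as the analysis pipeline itself:

1. **Cohort simulation** (`sim_config()`, `simulate_cohort()`) — a survival
   cohort with the statistical structure the analysis assumes.
2. **Preparation** (`prep_cohort()`) — inclusion filtering, imputation, the
   70/30 split, and leakage-safe protein standardization.
3. **Association screening** (`screen_proteins()`, `fit_cox()`) —
   per-protein proportional-hazards models under two adjustment sets with
   Bonferroni control.
4. **Panel selection** (`rank_importance()`, `forward_select()`) —
   gradient-boosting importance ranking and sequential forward selection
   with a DeLong/AUC plateau stopping rule.
5. **Evaluation** (`roc_auc()`, `delong_compare()`, `categorical_nri()`,
   `dynamic_auc()`, `optimism_corrected_auc()`, `region_cv()`) — the
   discrimination and reclassification statistics the framework rests on.
6. **Orchestration** (`run_subgroup_pipeline()`, `run_pipeline()`) — the
   ten one-variable subgroups, the specific-vs-general comparisons, the
   high-risk composite and the 32-cell sweep.

# The cohort simulator

`simulate_cohort()` draws a population of middle-aged adults (ages 40–69,
truncated normal with median near 57; about 55% female; smoking
never/previous/current at 55/34.5/10.5%; SBP normal with mean 139 and SD
19 mmHg; lipids, BMI, CRP, eGFR, education and diabetes prevalence from
independent truncated normals or log-normals matched to the medians and
IQRs typical of a large population cohort).  Protein levels are standard
normal — the standardized NPX scale — optionally block-equicorrelated and
optionally loaded on age/sex (off by default, so that protein-outcome
effects are unconfounded; confounding is a test scenario, not the
baseline).

Event times follow a Weibull proportional-hazards model,

$$S(t \mid \eta) = \exp\{-(t/\lambda)^{k} e^{\eta}\},$$

with the linear predictor $\eta$ the sum of the *planted* protein
log-hazards (`planted_effect()`), each optionally conditional on a subgroup
side (the heterogeneity the stratified framework is designed to detect).
Inversion of the survival function gives exact simulation, and the
proportional-hazards assumption of downstream Cox fits holds by
construction.  The default baseline ($\lambda = 368$ y, $k = 1$) yields a
cumulative incidence of about 4% at the 15-year administrative horizon —
the event rate of the emulated cohort.  Censoring is the minimum of the
horizon and an exponential dropout draw (default rate 0.01/y).  Regions are
exchangeable labels for leave-one-region-out cross-validation: they carry
no effect, so region folds are valid under the null.

Two deliberate simplifications matter when interpreting test results on
real data.  First, clinical covariates carry no hazard of their own: the
clinical comparator model is a null reference in simulations (validation
AUC near 0.5), whereas on real cohorts it would carry substantial signal;
simulated $\Delta$AUC values are therefore not comparable in magnitude to
real-data gains.  Second, the joint covariate distribution is a product of
independent marginals — only the medians/IQRs of the emulated cohort are
matched, not its correlation structure.  Passing tests demonstrate that the
machinery recovers planted structure at realistic sizes and noise levels,
not that real-data effect sizes will match.

# Preparation

* Proteins with more than 25% missing values are removed
  (`filter_proteins()`), mirroring standard proteomic inclusion practice.
* Clinical covariates are imputed (`impute_clinical()`): the default is a
  chained random-forest imputer built on `ranger` (median/mode
  initialization, iterated re-prediction of each incomplete column until
  imputations stabilize), with plain median/mode imputation as a fast
  fallback.  The contract is what downstream code relies on: all clinical
  missing values filled, observed values untouched, seed-deterministic.
  Proteins are *not* imputed — the boosted-tree learners treat missing
  protein values natively, and Cox screening drops missing rows per
  protein.
* The 70/30 derivation/validation split (`split_cohort()`) is a simple
  random split made once on the full cohort and inherited by every
  subgroup; the preparation report records that event rates of the two
  splits agree within two standard errors.
* `derive_variables()` recomputes non-HDL cholesterol (total − HDL) and
  standardizes each protein to mean 0 / SD 1 **using derivation rows
  only**, applying those frozen parameters to all rows.  Whether scaling
  precedes or follows the split is a genuinely open choice; freezing on the
  derivation set is the leakage-safe reading and is what the package does
  (`prep_cohort()` orders filter → impute → split → derive for exactly this
  reason).  Subgroup membership (age band, smoking, SBP band, non-HDL
  band) is computed after imputation so every row has a defined side.

# Cox screening

`fit_cox()` wraps a proportional-hazards fit (Efron tie handling, the
default of modern survival software) for one exposure plus an adjustment
set and returns the per-1-SD log hazard ratio with Wald inference.
`screen_proteins()` runs one fit per protein under either the demographic
adjustment (`model1`: age, sex, education years) or the full risk-factor
adjustment (`model2`: plus diabetes, smoking as two indicators against
never-smokers, BMI, SBP, DBP, total cholesterol, triglycerides, HDL, LDL,
CRP, eGFR), and applies the Bonferroni threshold $\alpha / (\text{proteins
tested in this run})$ — so subgroup screens use subgroup-specific
denominators.  Monotone-likelihood divergence ($|\log HR| > 15$) is
flagged non-convergent and excluded from significance, never fatal to the
screen.

The descriptive Kaplan–Meier analysis (`km_dichotomized_analysis()`) caps
follow-up at 15 years, dichotomizes one or two proteins at their
Youden-index cutoffs and reports product-limit curves plus adjusted hazard
ratios against a reference group (default: the lowest-crude-risk corner,
e.g. risk-protein-low/protective-protein-high).  `youden_cutoff()` scans
both marker directions so protective proteins dichotomize meaningfully;
ties break toward the risk direction and then the lower cutoff.  The
cutoff is computed on the rows analyzed (the descriptive analysis is not
part of the prediction pipeline, so no split is involved).

# Panel selection

Bonferroni-significant proteins are ranked by their total split-gain
importance in a single gradient-boosted classifier trained on protein
features only (`rank_importance()`; `xgboost` is the package's boosting
engine — binary logistic objective, single-thread, deterministic unless
row/column subsampling is requested).  Ties and never-used features rank
by column position for determinism.

`forward_select()` then adds candidates one at a time in rank order.  The
selection AUC at each step is computed on held-out derivation rows —
out-of-fold 5-fold cross-validation by default, or a single internal
holdout (`eval_scheme`); in-sample AUC of a boosted tree is near 1 and
would break any stopping rule, so both schemes score unseen rows.  Each
step is compared to the best panel so far with a paired DeLong test.

**The improvement rule.**  Under the default
(`improvement_rule = "significant_and_material"`) a step extends the panel
only when the DeLong test is significant at `delong_alpha` (0.05) *and*
the AUC gain reaches `auc_epsilon` (0.003); selection stops after
`plateau_length` (4) consecutive non-improving steps, and the selected
panel is the prefix ending at the last improving step.  The natural
alternative — accept a step when *either* condition holds — is retained as
a config switch.  The strict conjunction is the default for a measurable
reason: candidates arrive ordered by importance fitted on the full
derivation set, so the top-ranked *noise* candidates are exactly those
with the strongest spurious in-sample association, and that association
partially survives into within-derivation cross-validation folds.  Under
the either/or rule those spurious gains of roughly `auc_epsilon` extend
panels in about half of simulated replicates; under the conjunction a gain
that a paired DeLong test cannot distinguish from zero never extends the
panel, and planted panels are recovered essentially exactly (see the
acceptance tests).  With `auc_epsilon = Inf` no step can improve, so the
procedure degenerates to stopping after `plateau_length` steps with a
single-protein panel — a useful boundary check.

Boosting hyperparameters are config-fixed, not tuned: conservative
defaults of 500 trees, depth ≤ 3, learning rate 0.05, no early stopping.
For sparse additive protein signals (the planted-effect scenarios of the
test-bench) depth-1 stumps with 300 rounds at rate 0.1 are used instead:
an additive signal is exactly a sum of stumps, and deeper trees at fixed
rounds underfit small panels, which makes the AUC trace drift as further
(even uninformative) features act as implicit regularization.  SHAP-style
per-protein reporting is deliberately out of the ranking path — ranking
uses split gain only.

# Evaluation statistics

* `roc_auc()` — the Mann–Whitney estimator, ties counting one half.
* `delong_compare()` — the structural-components (midrank) computation of
  the variance of one AUC and the covariance of two correlated AUCs, with
  the two-sided normal test of the difference.  Comparing a score with
  itself is reported as degenerate with $p = 1$ rather than an error.
* `dynamic_auc()` — at horizon $t$: cases have an event by $t$; controls
  are event-free and still under observation at $t$; subjects censored
  early are excluded; no censoring weighting is applied (the simplest
  consistent rule; inverse-probability weighting is a documented
  non-goal).  Horizons run forward from baseline.
* `categorical_nri()` — two risk categories at a fixed threshold; the
  event NRI is the net fraction of events moved up, the non-event NRI the
  net fraction of non-events moved down, and the overall NRI their sum (an
  exact identity, tested at machine precision).  Inference is a percentile
  bootstrap over participants (default 1000 resamples) with a
  normal-approximation p-value on the bootstrap SE.  An optional logistic
  recalibration (`logistic_recalibrate()`: intercept and slope on the
  logit of predicted risk, fitted on derivation data) can precede the NRI;
  raw-risk NRI is the default output.
* `optimism_corrected_auc()` — Harrell's bootstrap: refit the full recipe
  on each resample, measure its AUC on the resample minus its AUC on the
  original data, and subtract the mean of that optimism from the apparent
  AUC.  A known limitation applies: for learners that memorize training
  rows, each refit still predicts the ~63% of original rows contained in
  its resample perfectly, so the optimism estimate is biased downward and
  the corrected AUC of a pure-noise memorizer stays well above 0.5 (this
  is the failure mode that motivated the .632+ family of estimators).  The
  package implements the standard procedure and documents the limitation
  rather than silently switching estimators.
* `region_cv()` — leave-one-region-out cross-validation with single-class
  test regions skipped and reported.
* `hr_heterogeneity_z()` — the pairwise Z-test for a difference of
  independent subgroup log hazard ratios.

Risk scores from the classifiers are predicted event probabilities by the
end of follow-up; reclassification thresholds (5% in the subgroup grid, the
observed composite incidence in the high-risk analysis) are applied to
those probabilities directly, with no baseline-hazard survival conversion.

# Orchestration

`run_subgroup_pipeline()` executes screen → rank → select → evaluate
inside one subgroup (or the overall cohort when `spec = NULL`): the
clinical comparator is a gradient-boosting model on the SCORE2 covariates
(age, sex, smoking, SBP, total and HDL cholesterol) retrained within the
subgroup — published SCORE2 coefficients are deliberately not used — with
any covariate constant inside the subgroup dropped automatically, and the
stratifying variable retained when it still varies within its band.
Subgroups below a derivation-event floor (default 30) are skipped with an
explicit report.  Clinical, specific and combined models of a subgroup are
always evaluated on the identical validation rows (row ids recorded on the
model cards).

`evaluate_high_risk()` pools the selected panels of the one-variable
subgroups matching a composite's sides (the documented pooling rule, also
used by the 32-cell `sweep_composites()`), sets the reclassification
threshold to the observed incidence in the composite (rounded to the
nearest percent) unless fixed by the user, and reports the four contrasts
of the reclassification figure: pooled panel alone, pooled panel plus
clinical, general panel alone, general panel plus clinical — each against
the clinical comparator, with event/non-event decompositions and movement
tables.  An `include_diabetes` flag extends the composite conjunction for
the diabetes-inclusive sensitivity analysis.

`run_pipeline()` ties the stages together from a single nested config
(YAML/JSON round-trippable), derives all stage seeds from one master seed,
and writes the tabular outputs (subgroup × model grid, intersection
matrix, reclassification tables, screening table, panel JSON, prep report)
plus a manifest of MD5 digests.  Identical config and seed reproduce
identical outputs bit for bit.

# Numerical choices and degenerate inputs

* Efron tie handling everywhere in Cox fits; the test-bench oracle uses
  tie-free fixtures so the explicit partial likelihood is unambiguous.
* Non-convergent per-protein fits are flagged, never propagated as
  significance and never fatal.
* `delong_compare()` treats a zero-variance difference as degenerate
  ($p = 1$) instead of dividing by zero.
* Bootstrap resamples with a single outcome class are redrawn (optimism)
  or skipped with a count (NRI), and logged.
* Youden ties break toward the risk direction, then the lower cutoff;
  forward-selection importance ties break by protein index — every
  tie-break is deterministic.
* The event floor guarantees no reclassification or DeLong call ever sees
  a single-class vector.

# Simulation sizes used by the test bench

The acceptance tests state their own problem sizes, chosen once: Cox
oracle fixtures of ≤ 8 subjects; DeLong bootstrap with 2000 resamples on a
60/140 fixture and 2000 null replicates for the level check; NRI coverage
over 200 generative replicates with 200-resample bootstraps; screening
error control over 25 null replicates of 200 proteins at n = 5000 and
power at n = 20,000; panel recovery over 20 replicates at n = 10,000 with
50 candidates; subgroup specificity over 20 replicates at n = 30,000; and
one end-to-end run at n = 10,000 with 200 proteins and twelve planted
effects (five general, seven subgroup-conditional).  The demonstration
design doubles the baseline hazard scale to keep the marginal incidence at
the ~4% study condition despite the planted hazards.

# Known limitations

* Competing risks, informative censoring, batch/plate effects and
  platform-specific normalization are out of scope of the simulator.
* The NSTEMI/STEMI distinction is not modeled; the event column is
  generic, and subtype analyses are reruns with a different event column.
* Continuous (category-free) NRI and IDI are not implemented.
* The optimism correction's memorizing-learner bias, and the exclusion of
  early-censored subjects from dynamic AUC, are documented above.
* Ethnicity/region-stratified models are a non-goal; regions exist for
  cross-validation only.
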
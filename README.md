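# score2pro

Subgroup-stratified plasma-proteomic risk prediction for incident
myocardial infarction (MI), as a tested, reusable R pipeline.

Clinical risk scores such as SCORE2 stratify cardiovascular risk along
sex, age, smoking status, systolic blood pressure (SBP) and non-HDL
cholesterol — yet substantial risk heterogeneity persists *within* those
strata. `score2pro` is for biostatisticians and cardiovascular
epidemiologists who want to ask whether circulating proteins refine MI
prediction differently in different clinical subgroups: instead of one
protein panel for the whole cohort, every side of every stratification
variable gets its own association screen, its own panel and its own
validated model, with a clinical comparator evaluated on the same held-out
rows.

## What it computes

Per-protein association uses Cox proportional hazards on the standardized
(per-SD) protein scale,

$$h(t \mid x) = h_0(t)\,\exp(\beta\,x_{\text{protein}} + \gamma^\top z),$$

with adjustment set $z$ either demographic (model 1: age, sex, education)
or full cardiovascular (model 2: + diabetes, smoking, BMI, SBP, DBP,
lipids, CRP, eGFR), and Bonferroni control at $\alpha/(\text{proteins
tested})$. Significant proteins are ranked by split-gain importance in a
gradient-boosted classifier and added one at a time; the panel stops
growing after four consecutive steps that fail to improve the held-out
AUC materially (gain $\ge \varepsilon = 0.003$) *and* significantly
(paired DeLong test at $\alpha = 0.05$). Validation reports the
Mann–Whitney AUC, the DeLong test of correlated AUCs,

$$z = \frac{\widehat{A}_1 - \widehat{A}_2}
          {\sqrt{\widehat{V}_1 + \widehat{V}_2 - 2\widehat{C}_{12}}},$$

and the categorical net reclassification improvement at a fixed risk
threshold,

$$\mathrm{NRI} = \underbrace{\tfrac{\#\text{up} - \#\text{down}}{\#\text{events}}}_{\text{event NRI}}
 + \underbrace{\tfrac{\#\text{down} - \#\text{up}}{\#\text{non-events}}}_{\text{non-event NRI}},$$

with percentile-bootstrap confidence intervals. Time-horizon dynamic AUC,
Harrell bootstrap optimism correction and leave-one-region-out
cross-validation round out the evaluation stack.

Because the cohort the design emulates is access-restricted, the package
ships a first-class survival-cohort simulator: covariates drawn from the
emulated marginals, standard-normal protein levels, and Weibull
proportional-hazards event times whose linear predictor is a sparse set of
*planted* protein log-hazards — optionally conditional on a clinical
subgroup, which is exactly the heterogeneity the stratified framework is
built to detect. Every planted effect is known ground truth, so the whole
pipeline is testable end to end.

## Worked example

Simulate a cohort with one general risk protein (HR 1.64 per SD) and one
female-specific protein (log-HR 0.5), prepare it, screen, and run the
female subgroup pipeline:

```r
library(score2pro)

cfg <- sim_config(
  n_participants = 8000, n_proteins = 40, seed = 42,
  effects = list(planted_effect(1, log(1.64)),
                 planted_effect(2, 0.5, subgroup_spec("sex", "female"))),
  missing_rate_proteins = 0.05, missing_rate_clinical = 0.02)
cohort <- apply_missingness(simulate_cohort(cfg), cfg)
cohort <- prep_cohort(cohort, prep_config(imputation_method = "median"))$cohort

scr <- screen_proteins(cohort, model = "model2",
                       rows = cohort$split == "derivation")
head(scr[, c("protein", "hr", "ci_lo", "ci_hi", "p",
             "significant_bonferroni")], 3)
#>    protein        hr     ci_lo     ci_hi            p significant_bonferroni
#>  prot_0001 1.6279195 1.4424565 1.8372283 2.873634e-15                   TRUE
#>  prot_0002 1.3108202 1.1609487 1.4800391 1.247889e-05                   TRUE
#>  prot_0034 0.8508411 0.7545312 0.9594442 8.402706e-03                  FALSE

fem <- run_subgroup_pipeline(
  cohort, subgroup_spec("sex", "female"),
  selection_config(gbm_params = list(nrounds = 300, max_depth = 1, eta = 0.1),
                   eval_scheme = "derivation_cv", seed = 1),
  min_events = 20, nri_boot = 500)
fem$panel
#> <panel_result> 2 of 2 candidates selected (no plateau reached)
#> panel: prot_0002, prot_0001
#> AUC trace: 0.639 0.688
fem$nri
#> Categorical NRI at threshold 0.05
#> overall      +0.2310 [0.0535, 0.4397] p=0.0168
#> event        +0.0317 [-0.1479, 0.2291] p=0.737
#> non-event    +0.1992 [0.1609, 0.2364] p=1.28e-24
```

The screen recovers the planted HR of 1.64 at the Bonferroni threshold
(0.05/40); inside the female subgroup both the female-specific protein and
the general protein pass the screen, the forward selection keeps both, and
the two-protein model beats the clinical comparator on the female
validation rows (AUC 0.687 vs 0.478 — the simulator plants no clinical
effects, so the clinical model is a null reference here) with a positive
overall NRI at the 5% threshold.

The full stratified analysis — all ten subgroups, panel intersections, the
high-risk composite — runs from one config:

```r
run <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "out")
run$table2          # subgroup x model grid: AUC, dAUC, DeLong p, NRI + CI
run$intersections   # protein x subgroup membership and intersection cells
run$highrisk        # four reclassification contrasts at the observed incidence
```

A thin command-line wrapper lives at `inst/cli/score2pro.R`
(`Rscript score2pro.R --config run.yaml --seed 1 --out DIR`).

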
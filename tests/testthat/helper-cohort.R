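# Shared fixture builders.  Generator conditions (sample sizes, effect
# sizes, incidence) follow the study conditions the simulator encodes;
# learner configs used in tests are light (few boosting rounds, holdout
# evaluation) so the suite stays fast without touching the generator.

quick_sim <- function(n = 2000, p = 20, seed = 1, effects = list(),
                      miss_prot = 0, miss_clin = 0, ...) {
  cfg <- sim_config(n_participants = n, n_proteins = p, seed = seed,
                    effects = effects,
                    missing_rate_proteins = miss_prot,
                    missing_rate_clinical = miss_clin, ...)
  simulate_cohort(cfg)
}

fast_gbm <- list(nrounds = 120L, max_depth = 3L, eta = 0.1)

fast_selection <- function(seed = 1, ...) {
  selection_config(gbm_params = fast_gbm,
                   eval_scheme = "holdout_within_derivation",
                   seed = seed, ...)
}

# prepared cohort without missingness: split + frozen scaling only
quick_prepared <- function(n = 2000, p = 20, seed = 1, effects = list(),
                           split_seed = 1) {
  co <- quick_sim(n, p, seed, effects)
  co <- split_cohort(co, 0.7, split_seed)
  derive_variables(co)
}
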
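test_that("protein filtering applies the missingness threshold exactly", {
  co <- quick_sim(n = 50, p = 4, seed = 1)
  fracs <- c(0.0, 0.24, 0.26, 0.50)
  for (k in 1:4) {
    n_na <- round(fracs[k] * 50)
    if (n_na > 0) co[seq_len(n_na), protein_cols(co)[k]] <- NA
  }
  out <- filter_proteins(co, 0.25)
  expect_setequal(protein_cols(out$cohort), c("prot_0001", "prot_0002"))
  expect_setequal(out$dropped$protein, c("prot_0003", "prot_0004"))
  expect_equal(out$dropped$missing_fraction[out$dropped$protein == "prot_0004"],
               0.50)

  # near-1 threshold drops nothing that is not entirely missing
  out2 <- filter_proteins(co, 0.9999)
  expect_length(out2$dropped$protein, 0)

  co_all_na <- co
  for (pc in protein_cols(co_all_na)) co_all_na[[pc]] <- NA_real_
  expect_error(filter_proteins(co_all_na, 0.25), "all proteins")
})

test_that("a 2923-protein cohort with 4 over-threshold proteins keeps 2919", {
  # paper-scale inclusion check on a minimal synthetic fixture
  n <- 40
  prot <- matrix(rnorm(n * 2923), n)
  colnames(prot) <- sprintf("prot_%04d", 1:2923)
  over <- sample(2923, 4)
  prot[seq_len(ceiling(0.26 * n)), over] <- NA
  co <- data.frame(id = 1:n, follow_time = rexp(n), event = rbinom(n, 1, 0.1))
  co <- cbind(co, prot)
  out <- filter_proteins(co, 0.25)
  expect_length(protein_cols(out$cohort), 2919)
  expect_length(out$dropped$protein, 4)
})

test_that("median imputation fills with observed medians and leaves the rest", {
  co <- quick_sim(n = 500, p = 2, seed = 3)
  idx <- seq(1, 500, by = 10)
  truth <- co$sbp
  co$sbp[idx] <- NA
  med <- median(co$sbp, na.rm = TRUE)
  out <- impute_clinical(co, "median")
  expect_false(anyNA(out$sbp))
  expect_true(all(out$sbp[idx] == med))
  expect_equal(out$sbp[-idx], truth[-idx])
  # complete table passes through untouched
  co2 <- quick_sim(n = 100, p = 2, seed = 4)
  expect_identical(impute_clinical(co2, "median"), co2)
  co3 <- co2
  co3$bmi <- NA_real_
  expect_error(impute_clinical(co3, "median"), "entirely missing")
})

test_that("iterative forest imputation beats the median on MCAR masking", {
  cfg <- sim_config(n_participants = 1500, n_proteins = 0, seed = 11,
                    missing_rate_clinical = 0.10)
  co <- simulate_cohort(cfg)
  # make sbp partly predictable from dbp so the forest has signal
  co$sbp <- 0.8 * co$dbp + 0.5 * co$bmi + rnorm(nrow(co), 60, 6)
  truth <- co$sbp
  masked <- apply_missingness(co, cfg, seed = 5)
  idx <- which(is.na(masked$sbp))
  rf <- impute_clinical(masked, "iterative_forest", seed = 2)
  md <- impute_clinical(masked, "median")
  rmse <- function(x) sqrt(mean((x[idx] - truth[idx])^2))
  expect_lt(rmse(rf$sbp), rmse(md$sbp))
  expect_false(anyNA(rf[, c("sbp", "dbp", "bmi", "smoking")]))
  # observed values untouched, deterministic under seed
  expect_equal(rf$sbp[-idx], truth[-idx])
  rf2 <- impute_clinical(masked, "iterative_forest", seed = 2)
  expect_identical(rf, rf2)
})

test_that("derived variables and frozen scaling behave as contracts say", {
  co <- quick_prepared(n = 1200, p = 5, seed = 21)
  expect_equal(co$non_hdl, co$total_chol - co$hdl, tolerance = 1e-12)
  d <- co$split == "derivation"
  for (pc in protein_cols(co)) {
    expect_lt(abs(mean(co[[pc]][d])), 1e-8)
    expect_lt(abs(sd(co[[pc]][d]) - 1), 1e-6)
  }

  # leakage check: shift the validation rows before scaling; their post-
  # scaling mean must equal shift/sd_derivation, not zero
  co2 <- quick_sim(n = 1000, p = 1, seed = 22)
  co2 <- split_cohort(co2, 0.7, 1)
  v <- co2$split == "validation"
  co2$prot_0001[v] <- co2$prot_0001[v] + 0.8
  sd_d <- sd(co2$prot_0001[co2$split == "derivation"])
  mu_d <- mean(co2$prot_0001[co2$split == "derivation"])
  out <- derive_variables(co2)
  expected_vmean <- (mean(co2$prot_0001[v]) - mu_d) / sd_d
  expect_equal(mean(out$prot_0001[v]), expected_vmean, tolerance = 1e-10)
  expect_gt(abs(mean(out$prot_0001[v])), 0.5)

  bad <- co2
  bad$hdl <- bad$total_chol + 1
  expect_error(derive_variables(bad), "malformed")
})

test_that("the split rounds, reproduces under seed, and balances events", {
  co <- suppressWarnings(quick_sim(n = 10, p = 0, seed = 1))
  s <- split_cohort(co, 0.7, 99)
  expect_equal(sum(s$split == "derivation"), 7)
  expect_equal(sum(s$split == "validation"), 3)
  expect_identical(split_cohort(co, 0.7, 99)$split, s$split)
  expect_false(identical(split_cohort(co, 0.7, 100)$split, s$split))
  # the cohort-scale arithmetic: round(0.70 * 51010)
  expect_equal(round(0.70 * 51010), 35707)

  pr <- prep_cohort(quick_sim(n = 3000, p = 3, seed = 2),
                    prep_config(imputation_method = "median"))
  expect_true(pr$report$event_rates_comparable)
  expect_equal(pr$report$n_derivation, 2100)
})

test_that("preparation is idempotent and never touches the outcome", {
  cfg <- sim_config(n_participants = 800, n_proteins = 6, seed = 31,
                    missing_rate_proteins = 0.10, missing_rate_clinical = 0.05)
  co <- apply_missingness(simulate_cohort(cfg), cfg)
  pc <- prep_config(imputation_method = "median")
  once <- prep_cohort(co, pc)
  twice <- prep_cohort(once$cohort, pc)
  expect_equal(twice$cohort, once$cohort, tolerance = 1e-12)
  expect_identical(once$cohort$follow_time, co$follow_time)
  expect_identical(once$cohort$event, co$event)
})
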
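test_that("the rank-sum AUC matches pair counting, limits and label flips", {
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  set.seed(5)
  for (rep in 1:10) {
    s <- sample(0:5, 40, replace = TRUE)  # heavy ties
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(s, y), 1 - roc_auc(s, 1 - y), tolerance = 1e-12)
  }
})

test_that("DeLong agrees with pROC and is symmetric", {
  set.seed(8)
  y <- rbinom(300, 1, 0.3)
  a <- rnorm(300) + 0.8 * y
  b <- rnorm(300) + 0.5 * y
  got <- delong_compare(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_equal(got$auc_a, as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE))),
               tolerance = 1e-12)
  # variance of a single AUC matches pROC::var
  expect_equal(got$var_a, pROC::var(pROC::roc(y, a, quiet = TRUE),
                                    method = "delong"), tolerance = 1e-9)
  # symmetry and identity
  rev <- delong_compare(b, a, y)
  expect_equal(got$p, rev$p, tolerance = 1e-12)
  expect_equal(got$delta, -rev$delta, tolerance = 1e-12)
  self <- delong_compare(a, a, y)
  expect_true(self$degenerate)
  expect_equal(self$p, 1)
  expect_equal(self$delta, 0)
})

test_that("DeLong variance tracks the bootstrap on a 60/140 Gaussian fixture", {
  set.seed(12)
  y <- rep(c(1, 0), c(60, 140))
  s <- rnorm(200) + y
  got <- delong_compare(s, rnorm(200), y)
  boot <- replicate(2000, {
    idx <- sample(200, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample(200, replace = TRUE)
    roc_auc(s[idx], y[idx])
  })
  expect_lt(abs(got$var_a - var(boot)) / var(boot), 0.15)
})

test_that("the DeLong test holds its type-I error under the null", {
  set.seed(19)
  rej <- mean(replicate(2000, {
    y <- rep(c(1, 0), c(100, 400))
    delong_compare(rnorm(500), rnorm(500), y)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("dynamic AUC handles horizons, exclusions and the no-censoring limit", {
  # earlier events scored higher, no censoring: AUC 1 at every horizon
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  scores <- -time
  out <- dynamic_auc(scores, time, event, c(1.5, 2.5, 3.5))
  expect_true(all(out$auc == 1))
  expect_equal(out$n_case, c(1, 2, 3))

  # censored-before-t subjects are excluded from the control set
  out2 <- dynamic_auc(c(5, 1, 2), c(1, 2, 5), c(1, 0, 0), 3)
  expect_equal(out2$n_control, 1)  # the t=2 censoring drops out
  expect_equal(out2$n_case, 1)

  # maximal horizon with zero censoring equals the plain end-of-study AUC:
  # non-events all reach the administrative end at t = 10
  set.seed(3)
  ev <- rbinom(300, 1, 0.3)
  tt <- ifelse(ev == 1, runif(300, 0, 10), 10)
  sc <- rnorm(300) + ev
  expect_equal(dynamic_auc(sc, tt, ev, 10)$auc, roc_auc(sc, ev),
               tolerance = 1e-12)

  # no cases before the first event time: NA, not an error
  expect_true(is.na(dynamic_auc(sc, tt, ev, min(tt[ev == 1]) / 2)$auc))
})

test_that("categorical NRI reproduces the counting formula and its identity", {
  # events: 10 up, 5 down of 50; non-events: 20 down, 10 up of 200
  lab <- rep(c(1, 0), c(50, 200))
  old <- rep(0.01, 250)
  new <- old
  new[1:10] <- 0.99                 # events up
  old[11:15] <- 0.99                # events down
  old[51:70] <- 0.99                # non-events down
  new[71:80] <- 0.99                # non-events up
  got <- categorical_nri(old, new, lab, threshold = 0.5, n_boot = 50, seed = 1)
  expect_equal(got$nri_event$estimate, 0.10, tolerance = 1e-12)
  expect_equal(got$nri_nonevent$estimate, 0.05, tolerance = 1e-12)
  expect_equal(got$nri_overall$estimate, 0.15, tolerance = 1e-12)
  expect_equal(got$counts$n, c(10, 5, 10, 20))

  # identity on random inputs, machine precision
  set.seed(2)
  for (rep in 1:20) {
    n <- 150
    lab <- rbinom(n, 1, 0.3)
    if (length(unique(lab)) < 2) next
    ro <- runif(n); rn <- runif(n)
    r <- categorical_nri(ro, rn, lab, threshold = runif(1, 0.2, 0.8),
                         n_boot = 10, seed = rep)
    expect_equal(r$nri_overall$estimate,
                 r$nri_event$estimate + r$nri_nonevent$estimate,
                 tolerance = 1e-14)
  }

  # identical risks: all zeros, empty movement table
  r0 <- categorical_nri(ro, ro, lab, 0.5, n_boot = 10, seed = 1)
  expect_equal(r0$nri_overall$estimate, 0)
  expect_true(all(r0$counts$n == 0))
  expect_error(categorical_nri(ro, rn, rep(1, n), 0.5), "both events")
})

test_that("optimism correction is null for a fixed score and fixes overfitting", {
  set.seed(31)
  df <- data.frame(y = rbinom(300, 1, 0.3), junk = rnorm(300))
  fixed <- function(train) function(newdata) rep(0.5, nrow(newdata)) + 0.001 * newdata$junk
  out <- optimism_corrected_auc(df, "y", fixed, n_boot = 40, seed = 2)
  expect_lt(abs(out$mean_optimism), 0.03)
  expect_lt(abs(out$corrected_auc - 0.5), 0.08)

  expect_warning(optimism_corrected_auc(df, "y", fixed, n_boot = 1, seed = 1),
                 "n_boot")
})

test_that("region CV rotates folds and is exchangeable under the null", {
  set.seed(41)
  n <- 600
  df <- data.frame(y = rbinom(n, 1, 0.3), x = rnorm(n),
                   region = sample(sprintf("r%02d", 1:6), n, replace = TRUE))
  recipe <- function(train) {
    fit <- glm(y ~ x, data = train, family = binomial())
    function(newdata) predict(fit, newdata, type = "response")
  }
  out <- region_cv(df, "y", "region", recipe)
  expect_equal(nrow(out$folds), 6)
  expect_equal(sum(out$folds$n), n)
  # null covariate: fold AUCs center near 1/2
  expect_lt(abs(out$mean_auc - 0.5), 0.1)

  # two regions = two folds, each trained on the other
  df2 <- df; df2$region <- rep(c("a", "b"), length.out = n)
  out2 <- region_cv(df2, "y", "region", recipe)
  expect_equal(out2$folds$region, c("a", "b"))
  expect_error(region_cv(transform(df, region = "one"), "y", "region", recipe),
               "2 regions")
})

test_that("the heterogeneity Z-test matches closed-form arithmetic and its null", {
  expect_equal(hr_heterogeneity_z(0.3, 0.1, 0.3, 0.2)$z, 0)
  expect_equal(hr_heterogeneity_z(0.3, 0.1, 0.3, 0.2)$p, 1)
  got <- hr_heterogeneity_z(log(2), 0.2, 0, 0.2)
  expect_equal(got$z, log(2) / sqrt(0.08), tolerance = 1e-6)
  expect_equal(got$z, 2.4506, tolerance = 1e-4)
  expect_equal(got$p, 0.0143, tolerance = 5e-3)
  expect_error(hr_heterogeneity_z(1, 0, 1, 0.1), "positive")

  set.seed(51)
  rej <- mean(replicate(2000, {
    hr_heterogeneity_z(rnorm(1, 0, 0.15), 0.15, rnorm(1, 0, 0.15), 0.15)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("logistic recalibration restores calibration-in-the-large", {
  set.seed(61)
  z <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(z - 1))
  miscal <- plogis(2 * z + 1)      # wrong slope and intercept
  recal <- logistic_recalibrate(miscal, miscal, y)
  expect_lt(abs(mean(recal) - mean(y)), 0.02)
  expect_gt(abs(mean(miscal) - mean(y)), 0.1)
})
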
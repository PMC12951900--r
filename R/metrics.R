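#' Mann-Whitney AUC
#'
#' Probability that a random case scores above a random control, ties
#' counting one half (the rank-sum estimator).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each case the placement value
# P(score > random control) and vice versa, via midranks (fast O(n log n)).
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # per-case components
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m  # per-control components
  list(auc = sum(v10) / m, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong comparison of two correlated AUCs
#'
#' Computes both AUCs, their variances and covariance from the structural
#' (placement) components of the Mann-Whitney statistic, and the two-sided
#' normal test of the AUC difference.  The two score vectors must be paired
#' on the same subjects/labels.
#'
#' @param scores_a,scores_b paired risk scores.
#' @param labels 0/1 labels shared by both scores.
#' @return list of class `roc_comparison`: `auc_a`, `auc_b`, `delta`
#'   (= `auc_b - auc_a`), `var_a`, `var_b`, `cov_ab`, `z`, `p`, `degenerate`.
#'   A zero-variance difference (e.g. comparing a score with itself) yields
#'   `delta` as computed, `p = 1` and `degenerate = TRUE`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]; scores_b <- scores_b[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) stop("delong_compare: both classes required")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- pa$m; n <- pa$n
  var_a <- stats::var(pa$v10) / m + stats::var(pa$v01) / n
  var_b <- stats::var(pb$v10) / m + stats::var(pb$v01) / n
  cov_ab <- stats::cov(pa$v10, pb$v10) / m + stats::cov(pa$v01, pb$v01) / n
  delta <- pb$auc - pa$auc
  var_delta <- var_a + var_b - 2 * cov_ab
  degenerate <- !is.finite(var_delta) || var_delta <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 var_a = var_a, var_b = var_b, cov_ab = cov_ab,
                 z = z, p = p, degenerate = degenerate),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.4f vs %.4f (delta %+.4f), DeLong z = %.3f, p = %.3g%s\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Dynamic AUC over follow-up horizons
#'
#' At each horizon `t`, cases are subjects with an event by `t`
#' (`event == 1 & follow_time <= t`) and controls are subjects still
#' event-free and under observation at `t` (`follow_time >= t` without an
#' event by `t`); subjects censored before `t` without an event are
#' excluded.  The Mann-Whitney AUC is computed on that case/control split,
#' independently per horizon (no censoring weighting).
#'
#' @param scores risk scores.
#' @param time follow-up times (years).
#' @param event 0/1 event indicators.
#' @param horizons numeric vector of horizons (years).
#' @return data.frame: `horizon`, `auc` (`NA` when a class is empty),
#'   `n_case`, `n_control`.
#' @export
dynamic_auc <- function(scores, time, event, horizons) {
  out <- lapply(horizons, function(t) {
    is_case <- event == 1 & time <= t
    is_control <- time >= t & !is_case
    nc <- sum(is_case); nk <- sum(is_control)
    a <- if (nc == 0L || nk == 0L) NA_real_ else {
      sel <- is_case | is_control
      roc_auc(scores[sel], as.integer(is_case[sel]))
    }
    data.frame(horizon = t, auc = a, n_case = nc, n_control = nk)
  })
  do.call(rbind, out)
}

#' Categorical net reclassification improvement
#'
#' Two risk categories (below / at-or-above `threshold`).  The event NRI is
#' the net proportion of events reclassified upward by the new model, the
#' non-event NRI the net proportion of non-events reclassified downward, and
#' the overall NRI their sum (an exact identity on the same sample).
#' Inference is by percentile bootstrap over participants (paired
#' resampling); p-values use the normal approximation on the bootstrap SE.
#'
#' @param risk_old,risk_new predicted risks in `[0, 1]` from the reference
#'   and the new model, paired on the same subjects.
#' @param labels 0/1 outcome labels.
#' @param threshold risk threshold defining the two categories.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class `reclass_result`: `threshold`, `counts` (up/down
#'   movements for events and non-events), `nri_event`, `nri_nonevent`,
#'   `nri_overall`, each with `ci95` and `p`, and `n_boot`.
#' @export
categorical_nri <- function(risk_old, risk_new, labels, threshold,
                            n_boot = 1000L, seed = 1L) {
  keep <- !is.na(risk_old) & !is.na(risk_new) & !is.na(labels)
  risk_old <- risk_old[keep]; risk_new <- risk_new[keep]; labels <- labels[keep]
  stopifnot(all(risk_old >= 0 & risk_old <= 1),
            all(risk_new >= 0 & risk_new <= 1))
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    stop("categorical_nri: both events and non-events required")
  }
  cat_old <- risk_old >= threshold
  cat_new <- risk_new >= threshold
  point <- function(idx) {
    ev <- labels[idx] == 1
    up <- cat_new[idx] & !cat_old[idx]
    down <- !cat_new[idx] & cat_old[idx]
    ne <- sum(ev); nn <- sum(!ev)
    e <- (sum(up & ev) - sum(down & ev)) / ne
    v <- (sum(down & !ev) - sum(up & !ev)) / nn
    c(event = e, nonevent = v, overall = e + v)
  }
  idx_all <- seq_along(labels)
  est <- point(idx_all)
  counts <- data.frame(
    class = c("event", "event", "nonevent", "nonevent"),
    movement = c("up", "down", "up", "down"),
    n = c(sum(cat_new & !cat_old & labels == 1),
          sum(!cat_new & cat_old & labels == 1),
          sum(cat_new & !cat_old & labels == 0),
          sum(!cat_new & cat_old & labels == 0))
  )
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 3L)
  b <- 1L
  while (b <= n_boot) {
    idx <- sample(idx_all, replace = TRUE)
    if (sum(labels[idx] == 1) == 0L || sum(labels[idx] == 0) == 0L) next
    boots[b, ] <- point(idx)
    b <- b + 1L
  }
  wrap <- function(k) {
    bs <- boots[, k]
    se <- stats::sd(bs)
    p <- if (se > 0) 2 * stats::pnorm(-abs(est[k] / se)) else as.numeric(est[k] == 0)
    list(estimate = unname(est[k]),
         ci95 = unname(stats::quantile(bs, c(0.025, 0.975), names = FALSE)),
         p = p)
  }
  structure(list(threshold = threshold, counts = counts,
                 nri_event = wrap(1L), nri_nonevent = wrap(2L),
                 nri_overall = wrap(3L), n_boot = n_boot),
            class = "reclass_result")
}

#' @export
print.reclass_result <- function(x, ...) {
  f <- function(nm, b) sprintf("%-12s %+0.4f [%.4f, %.4f] p=%.3g",
                               nm, b$estimate, b$ci95[1], b$ci95[2], b$p)
  cat("Categorical NRI at threshold", x$threshold, "\n")
  cat(f("overall", x$nri_overall), "\n")
  cat(f("event", x$nri_event), "\n")
  cat(f("non-event", x$nri_nonevent), "\n")
  invisible(x)
}

#' Logistic recalibration of predicted risks
#'
#' One-variable logistic recalibration (intercept and slope on the logit of
#' the predicted risk), the minimal standard recalibration used before a
#' calibrated NRI.  Fit the recalibration on derivation data and apply it to
#' validation risks.
#'
#' @param risk predicted risks in (0, 1) to recalibrate.
#' @param fit_risk,fit_labels risks and 0/1 labels to fit the recalibration
#'   on (default: `risk` and `labels` supplied for application).
#' @return recalibrated risks.
#' @export
logistic_recalibrate <- function(risk, fit_risk = risk, fit_labels) {
  eps <- 1e-12
  lg <- function(p) stats::qlogis(pmin(pmax(p, eps), 1 - eps))
  fit <- stats::glm(fit_labels ~ lg(fit_risk), family = stats::binomial())
  stats::plogis(stats::coef(fit)[1] + stats::coef(fit)[2] * lg(risk))
}

#' Bootstrap optimism-corrected AUC
#'
#' Harrell's procedure: the modeling recipe is refit on each bootstrap
#' resample; the optimism of that refit is its AUC on the resample minus its
#' AUC on the original data; the corrected AUC is the apparent AUC minus the
#' mean optimism.  Resamples with a single outcome class are redrawn (and
#' counted).
#'
#' @param data data.frame of modeling rows.
#' @param label_col name of the 0/1 outcome column.
#' @param recipe function `(train_data) -> function(newdata) -> scores`: the
#'   full, self-contained modeling pipeline.
#' @param n_boot bootstrap resamples (default 500).
#' @param seed integer seed.
#' @return list: `apparent_auc`, `mean_optimism`, `corrected_auc`,
#'   `optimism` (per-resample values), `n_redrawn`.
#' @export
optimism_corrected_auc <- function(data, label_col, recipe,
                                   n_boot = 500L, seed = 1L) {
  y <- data[[label_col]]
  predictor <- recipe(data)
  apparent <- roc_auc(predictor(data), y)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (n_boot < 2L) warning("optimism_corrected_auc: n_boot < 2 gives an unstable correction")
  opt <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample(nrow(data), replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    boot <- data[idx, , drop = FALSE]
    pred_b <- recipe(boot)
    opt[b] <- roc_auc(pred_b(boot), y[idx]) - roc_auc(pred_b(data), y)
  }
  list(apparent_auc = apparent, mean_optimism = mean(opt),
       corrected_auc = apparent - mean(opt), optimism = opt,
       n_redrawn = n_redrawn)
}

#' Leave-one-region-out cross-validation
#'
#' Trains the recipe on all regions but one and scores the held-out region,
#' rotating over every region; regions whose test rows contain a single
#' outcome class are skipped with a warning.
#'
#' @param data data.frame of modeling rows.
#' @param label_col name of the 0/1 outcome column.
#' @param region_col name of the region label column.
#' @param recipe function `(train_data) -> function(newdata) -> scores`.
#' @return list: `folds` (data.frame region/auc/n/n_events), `mean_auc`,
#'   `sd_auc`.
#' @export
region_cv <- function(data, label_col, region_col, recipe) {
  regions <- unique(as.character(data[[region_col]]))
  if (length(regions) < 2L) stop("region_cv: at least 2 regions required")
  rows <- lapply(sort(regions), function(rg) {
    test <- data[[region_col]] == rg
    if (length(unique(data[[label_col]][test])) < 2L) {
      warning("region_cv: region ", rg, " has a single outcome class; fold skipped")
      return(NULL)
    }
    predictor <- recipe(data[!test, , drop = FALSE])
    a <- roc_auc(predictor(data[test, , drop = FALSE]), data[[label_col]][test])
    data.frame(region = rg, auc = a, n = sum(test),
               n_events = sum(data[[label_col]][test]))
  })
  folds <- do.call(rbind, rows)
  list(folds = folds, mean_auc = mean(folds$auc), sd_auc = stats::sd(folds$auc))
}

#' Pairwise Z-test for hazard-ratio heterogeneity between subgroups
#'
#' `z = (log_hr_1 - log_hr_2) / sqrt(se_1^2 + se_2^2)` with a two-sided
#' normal p, for independent subgroup estimates.
#'
#' @param log_hr_1,log_hr_2 subgroup log hazard ratios.
#' @param se_1,se_2 their standard errors (must be positive).
#' @return list: `z`, `p`.
#' @export
hr_heterogeneity_z <- function(log_hr_1, se_1, log_hr_2, se_2) {
  if (any(c(se_1, se_2) <= 0)) stop("hr_heterogeneity_z: SEs must be positive")
  z <- (log_hr_1 - log_hr_2) / sqrt(se_1^2 + se_2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
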
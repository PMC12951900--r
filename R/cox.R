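#' Covariate adjustment sets for protein screening
#'
#' Two nested adjustment models are used throughout: the demographic model
#' (`model1`: age, sex, education years) and the cardiovascular risk-factor
#' model (`model2`: model1 plus diabetes, smoking status as two indicator
#' levels against never-smokers, BMI, systolic and diastolic blood pressure,
#' total cholesterol, triglycerides, HDL and LDL cholesterol, C-reactive
#' protein and eGFR).
#'
#' @param name `"model1"` or `"model2"`.
#' @return character vector of covariate column names.
#' @export
adjustment_model <- function(name = c("model2", "model1")) {
  name <- match.arg(name)
  m1 <- c("age", "sex", "education")
  if (name == "model1") return(m1)
  c(m1, "diabetes", "smoking", "bmi", "sbp", "dbp", "total_chol",
    "triglycerides", "hdl", "ldl", "crp", "egfr")
}

#' Fit a single-exposure Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron handling of tied event times)
#' for one exposure plus an optional covariate adjustment set, and returns
#' the exposure's log hazard ratio with model-based SE, Wald p and 95% CI.
#' Rows with a missing value in any used column are dropped (`n_used`
#' records the rows kept).  A fit with `|log HR| > 15` is flagged
#' non-convergent (monotone-likelihood divergence).
#'
#' @param time follow-up times (years).
#' @param event 0/1 event indicators.
#' @param exposure numeric exposure vector (per-1-SD convention is the
#'   caller's responsibility; screening passes standardized proteins).
#' @param covariates optional data.frame of adjustment covariates.
#' @param exposure_name label used in the result.
#' @return one-row data.frame: `protein`, `log_hr`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `n_used`, `n_events`, `converged`.
#' @export
fit_cox <- function(time, event, exposure, covariates = NULL,
                    exposure_name = "exposure") {
  df <- data.frame(.time = time, .event = event, .exposure = exposure)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (sum(df$.event) < 2) stop("fit_cox: fewer than 2 events among usable rows")
  if (length(unique(df$.exposure)) < 2L) {
    stop("fit_cox: exposure is constant among usable rows")
  }
  rhs <- c(".exposure", setdiff(names(df), c(".time", ".event", ".exposure")))
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                               paste(rhs, collapse = " + ")))
  fit <- survival::coxph(f, data = df, ties = "efron")
  beta <- unname(stats::coef(fit)[".exposure"])
  se <- sqrt(diag(stats::vcov(fit))[".exposure"])
  se <- unname(se)
  conv <- is.finite(beta) && abs(beta) <= 15
  z <- beta / se
  data.frame(
    protein = exposure_name,
    log_hr = beta, se = se, hr = exp(beta),
    ci_lo = exp(beta - 1.959964 * se),
    ci_hi = exp(beta + 1.959964 * se),
    p = 2 * stats::pnorm(-abs(z)),
    n_used = nrow(df), n_events = sum(df$.event),
    converged = conv,
    stringsAsFactors = FALSE
  )
}

#' Per-protein Cox screening with Bonferroni control
#'
#' Fits one adjusted Cox model per retained protein and flags significance
#' at the Bonferroni-corrected threshold `alpha / (number of proteins
#' tested in this run)`.  Non-convergent fits are kept in the table but
#' flagged and never marked significant; the screen itself never aborts on a
#' per-protein failure.
#'
#' @param cohort a prepared cohort table.
#' @param model `"model1"` or `"model2"` adjustment set.
#' @param alpha family-wise level (default 0.05).
#' @param rows optional logical/integer row subset (e.g. derivation rows of
#'   one subgroup).
#' @param proteins optional character vector of protein columns to test
#'   (default: all).
#' @return data.frame of per-protein results, one row per protein, with
#'   `model`, `bonferroni_threshold` and `significant_bonferroni` columns,
#'   sorted by p.
#' @export
screen_proteins <- function(cohort, model = "model2", alpha = 0.05,
                            rows = NULL, proteins = NULL) {
  if (!is.null(rows)) cohort <- cohort[rows, , drop = FALSE]
  if (is.null(proteins)) proteins <- protein_cols(cohort)
  covars <- adjustment_model(model)
  covdf <- cohort[, covars, drop = FALSE]
  res <- lapply(proteins, function(pr) {
    out <- tryCatch(
      fit_cox(cohort$follow_time, cohort$event, cohort[[pr]],
              covariates = covdf, exposure_name = pr),
      error = function(e) {
        warning("screen_proteins: ", pr, ": ", conditionMessage(e), call. = FALSE)
        data.frame(protein = pr, log_hr = NA_real_, se = NA_real_,
                   hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   p = NA_real_, n_used = NA_integer_, n_events = NA_integer_,
                   converged = FALSE, stringsAsFactors = FALSE)
      })
    if (!out$converged && is.finite(out$log_hr)) {
      warning("screen_proteins: ", pr, ": non-convergent fit (|log HR| > 15)",
              call. = FALSE)
    }
    out
  })
  res <- do.call(rbind, res)
  n_tested <- length(proteins)
  thr <- if (n_tested > 0) alpha / n_tested else 0
  res$model <- model
  res$n_tested <- n_tested
  res$bonferroni_threshold <- thr
  res$significant_bonferroni <- res$converged & !is.na(res$p) & res$p < thr
  res[order(res$p), , drop = FALSE]
}

#' Youden-index optimal cutoff
#'
#' Scans the observed marker values as candidate thresholds and returns the
#' threshold maximizing J = sensitivity + specificity - 1.  Both marker
#' directions are considered (positive call = marker >= threshold for a risk
#' marker, marker < threshold for a protective one), so protective proteins
#' dichotomize meaningfully too.  Ties are broken in favour of the risk
#' direction, then the lower cutoff.
#'
#' @param marker numeric marker values.
#' @param event 0/1 outcome by end of follow-up.
#' @return list with `cutoff`, `j` (the Youden index there) and `direction`
#'   (`">="` or `"<"`: the side called positive).
#' @export
youden_cutoff <- function(marker, event) {
  keep <- !is.na(marker) & !is.na(event)
  marker <- marker[keep]; event <- event[keep]
  if (length(unique(marker)) < 2L) stop("youden_cutoff: marker is constant")
  if (length(unique(event)) < 2L) stop("youden_cutoff: both classes required")
  thr <- sort(unique(marker))
  n1 <- sum(event == 1); n0 <- sum(event == 0)
  j_ge <- vapply(thr, function(ct) {
    pos <- marker >= ct
    sum(pos & event == 1) / n1 + sum(!pos & event == 0) / n0 - 1
  }, 0)
  best_ge <- which(j_ge >= max(j_ge) - 1e-12)[1L]  # lowest threshold among ties
  best_lt <- which(-j_ge >= max(-j_ge) - 1e-12)[1L]
  if (max(j_ge) >= max(-j_ge)) {
    list(cutoff = thr[best_ge], j = j_ge[best_ge], direction = ">=")
  } else {
    list(cutoff = thr[best_lt], j = -j_ge[best_lt], direction = "<")
  }
}

#' Kaplan-Meier analysis of Youden-dichotomized protein groups
#'
#' Caps follow-up at `cap_years` (late times are administratively truncated),
#' dichotomizes each requested protein at its Youden-index cutoff (computed
#' on the rows analyzed), forms 2 groups for one protein or the 4-cell cross
#' for two proteins, and returns Kaplan-Meier curves with standard errors per
#' group plus covariate-adjusted Cox hazard ratios of each group against a
#' reference group.
#'
#' @param cohort a prepared cohort table.
#' @param proteins one or two protein column names.
#' @param model adjustment set for the group Cox model (default `"model2"`).
#' @param cap_years follow-up cap (default 15).
#' @param reference reference group label; default is the group with the
#'   lowest crude event rate (the low-risk corner).
#' @return list with `cutoffs`, `groups` (per-row labels), `km` (step-function
#'   coordinates: group, time, surv, se, n_risk, n_event) and `cox`
#'   (per-group results vs the reference).
#' @export
km_dichotomized_analysis <- function(cohort, proteins, model = "model2",
                                     cap_years = 15, reference = NULL) {
  stopifnot(length(proteins) %in% 1:2, all(proteins %in% names(cohort)))
  keep <- stats::complete.cases(cohort[, proteins, drop = FALSE])
  cohort <- cohort[keep, , drop = FALSE]
  time <- pmin(cohort$follow_time, cap_years)
  event <- ifelse(cohort$follow_time > cap_years, 0L, cohort$event)

  cuts <- lapply(proteins, function(pr) youden_cutoff(cohort[[pr]], event))
  names(cuts) <- proteins
  lev <- function(pr) ifelse(cohort[[pr]] >= cuts[[pr]]$cutoff, "high", "low")
  group <- if (length(proteins) == 1L) {
    paste0(proteins, lev(proteins))
  } else {
    paste0(proteins[1], lev(proteins[1]), ".", proteins[2], lev(proteins[2]))
  }
  group <- factor(group)

  rate <- tapply(event, group, mean)
  if (is.null(reference)) reference <- names(rate)[which.min(rate)]
  stopifnot(reference %in% levels(group))
  group <- stats::relevel(group, ref = reference)

  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, surv = sf$surv, se = sf$std.err * sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event
  )

  covars <- cohort[, adjustment_model(model), drop = FALSE]
  cox <- lapply(setdiff(levels(group), reference), function(g) {
    sel <- group %in% c(reference, g)
    if (sum(sel & group == g) == 0L || sum(sel & group == reference) == 0L) {
      warning("km_dichotomized_analysis: empty group, contrast skipped: ", g)
      return(NULL)
    }
    out <- fit_cox(time[sel], event[sel],
                   as.numeric(group[sel] == g),
                   covariates = covars[sel, , drop = FALSE],
                   exposure_name = g)
    out$reference <- reference
    out
  })
  cox <- do.call(rbind, cox)
  list(cutoffs = lapply(cuts, `[[`, "cutoff"), groups = group,
       km = km, cox = cox)
}
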
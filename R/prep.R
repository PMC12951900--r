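#' Preparation configuration
#'
#' @param protein_missing_threshold proteins with a missing fraction strictly
#'   above this are dropped (default 0.25).
#' @param derivation_fraction fraction of rows assigned to the derivation
#'   set (default 0.70).
#' @param split_seed seed for the random split.
#' @param imputation_method `"iterative_forest"` (chained random-forest
#'   imputation) or `"median"`.
#' @param impute_seed seed for the imputation draws.
#' @param scale_proteins standardize proteins to mean 0 / SD 1, with the
#'   standardization parameters frozen on the derivation rows (default on).
#' @return object of class `prep_config`.
#' @export
prep_config <- function(protein_missing_threshold = 0.25,
                        derivation_fraction = 0.70,
                        split_seed = 1L,
                        imputation_method = c("iterative_forest", "median"),
                        impute_seed = 1L,
                        scale_proteins = TRUE) {
  stopifnot(protein_missing_threshold > 0, protein_missing_threshold < 1,
            derivation_fraction > 0, derivation_fraction < 1)
  structure(list(
    protein_missing_threshold = protein_missing_threshold,
    derivation_fraction = derivation_fraction,
    split_seed = as.integer(split_seed),
    imputation_method = match.arg(imputation_method),
    impute_seed = as.integer(impute_seed),
    scale_proteins = isTRUE(scale_proteins)
  ), class = "prep_config")
}

#' Drop proteins with excessive missingness
#'
#' Removes every protein column whose missing fraction (over all rows)
#' exceeds `threshold`.
#'
#' @param cohort a cohort table.
#' @param threshold missing-fraction cutoff in (0, 1); proteins with
#'   fraction strictly greater are dropped.
#' @return list with `cohort` (columns removed) and `dropped`, a data.frame
#'   of the removed proteins and their missing fractions.
#' @export
filter_proteins <- function(cohort, threshold = 0.25) {
  stopifnot(threshold > 0, threshold < 1)
  prots <- protein_cols(cohort)
  frac <- vapply(prots, function(cl) mean(is.na(cohort[[cl]])), 0)
  drop <- prots[frac > threshold]
  if (length(drop) == length(prots) && length(prots) > 0) {
    stop("filter_proteins: all proteins exceed the missingness threshold")
  }
  list(
    cohort = cohort[, setdiff(names(cohort), drop), drop = FALSE],
    dropped = data.frame(protein = drop,
                         missing_fraction = unname(frac[drop]),
                         stringsAsFactors = FALSE)
  )
}

#' Impute missing clinical covariates
#'
#' Fills all missing values of the clinical covariate columns.  Observed
#' values are never modified; protein columns are never imputed (downstream
#' tree learners handle missing proteins natively and Cox screening drops
#' missing rows per protein).  Both methods are deterministic given `seed`.
#'
#' `"median"` replaces missing entries by the column median (mode for the
#' categorical smoking status).  `"iterative_forest"` runs chained
#' random-forest imputation: after a median/mode initialization, each
#' incomplete column is repeatedly re-predicted from the other clinical
#' covariates with a small [ranger][ranger::ranger] forest until the
#' imputations stabilize.
#'
#' @param cohort a cohort table.
#' @param method `"iterative_forest"` or `"median"`.
#' @param seed integer seed.
#' @param max_iter maximum chained-imputation sweeps.
#' @param num_trees trees per forest.
#' @return the cohort with complete clinical columns.
#' @export
impute_clinical <- function(cohort,
                            method = c("iterative_forest", "median"),
                            seed = 1L, max_iter = 5L, num_trees = 50L) {
  method <- match.arg(method)
  cols <- intersect(clinical_cols(), names(cohort))
  for (cl in cols) {
    if (all(is.na(cohort[[cl]]))) {
      stop("impute_clinical: column '", cl, "' is entirely missing")
    }
  }
  na_idx <- lapply(cols, function(cl) which(is.na(cohort[[cl]])))
  names(na_idx) <- cols
  incomplete <- cols[vapply(na_idx, length, 0L) > 0L]
  if (length(incomplete) == 0L) return(cohort)

  impute_one <- function(x) {
    if (is.factor(x)) {
      tab <- table(x)
      x[is.na(x)] <- names(tab)[which.max(tab)]
    } else {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    }
    x
  }
  # median/mode fill (also the full answer for method = "median")
  filled <- cohort
  for (cl in incomplete) filled[[cl]] <- impute_one(filled[[cl]])
  if (method == "median") return(filled)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  preds <- cols
  for (iter in seq_len(max_iter)) {
    max_change <- 0
    for (cl in incomplete) {
      idx <- na_idx[[cl]]
      train <- filled[-idx, c(cl, setdiff(preds, cl)), drop = FALSE]
      test <- filled[idx, setdiff(preds, cl), drop = FALSE]
      fit <- ranger::ranger(
        stats::as.formula(paste(cl, "~ .")), data = train,
        num.trees = num_trees, num.threads = 1L,
        seed = seed + iter, respect.unordered.factors = TRUE
      )
      new_vals <- stats::predict(fit, data = test, num.threads = 1L)$predictions
      if (cl == "diabetes") new_vals <- as.integer(round(new_vals))
      old_vals <- filled[[cl]][idx]
      if (is.numeric(old_vals)) {
        denom <- max(stats::sd(filled[[cl]]), 1e-8)
        max_change <- max(max_change, max(abs(new_vals - old_vals)) / denom)
      } else {
        max_change <- max(max_change, mean(new_vals != old_vals))
      }
      filled[[cl]][idx] <- new_vals
    }
    if (max_change < 0.01) break
  }
  filled
}

#' Derive non-HDL cholesterol and standardize proteins
#'
#' Recomputes `non_hdl = total_chol - hdl` and, when `scale_proteins` is on,
#' standardizes every protein column to mean 0 / SD 1.  Standardization
#' parameters are computed on derivation rows only (when the cohort carries a
#' split) and applied to all rows, so the validation set never leaks into the
#' scaling; with no split assigned, all rows are used.
#'
#' @param cohort a cohort table.
#' @param scale_proteins logical.
#' @return the cohort with `non_hdl` refreshed and (optionally) proteins
#'   standardized; attribute `proteins_scaled` set accordingly.
#' @export
derive_variables <- function(cohort, scale_proteins = TRUE) {
  bad <- !is.na(cohort$hdl) & !is.na(cohort$total_chol) &
    cohort$hdl > cohort$total_chol
  if (mean(bad) > 0.01) {
    stop("derive_variables: HDL exceeds total cholesterol for >1% of rows; malformed input")
  }
  cohort$non_hdl <- cohort$total_chol - cohort$hdl
  if (scale_proteins) {
    ref <- if ("split" %in% names(cohort) && any(cohort$split == "derivation")) {
      cohort$split == "derivation"
    } else {
      rep(TRUE, nrow(cohort))
    }
    for (cl in protein_cols(cohort)) {
      mu <- mean(cohort[[cl]][ref], na.rm = TRUE)
      sdv <- stats::sd(cohort[[cl]][ref], na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      cohort[[cl]] <- (cohort[[cl]] - mu) / sdv
    }
    attr(cohort, "proteins_scaled") <- TRUE
  }
  cohort
}

#' Random derivation/validation split
#'
#' Simple random split, reproducible by seed; `round(fraction * n)` rows are
#' labelled `derivation`, the rest `validation`.
#'
#' @param cohort a cohort table.
#' @param fraction derivation fraction in (0, 1).
#' @param seed integer seed.
#' @return the cohort with the `split` column assigned.
#' @export
split_cohort <- function(cohort, fraction = 0.70, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(cohort)
  n_deriv <- round(fraction * n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n, n_deriv)
  split <- rep("validation", n)
  split[idx] <- "derivation"
  cohort$split <- factor(split, levels = c("derivation", "validation", "unassigned"))
  cohort
}

#' Full preparation pipeline
#'
#' filter proteins -> impute clinical -> split -> derive (leakage-safe
#' scaling frozen on the derivation rows).  Idempotent on its own output.
#' `follow_time` and `event` are never modified by any step.
#'
#' @param cohort a cohort table (possibly with missing values).
#' @param config a [prep_config()].
#' @return list with `cohort` (prepared) and `report`: dropped proteins,
#'   split sizes and the per-split event rates with the standard error of
#'   their difference.
#' @export
prep_cohort <- function(cohort, config = prep_config()) {
  flt <- filter_proteins(cohort, config$protein_missing_threshold)
  cohort <- impute_clinical(flt$cohort, config$imputation_method,
                            seed = config$impute_seed)
  cohort <- split_cohort(cohort, config$derivation_fraction, config$split_seed)
  cohort <- derive_variables(cohort, config$scale_proteins)

  is_d <- cohort$split == "derivation"
  r_d <- mean(cohort$event[is_d]); r_v <- mean(cohort$event[!is_d])
  se_diff <- sqrt(r_d * (1 - r_d) / sum(is_d) + r_v * (1 - r_v) / sum(!is_d))
  report <- list(
    dropped_proteins = flt$dropped,
    n_derivation = sum(is_d),
    n_validation = sum(!is_d),
    event_rate_derivation = r_d,
    event_rate_validation = r_v,
    event_rate_diff_se = se_diff,
    event_rates_comparable = abs(r_d - r_v) <= 2 * se_diff
  )
  list(cohort = cohort, report = report)
}
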
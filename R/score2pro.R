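#' The SCORE2 clinical covariate set
#'
#' The clinical comparator model uses the SCORE2 covariates (age, sex,
#' smoking status, systolic blood pressure, total and HDL cholesterol) as a
#' de-novo machine-learning model; the published SCORE2 equation and
#' coefficients are not used.
#' @return character vector of covariate names.
#' @export
score2_covariates <- function() {
  c("age", "sex", "smoking", "sbp", "total_chol", "hdl")
}

# numeric feature matrix for the boosted-tree models: binary indicator for
# sex, two indicators for smoking vs never, proteins passed through as-is.
# Constant columns (e.g. sex inside a sex subgroup) are dropped.
feature_matrix <- function(cohort, clinical = character(), proteins = character()) {
  cols <- list()
  for (cl in clinical) {
    if (cl == "sex") {
      cols[["sex_male"]] <- as.numeric(cohort$sex == "male")
    } else if (cl == "smoking") {
      cols[["smoking_previous"]] <- as.numeric(cohort$smoking == "previous")
      cols[["smoking_current"]] <- as.numeric(cohort$smoking == "current")
    } else {
      cols[[cl]] <- as.numeric(cohort[[cl]])
    }
  }
  for (pr in proteins) cols[[pr]] <- cohort[[pr]]
  x <- do.call(cbind, cols)
  if (is.null(x)) stop("feature_matrix: no features requested")
  keep <- apply(x, 2L, function(v) {
    u <- unique(v[!is.na(v)]); length(u) >= 2L
  })
  x[, keep, drop = FALSE]
}

# train on derivation rows, score validation rows; returns a model card
fit_model_card <- function(cohort, rows_deriv, rows_valid, model_kind,
                           clinical = character(), proteins = character(),
                           gbm_params = list(), seed = 1L, subgroup = "overall") {
  x_d <- feature_matrix(cohort[rows_deriv, , drop = FALSE], clinical, proteins)
  x_v <- feature_matrix(cohort[rows_valid, , drop = FALSE], clinical, proteins)
  x_v <- x_v[, colnames(x_d), drop = FALSE]
  y_d <- cohort$event[rows_deriv]
  y_v <- cohort$event[rows_valid]
  model <- train_gbm(x_d, y_d, gbm_params, seed)
  structure(list(
    model_kind = model_kind, subgroup = subgroup,
    features = colnames(x_d), proteins = proteins,
    model = model,
    auc = roc_auc(predict_gbm(model, x_v), y_v),
    valid_scores = predict_gbm(model, x_v),
    deriv_scores = predict_gbm(model, x_d),
    valid_ids = cohort$id[rows_valid],
    valid_labels = y_v
  ), class = "model_card")
}

#' @export
print.model_card <- function(x, ...) {
  cat(sprintf("<model_card> %s / %s: %d features, validation AUC %.3f\n",
              x$subgroup, x$model_kind, length(x$features), x$auc))
  invisible(x)
}

#' Run the full panel pipeline inside one clinical subgroup
#'
#' Within the subgroup's derivation rows: Bonferroni-controlled Cox screen
#' (model 2 adjustment; the Bonferroni denominator is the number of proteins
#' tested in this subgroup), gradient-boosting importance ranking of the
#' significant proteins, sequential forward selection, then training of the
#' subgroup-specific protein model.  Evaluation on the subgroup's validation
#' rows compares the specific model against the clinical comparator (SCORE2
#' covariates, any variable constant within the subgroup dropped): AUC,
#' delta AUC with DeLong p, and categorical NRI at the 5% risk threshold.
#' All models of a subgroup are evaluated on exactly the same validation
#' rows (row ids recorded on the cards).
#'
#' @param cohort a prepared cohort (split assigned, proteins scaled).
#' @param spec a [subgroup_spec()], or `NULL` for the overall cohort.
#' @param sel_config a [selection_config()].
#' @param alpha family-wise level of the screen (default 0.05).
#' @param min_events minimum derivation events required (default 30);
#'   below the floor the subgroup is skipped with a report entry.
#' @param nri_threshold risk threshold of the reclassification analysis
#'   (default 0.05).
#' @param nri_boot bootstrap resamples for the NRI (default 1000).
#' @return list of class `subgroup_result`: `subgroup`, `screen` (the Cox
#'   table), `panel` (a `panel_result`), `cards` (clinical, specific,
#'   clinical_plus_protein model cards), `comparison` (one-row data.frame
#'   with AUCs, delta AUC, DeLong p, NRI bundle), `skipped`, `reason`.
#' @export
run_subgroup_pipeline <- function(cohort, spec = NULL,
                                  sel_config = selection_config(),
                                  alpha = 0.05, min_events = 30L,
                                  nri_threshold = 0.05, nri_boot = 1000L) {
  label <- if (is.null(spec)) "overall" else spec$name
  member <- if (is.null(spec)) rep(TRUE, nrow(cohort)) else
    subgroup_membership(cohort, spec)
  rows_d <- which(member & cohort$split == "derivation")
  rows_v <- which(member & cohort$split == "validation")
  skip <- function(reason) {
    structure(list(subgroup = label, screen = NULL, panel = NULL,
                   cards = NULL, comparison = NULL,
                   skipped = TRUE, reason = reason),
              class = "subgroup_result")
  }
  if (sum(cohort$event[rows_d]) < min_events) {
    return(skip(sprintf("only %d derivation events (< %d floor)",
                        sum(cohort$event[rows_d]), min_events)))
  }
  if (length(unique(cohort$event[rows_v])) < 2L) {
    return(skip("validation rows contain a single outcome class"))
  }

  screen <- screen_proteins(cohort, model = "model2", alpha = alpha,
                            rows = rows_d)
  sig <- screen$protein[screen$significant_bonferroni]
  if (length(sig) == 0L) {
    return(skip("no protein passed the Bonferroni screen"))
  }

  deriv <- cohort[rows_d, , drop = FALSE]
  ranked <- rank_importance(as.matrix(deriv[, sig, drop = FALSE]),
                            deriv$event, sel_config$gbm_params,
                            seed = sel_config$seed)
  panel <- forward_select(as.matrix(deriv[, ranked$protein, drop = FALSE]),
                          deriv$event, sel_config)
  panel$importance <- ranked

  gp <- sel_config$gbm_params
  card <- function(kind, clinical, proteins) {
    fit_model_card(cohort, rows_d, rows_v, kind, clinical, proteins,
                   gbm_params = gp, seed = sel_config$seed, subgroup = label)
  }
  cards <- list(
    clinical = card("clinical", score2_covariates(), character()),
    specific = card("specific_protein", character(), panel$selected_panel),
    clinical_plus_protein = card("clinical_plus_protein", score2_covariates(),
                                 panel$selected_panel)
  )

  cmp <- delong_compare(cards$clinical$valid_scores,
                        cards$specific$valid_scores,
                        cards$specific$valid_labels)
  nri <- categorical_nri(cards$clinical$valid_scores,
                         cards$specific$valid_scores,
                         cards$specific$valid_labels,
                         threshold = nri_threshold,
                         n_boot = nri_boot, seed = sel_config$seed)
  comparison <- data.frame(
    subgroup = label,
    n_proteins = length(panel$selected_panel),
    auc_clinical = cards$clinical$auc,
    auc_specific = cards$specific$auc,
    auc_combined = cards$clinical_plus_protein$auc,
    delta_auc = cmp$delta,
    delong_p = cmp$p,
    nri = nri$nri_overall$estimate,
    nri_lo = nri$nri_overall$ci95[1],
    nri_hi = nri$nri_overall$ci95[2],
    nri_p = nri$nri_overall$p,
    stringsAsFactors = FALSE
  )
  structure(list(subgroup = label, screen = screen, panel = panel,
                 cards = cards, comparison = comparison, nri = nri,
                 skipped = FALSE, reason = NULL),
            class = "subgroup_result")
}

#' Compare a subgroup-specific model with the general protein model
#'
#' Both models are evaluated on the identical validation rows of the
#' subgroup; the general model is retrained here on the subgroup's
#' derivation rows restricted to the general panel's proteins only if
#' `retrain = TRUE`, otherwise the general model's scores on those rows are
#' used as-is.
#'
#' @param cohort a prepared cohort.
#' @param subgroup_result a `subgroup_result` from [run_subgroup_pipeline()].
#' @param general_card a `model_card` for the general protein model trained
#'   on the overall derivation set.
#' @param nri_threshold risk threshold of the NRI (default 0.05).
#' @param nri_boot,seed bootstrap controls.
#' @return one-row data.frame: subgroup, panel sizes, both AUCs, delta AUC
#'   with DeLong p, NRI of specific vs general.
#' @export
compare_specific_vs_general <- function(cohort, subgroup_result, general_card,
                                        nri_threshold = 0.05,
                                        nri_boot = 1000L, seed = 1L) {
  stopifnot(!subgroup_result$skipped)
  spec_card <- subgroup_result$cards$specific
  ids <- spec_card$valid_ids
  idx <- match(ids, general_card$valid_ids)
  if (anyNA(idx)) stop("compare_specific_vs_general: validation rows differ")
  gen_scores <- general_card$valid_scores[idx]
  labels <- spec_card$valid_labels
  cmp <- delong_compare(gen_scores, spec_card$valid_scores, labels)
  nri <- categorical_nri(gen_scores, spec_card$valid_scores, labels,
                         threshold = nri_threshold, n_boot = nri_boot,
                         seed = seed)
  data.frame(
    subgroup = subgroup_result$subgroup,
    n_specific = length(spec_card$proteins),
    n_general = length(general_card$proteins),
    auc_general = roc_auc(gen_scores, labels),
    auc_specific = roc_auc(spec_card$valid_scores, labels),
    delta_auc = cmp$delta,
    delong_p = cmp$p,
    nri = nri$nri_overall$estimate,
    nri_p = nri$nri_overall$p,
    stringsAsFactors = FALSE
  )
}

#' Reclassification analysis in a high-risk composite subgroup
#'
#' Evaluates, on the validation rows of a composite subgroup (by default:
#' male, previous/current smoker, SBP >= 140 mmHg, non-HDL >= 4 mmol/L),
#' four reclassification contrasts against the clinical comparator:
#' the combined subgroup-panel protein model alone and with clinical
#' covariates, and the general protein model alone and with clinical
#' covariates.  The protein set of the composite model is the union of the
#' selected panels of the one-variable subgroups matching the composite's
#' sides.  The NRI threshold defaults to the observed event incidence in
#' the composite subgroup (full cohort), rounded to the nearest percent.
#'
#' @param cohort a prepared cohort.
#' @param composite a [composite_subgroup()].
#' @param subgroup_results named list of `subgroup_result`s (from the
#'   one-variable sweep); panels of the sides matching the composite are
#'   pooled.
#' @param general_panel character vector: the general model's proteins.
#' @param sel_config a [selection_config()] (gbm parameters and seed).
#' @param threshold NRI risk threshold; `NULL` (default) uses the observed
#'   composite incidence rounded to 2 decimals.
#' @param min_events minimum derivation events in the composite.
#' @param nri_boot bootstrap resamples.
#' @return list of class `highrisk_result`: `composite`, `threshold`,
#'   `observed_incidence`, `panel` (the pooled protein set), `nri` (named
#'   list of four `reclass_result`s), `table` (tidy summary data.frame).
#' @export
evaluate_high_risk <- function(cohort, composite, subgroup_results,
                               general_panel, sel_config = selection_config(),
                               threshold = NULL, min_events = 10L,
                               nri_boot = 1000L) {
  member <- composite_membership(cohort, composite)
  if (!any(member, na.rm = TRUE)) {
    stop("evaluate_high_risk: empty composite subgroup: ", composite$name)
  }
  rows_d <- which(member & cohort$split == "derivation")
  rows_v <- which(member & cohort$split == "validation")
  if (sum(cohort$event[rows_d]) < min_events ||
      length(unique(cohort$event[rows_v])) < 2L) {
    stop("evaluate_high_risk: too few events in composite subgroup ",
         composite$name)
  }
  incidence <- mean(cohort$event[member])
  if (is.null(threshold)) threshold <- round(incidence, 2)

  sides <- vapply(composite$specs, `[[`, "", "side")
  pool <- unique(unlist(lapply(subgroup_results[sides], function(r) {
    if (is.null(r) || r$skipped) character() else r$panel$selected_panel
  })))
  pool <- intersect(pool, names(cohort))
  if (length(pool) == 0L) {
    stop("evaluate_high_risk: no proteins available from the matching subgroup panels")
  }
  general_panel <- intersect(general_panel, names(cohort))

  gp <- sel_config$gbm_params
  card <- function(kind, clinical, proteins) {
    fit_model_card(cohort, rows_d, rows_v, kind, clinical, proteins,
                   gbm_params = gp, seed = sel_config$seed,
                   subgroup = composite$name)
  }
  clinical <- card("clinical", score2_covariates(), character())
  contrasts <- list(
    specific          = card("specific_protein", character(), pool),
    specific_clinical = card("clinical_plus_protein", score2_covariates(), pool),
    general           = card("general_protein", character(), general_panel),
    general_clinical  = card("clinical_plus_protein", score2_covariates(),
                             general_panel)
  )
  labels <- clinical$valid_labels
  nri <- lapply(contrasts, function(cd) {
    categorical_nri(clinical$valid_scores, cd$valid_scores, labels,
                    threshold = threshold, n_boot = nri_boot,
                    seed = sel_config$seed)
  })
  tab <- do.call(rbind, lapply(names(nri), function(nm) {
    r <- nri[[nm]]
    data.frame(model = nm,
               auc = contrasts[[nm]]$auc,
               nri = r$nri_overall$estimate,
               nri_lo = r$nri_overall$ci95[1], nri_hi = r$nri_overall$ci95[2],
               nri_p = r$nri_overall$p,
               nri_event = r$nri_event$estimate,
               nri_nonevent = r$nri_nonevent$estimate,
               stringsAsFactors = FALSE)
  }))
  structure(list(composite = composite$name, threshold = threshold,
                 observed_incidence = incidence, panel = pool,
                 auc_clinical = clinical$auc,
                 nri = nri, table = tab),
            class = "highrisk_result")
}

#' Protein-set intersections across subgroup panels
#'
#' Union of all selected proteins, per-protein subgroup counts, and the
#' exact intersection cells (which combination of subgroups each protein
#' belongs to) -- the set-membership table behind an UpSet-style display.
#'
#' @param panels named list, each element a character vector of selected
#'   proteins (or a `panel_result`).
#' @return list: `membership` (protein x subgroup incidence data.frame with
#'   `n_subgroups`), `cells` (data.frame of exact intersection signatures
#'   and their protein counts), `panel_sizes`.
#' @export
panel_intersections <- function(panels) {
  stopifnot(length(panels) >= 1L)
  panels <- lapply(panels, function(p) {
    if (inherits(p, "panel_result")) p$selected_panel else as.character(p)
  })
  union_list <- sort(unique(unlist(panels)))
  inc <- vapply(panels, function(p) union_list %in% p,
                logical(length(union_list)))
  inc <- matrix(inc, nrow = length(union_list),
                dimnames = list(union_list, names(panels)))
  membership <- data.frame(protein = union_list, inc,
                           n_subgroups = rowSums(inc),
                           row.names = NULL, check.names = FALSE)
  sig <- apply(inc, 1L, function(r) paste(colnames(inc)[r], collapse = "&"))
  cells <- as.data.frame(table(signature = sig), stringsAsFactors = FALSE)
  names(cells) <- c("signature", "n_proteins")
  cells <- cells[order(-cells$n_proteins, cells$signature), , drop = FALSE]
  list(membership = membership, cells = cells,
       panel_sizes = vapply(panels, length, 0L))
}
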
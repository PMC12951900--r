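#' Default end-to-end pipeline configuration
#'
#' A nested list with `simulation`, `prep`, `selection`, `screening`,
#' `subgroups` and `output` blocks, suitable for [run_pipeline()] and
#' round-trippable through YAML/JSON.  Any subset of fields may be
#' overridden in a user config; unknown fields are rejected.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    simulation = list(
      n_participants = 10000L, n_proteins = 200L,
      effects = list(),
      baseline_hazard = c(scale = 368, shape = 1),
      missing_rate_proteins = 0.05, missing_rate_clinical = 0.02
    ),
    prep = list(
      protein_missing_threshold = 0.25,
      derivation_fraction = 0.70,
      imputation_method = "median"
    ),
    screening = list(model = "model2", alpha = 0.05),
    selection = list(
      auc_epsilon = 0.003, plateau_length = 4L, delong_alpha = 0.05,
      gbm_params = list(nrounds = 150L, max_depth = 3L, eta = 0.1),
      eval_scheme = "holdout_within_derivation", cv_folds = 5L
    ),
    subgroups = list(
      min_events = 30L, nri_threshold = 0.05, nri_boot = 500L,
      run_sweep32 = FALSE
    ),
    highrisk = list(enabled = TRUE, min_events = 10L,
                    include_diabetes = FALSE)
  )
}

# deep-merge a partial user config over the defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (!nm %in% names(base)) stop("unknown config field: ", nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "effects" && nm != "gbm_params") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override [default_pipeline_config()]; planted
#' effects are given as a list of `{protein_index, log_hr_per_sd,
#' subgroup_variable, subgroup_side}` entries.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param seed master seed used where the file does not set one.
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  merge_config(default_pipeline_config(seed), raw)
}

config_effects <- function(effects) {
  lapply(effects, function(e) {
    cond <- NULL
    if (!is.null(e$subgroup_variable)) {
      cond <- subgroup_spec(e$subgroup_variable, e$subgroup_side)
    }
    planted_effect(e$protein_index, e$log_hr_per_sd, cond)
  })
}

#' Run the stratified proteomic risk-prediction pipeline end to end
#'
#' simulate (or load) -> prepare -> screen -> select -> evaluate:
#' the general protein panel is derived on the overall derivation set, each
#' of the ten one-variable clinical subgroups gets its own screen /
#' importance ranking / forward selection / evaluation, the selected panels
#' are intersected, and the high-risk composite reclassification analysis is
#' run.  Deterministic given the config seed.
#'
#' @param config a config list (see [default_pipeline_config()]) or a path
#'   to a YAML/JSON config file.
#' @param cohort optional pre-built cohort table; when supplied the
#'   simulation block is ignored.
#' @param out_dir optional directory; when given, the tabular outputs, the
#'   run manifest and the cohort are written there.
#' @param verbose print stage progress.
#' @return list of class `score2pro_run`: `cohort`, `prep_report`,
#'   `general` (subgroup_result of the overall cohort), `subgroups` (named
#'   list over the ten sides), `table2` (subgroup x model summary grid),
#'   `specific_vs_general`, `intersections`, `highrisk`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), cohort = NULL,
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(config$seed)
  say <- function(...) if (verbose) message(...)

  if (is.null(cohort)) {
    say("simulate: n = ", config$simulation$n_participants)
    sim_cfg <- sim_config(
      n_participants = config$simulation$n_participants,
      n_proteins = config$simulation$n_proteins,
      seed = seed,
      effects = config_effects(config$simulation$effects),
      baseline_hazard = unlist(config$simulation$baseline_hazard),
      missing_rate_proteins = config$simulation$missing_rate_proteins,
      missing_rate_clinical = config$simulation$missing_rate_clinical
    )
    cohort <- simulate_cohort(sim_cfg)
    cohort <- apply_missingness(cohort, sim_cfg, seed = seed + 1L)
  } else {
    sim_cfg <- NULL
  }

  say("prepare")
  pc <- prep_config(
    protein_missing_threshold = config$prep$protein_missing_threshold,
    derivation_fraction = config$prep$derivation_fraction,
    split_seed = seed + 2L,
    imputation_method = config$prep$imputation_method,
    impute_seed = seed + 3L
  )
  prep <- prep_cohort(cohort, pc)
  cohort <- prep$cohort

  sel_cfg <- selection_config(
    auc_epsilon = config$selection$auc_epsilon,
    plateau_length = config$selection$plateau_length,
    delong_alpha = config$selection$delong_alpha,
    gbm_params = config$selection$gbm_params,
    eval_scheme = config$selection$eval_scheme,
    cv_folds = config$selection$cv_folds,
    seed = seed + 4L
  )
  sg <- config$subgroups

  say("general model")
  general <- run_subgroup_pipeline(
    cohort, NULL, sel_cfg, alpha = config$screening$alpha,
    min_events = sg$min_events, nri_threshold = sg$nri_threshold,
    nri_boot = sg$nri_boot
  )
  if (general$skipped) stop("run_pipeline: overall pipeline skipped: ", general$reason)

  roster <- subgroup_roster()
  subgroups <- list()
  for (nm in names(roster)) {
    say("subgroup: ", nm)
    subgroups[[nm]] <- run_subgroup_pipeline(
      cohort, roster[[nm]], sel_cfg, alpha = config$screening$alpha,
      min_events = sg$min_events, nri_threshold = sg$nri_threshold,
      nri_boot = sg$nri_boot
    )
  }

  ok <- !vapply(subgroups, `[[`, TRUE, "skipped")
  table2 <- do.call(rbind, lapply(subgroups[ok], `[[`, "comparison"))
  rownames(table2) <- NULL

  svg <- do.call(rbind, lapply(subgroups[ok], function(r) {
    compare_specific_vs_general(cohort, r, general$cards$specific,
                                nri_threshold = sg$nri_threshold,
                                nri_boot = sg$nri_boot, seed = seed + 5L)
  }))
  rownames(svg) <- NULL

  inter <- panel_intersections(
    lapply(subgroups[ok], function(r) r$panel$selected_panel))

  highrisk <- NULL
  if (isTRUE(config$highrisk$enabled)) {
    say("high-risk composite")
    composite <- composite_subgroup(
      subgroup_spec("sex", "male"), subgroup_spec("smoking", "smoking"),
      subgroup_spec("sbp", "sbp_high"), subgroup_spec("non_hdl", "non_hdl_high"))
    highrisk <- tryCatch(
      evaluate_high_risk(cohort, composite, subgroups,
                         general$panel$selected_panel, sel_cfg,
                         min_events = config$highrisk$min_events,
                         nri_boot = sg$nri_boot),
      error = function(e) {
        warning("high-risk analysis skipped: ", conditionMessage(e))
        NULL
      })
  }

  sweep32 <- NULL
  if (isTRUE(sg$run_sweep32)) {
    say("32-cell sweep")
    sweep32 <- sweep_composites(cohort, subgroups,
                                general$panel$selected_panel, sel_cfg,
                                nri_boot = sg$nri_boot)
  }

  run <- structure(list(
    config = config, cohort = cohort, prep_report = prep$report,
    general = general, subgroups = subgroups, table2 = table2,
    specific_vs_general = svg, intersections = inter,
    highrisk = highrisk, sweep32 = sweep32, manifest = NULL
  ), class = "score2pro_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run_outputs(run, out_dir, sim_cfg)
  }
  run
}

#' Reclassification sweep over the 32 composite cells
#'
#' For each cell of the full five-variable cross, pools the panels of the
#' five matching one-variable subgroups and computes the NRI of the pooled
#' protein model against the clinical comparator on the cell's validation
#' rows, at a threshold equal to the cell's observed incidence.  Cells
#' below the event floor are reported as skipped.
#'
#' @param cohort prepared cohort.
#' @param subgroup_results named list of `subgroup_result`s.
#' @param general_panel general model proteins (used when no matching panel
#'   exists).
#' @param sel_config a [selection_config()].
#' @param min_events derivation event floor per cell.
#' @param nri_boot bootstrap resamples.
#' @return data.frame with one row per cell: incidence, threshold, NRI and
#'   p (NA where skipped).
#' @export
sweep_composites <- function(cohort, subgroup_results, general_panel,
                             sel_config = selection_config(),
                             min_events = 10L, nri_boot = 200L) {
  cells <- composite_sweep()
  rows <- lapply(cells, function(cmp) {
    out <- tryCatch(
      evaluate_high_risk(cohort, cmp, subgroup_results, general_panel,
                         sel_config, min_events = min_events,
                         nri_boot = nri_boot),
      error = function(e) NULL)
    if (is.null(out)) {
      return(data.frame(cell = cmp$name, n = sum(composite_membership(cohort, cmp)),
                        incidence = NA_real_, threshold = NA_real_,
                        nri = NA_real_, nri_p = NA_real_,
                        nri_nonevent = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- out$nri$specific
    data.frame(cell = cmp$name, n = sum(composite_membership(cohort, cmp)),
               incidence = out$observed_incidence, threshold = out$threshold,
               nri = r$nri_overall$estimate, nri_p = r$nri_overall$p,
               nri_nonevent = r$nri_nonevent$estimate, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# write tabular outputs + manifest; returns the manifest
write_run_outputs <- function(run, out_dir, sim_cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "NA")
    paths[[name]] <<- p
  }
  write_cohort(run$cohort, file.path(out_dir, "cohort.csv"), sim_cfg)
  paths[["cohort.csv"]] <- file.path(out_dir, "cohort.csv")
  put_csv(run$general$screen, "screening_overall.csv")
  put_csv(run$table2, "table2_subgroup_models.csv")
  put_csv(run$specific_vs_general, "specific_vs_general.csv")
  put_csv(run$intersections$membership, "panel_intersections.csv")
  if (!is.null(run$highrisk)) {
    put_csv(run$highrisk$table, "highrisk_reclassification.csv")
    counts <- do.call(rbind, lapply(names(run$highrisk$nri), function(nm) {
      cbind(model = nm, run$highrisk$nri[[nm]]$counts)
    }))
    put_csv(counts, "highrisk_reclassification_counts.csv")
  }
  if (!is.null(run$sweep32)) put_csv(run$sweep32, "sweep32.csv")
  panel_json <- file.path(out_dir, "general_panel.json")
  jsonlite::write_json(
    list(candidates = run$general$panel$candidates,
         cumulative_auc = run$general$panel$cumulative_auc,
         stop_index = run$general$panel$stop_index,
         selected_panel = run$general$panel$selected_panel),
    panel_json, auto_unbox = TRUE, digits = NA)
  paths[["general_panel.json"]] <- panel_json
  prep_json <- file.path(out_dir, "prep_report.json")
  jsonlite::write_json(run$prep_report, prep_json, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths[["prep_report.json"]] <- prep_json

  manifest <- list(
    package_version = as.character(utils::packageVersion("score2pro")),
    seed = run$config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.score2pro_run <- function(x, ...) {
  cat("<score2pro_run>\n")
  cat("  cohort:", nrow(x$cohort), "rows,", length(protein_cols(x$cohort)),
      "proteins\n")
  cat("  general panel:", paste(x$general$panel$selected_panel, collapse = ", "),
      "\n")
  cat(sprintf("  general AUC %.3f vs clinical %.3f\n",
              x$general$comparison$auc_specific,
              x$general$comparison$auc_clinical))
  cat("  subgroups run:", sum(!vapply(x$subgroups, `[[`, TRUE, "skipped")),
      "of", length(x$subgroups), "\n")
  invisible(x)
}
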
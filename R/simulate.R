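#' Simulation configuration for a synthetic proteomic survival cohort
#'
#' The generator emulates the statistical structure of a middle-aged
#' population-scale proteomic cohort: ages 40-69 (median near 58),
#' about 55% female, roughly 4% event incidence over a 15-year
#' administrative horizon, standardized protein levels with a sparse set of
#' true log-hazard effects, some of which may be conditional on a clinical
#' subgroup.  Defaults reproduce those conditions; see the methods vignette
#' for the provenance of each marginal.
#'
#' @param n_participants number of rows to simulate.
#' @param n_proteins number of protein columns (`prot_0001`, ...).
#' @param seed integer seed; the whole table is deterministic given the seed.
#' @param frac_female proportion female.
#' @param age_range two-element vector, truncation bounds in years.
#' @param age_mean_sd mean and SD of the (truncated) age normal.
#' @param smoking_probs probabilities of never/previous/current smoking,
#'   summing to 1.
#' @param sbp_mean_sd,dbp_mean_sd systolic/diastolic blood pressure normals
#'   (mmHg).
#' @param lipid_params list with `total`, `hdl`, `ldl` (mean, sd in mmol/L)
#'   and `trig_meanlog_sdlog` (log-normal parameters for triglycerides).
#' @param extra_covariate_params list with `bmi` (mean, sd), `crp_meanlog_sdlog`,
#'   `egfr` (mean, sd), `education` (mean, sd years), `diabetes_prev`.
#' @param protein_block_corr within-block equicorrelation of proteins in
#'   `[0, 1)`; 0 means independent proteins.
#' @param protein_block_size number of consecutive proteins per correlated
#'   block (1 = independent).
#' @param protein_age_sex_loading optional length-2 numeric `c(age, sex)`:
#'   linear loading of every protein on standardized age and on an indicator
#'   of male sex.  Off (`c(0, 0)`) by default so that protein effects are
#'   unconfounded; confounding is a test scenario, not the baseline.
#' @param effects list of [planted_effect()] objects: the ground-truth
#'   protein log-hazards.
#' @param baseline_hazard Weibull baseline, `c(scale, shape)` (scale in
#'   years; shape 1 = exponential).  The default scale 368 with shape 1
#'   gives a cumulative baseline incidence of about 4% at 15 years.
#' @param admin_censor_years administrative censoring horizon (years).
#' @param dropout_rate per-year exponential dropout (censoring) rate.
#' @param missing_rate_proteins,missing_rate_clinical MCAR masking rates
#'   used by [apply_missingness()].
#' @param n_regions number of exchangeable region labels (fold-assignment
#'   device for leave-one-region-out CV); regions carry no effect.
#'
#' @return object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [planted_effect()]
#' @export
sim_config <- function(n_participants = 10000,
                       n_proteins = 200,
                       seed = 1L,
                       frac_female = 0.549,
                       age_range = c(40, 69),
                       age_mean_sd = c(56.5, 8.1),
                       smoking_probs = c(never = 0.55, previous = 0.345, current = 0.105),
                       sbp_mean_sd = c(139, 19),
                       dbp_mean_sd = c(82, 10),
                       lipid_params = list(
                         total = c(5.65, 1.11),
                         hdl = c(1.45, 0.37),
                         ldl = c(3.5, 0.89),
                         trig_meanlog_sdlog = c(log(1.5), 0.55)
                       ),
                       extra_covariate_params = list(
                         bmi = c(27.2, 4.2),
                         crp_meanlog_sdlog = c(log(1.3), 1.0),
                         egfr = c(101, 24),
                         education = c(15, 5.5),
                         diabetes_prev = 0.053
                       ),
                       protein_block_corr = 0,
                       protein_block_size = 1L,
                       protein_age_sex_loading = c(0, 0),
                       effects = list(),
                       baseline_hazard = c(scale = 368, shape = 1),
                       admin_censor_years = 15,
                       dropout_rate = 0.01,
                       missing_rate_proteins = 0.05,
                       missing_rate_clinical = 0.02,
                       n_regions = 10L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_proteins = as.integer(n_proteins),
    seed = as.integer(seed),
    frac_female = frac_female,
    age_range = age_range,
    age_mean_sd = age_mean_sd,
    smoking_probs = smoking_probs,
    sbp_mean_sd = sbp_mean_sd,
    dbp_mean_sd = dbp_mean_sd,
    lipid_params = lipid_params,
    extra_covariate_params = extra_covariate_params,
    protein_block_corr = protein_block_corr,
    protein_block_size = as.integer(protein_block_size),
    protein_age_sex_loading = protein_age_sex_loading,
    effects = effects,
    baseline_hazard = baseline_hazard,
    admin_censor_years = admin_censor_years,
    dropout_rate = dropout_rate,
    missing_rate_proteins = missing_rate_proteins,
    missing_rate_clinical = missing_rate_clinical,
    n_regions = as.integer(n_regions)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1L,
    cfg$n_proteins >= 0L,
    cfg$frac_female >= 0, cfg$frac_female <= 1,
    length(cfg$smoking_probs) == 3L,
    all(cfg$smoking_probs >= 0), all(cfg$smoking_probs <= 1),
    abs(sum(cfg$smoking_probs) - 1) < 1e-8,
    cfg$age_range[1] < cfg$age_range[2],
    cfg$age_mean_sd[2] > 0, cfg$sbp_mean_sd[2] > 0, cfg$dbp_mean_sd[2] > 0,
    all(vapply(cfg$lipid_params[c("total", "hdl", "ldl")],
               function(p) p[2] > 0, TRUE)),
    cfg$protein_block_corr >= 0, cfg$protein_block_corr < 1,
    cfg$protein_block_size >= 1L,
    length(cfg$protein_age_sex_loading) == 2L,
    cfg$baseline_hazard[1] > 0, cfg$baseline_hazard[2] > 0,
    cfg$admin_censor_years > 0,
    cfg$dropout_rate >= 0,
    cfg$missing_rate_proteins >= 0, cfg$missing_rate_proteins < 1,
    cfg$missing_rate_clinical >= 0, cfg$missing_rate_clinical < 1,
    cfg$n_regions >= 1L
  )
  for (eff in cfg$effects) {
    stopifnot(inherits(eff, "planted_effect"))
    if (eff$protein_index < 1L || eff$protein_index > cfg$n_proteins) {
      stop("planted effect protein_index out of range")
    }
  }
  # implied null incidence at the administrative horizon must be interior
  p0 <- 1 - exp(-(cfg$admin_censor_years / cfg$baseline_hazard[[1]])^cfg$baseline_hazard[[2]])
  if (p0 <= 0 || p0 >= 1) {
    stop("baseline hazard implies degenerate (0 or 1) event fraction")
  }
  invisible(cfg)
}

#' A planted ground-truth protein hazard
#'
#' @param protein_index 1-based protein column index.
#' @param log_hr_per_sd log hazard ratio per 1-SD increase of the protein.
#' @param subgroup_condition optional [subgroup_spec()]; when given, the
#'   effect applies only to participants in that subgroup side (log-HR 0
#'   elsewhere, unless another planted effect covers the other side).
#' @return object of class `planted_effect`.
#' @export
#' @examples
#' planted_effect(1, log(1.64))                     # everywhere
#' planted_effect(2, 0.5, subgroup_spec("sex", "female"))  # females only
planted_effect <- function(protein_index, log_hr_per_sd,
                           subgroup_condition = NULL) {
  stopifnot(is.finite(log_hr_per_sd), protein_index >= 1)
  if (!is.null(subgroup_condition)) {
    stopifnot(inherits(subgroup_condition, "subgroup_spec"))
  }
  structure(list(protein_index = as.integer(protein_index),
                 log_hr_per_sd = log_hr_per_sd,
                 subgroup_condition = subgroup_condition),
            class = "planted_effect")
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  # inverse-CDF truncated normal: exact, vectorized, no rejection loop
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

protein_names <- function(n) sprintf("prot_%04d", seq_len(n))

#' Names of the protein columns of a cohort table
#' @param cohort a cohort table.
#' @return character vector of protein column names.
#' @export
protein_cols <- function(cohort) {
  grep("^prot_", names(cohort), value = TRUE)
}

# clinical columns eligible for MCAR masking / imputation
clinical_cols <- function() {
  c("age", "smoking", "sbp", "dbp", "total_chol", "hdl", "ldl",
    "triglycerides", "bmi", "crp", "egfr", "education", "diabetes")
}

#' Simulate a proteomic survival cohort
#'
#' Draws covariates from the configured marginals, proteins from a standard
#' normal (optionally block-equicorrelated and/or loaded on age/sex), and
#' event times from a Weibull proportional-hazards model whose linear
#' predictor is the sum of the planted protein log-hazards (evaluated on the
#' standardized protein scale, subgroup-conditionally where configured).
#' Censoring is the minimum of the administrative horizon and an exponential
#' dropout draw.  The result is complete (no missing values); use
#' [apply_missingness()] to overlay MCAR missingness.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` cohort table: `id`, clinical covariates, `non_hdl`
#'   (= total - HDL cholesterol), `region`, protein columns, `follow_time`
#'   (years), `event` (0/1), `split` (all `"unassigned"`).  The attribute
#'   `proteins_scaled` records that protein values are on the standardized
#'   (mean-0, SD-1 population) scale.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  p <- config$n_proteins

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  sex <- factor(ifelse(stats::runif(n) < config$frac_female, "female", "male"),
                levels = c("female", "male"))
  age <- rtruncnorm1(n, config$age_mean_sd[1], config$age_mean_sd[2],
                     config$age_range[1], config$age_range[2])
  smoking <- factor(sample(c("never", "previous", "current"), n, replace = TRUE,
                           prob = config$smoking_probs),
                    levels = c("never", "previous", "current"))
  sbp <- rtruncnorm1(n, config$sbp_mean_sd[1], config$sbp_mean_sd[2], 70, 250)
  dbp <- rtruncnorm1(n, config$dbp_mean_sd[1], config$dbp_mean_sd[2], 40, 150)
  lp <- config$lipid_params
  total_chol <- rtruncnorm1(n, lp$total[1], lp$total[2], 2.5, 12)
  hdl <- rtruncnorm1(n, lp$hdl[1], lp$hdl[2], 0.4, 3.5)
  ldl <- rtruncnorm1(n, lp$ldl[1], lp$ldl[2], 0.5, 8)
  triglycerides <- stats::rlnorm(n, lp$trig_meanlog_sdlog[1], lp$trig_meanlog_sdlog[2])
  ep <- config$extra_covariate_params
  bmi <- rtruncnorm1(n, ep$bmi[1], ep$bmi[2], 15, 60)
  crp <- stats::rlnorm(n, ep$crp_meanlog_sdlog[1], ep$crp_meanlog_sdlog[2])
  egfr <- rtruncnorm1(n, ep$egfr[1], ep$egfr[2], 15, 200)
  education <- round(rtruncnorm1(n, ep$education[1], ep$education[2], 0, 25))
  diabetes <- as.integer(stats::runif(n) < ep$diabetes_prev)
  region <- factor(sprintf("region%02d", sample.int(config$n_regions, n, replace = TRUE)),
                   levels = sprintf("region%02d", seq_len(config$n_regions)))

  # proteins: standard normal, optional block equicorrelation via one
  # shared factor per block, optional linear age/sex loading
  prot <- matrix(stats::rnorm(n * p), nrow = n)
  if (p > 0 && config$protein_block_corr > 0 && config$protein_block_size > 1L) {
    rho <- config$protein_block_corr
    block <- (seq_len(p) - 1L) %/% config$protein_block_size
    for (b in unique(block)) {
      idx <- which(block == b)
      z <- stats::rnorm(n)
      prot[, idx] <- sqrt(rho) * z + sqrt(1 - rho) * prot[, idx]
    }
  }
  if (p > 0 && any(config$protein_age_sex_loading != 0)) {
    la <- config$protein_age_sex_loading
    z_age <- (age - mean(age)) / stats::sd(age)
    z_sex <- as.numeric(sex == "male")
    prot <- prot + la[1] * z_age + la[2] * z_sex
  }
  colnames(prot) <- protein_names(p)

  cohort <- data.frame(
    id = seq_len(n), age = age, sex = sex, smoking = smoking,
    sbp = sbp, dbp = dbp, total_chol = total_chol, hdl = hdl, ldl = ldl,
    triglycerides = triglycerides, non_hdl = total_chol - hdl,
    bmi = bmi, crp = crp, egfr = egfr, education = education,
    diabetes = diabetes, region = region
  )

  # linear predictor from planted effects (proteins are already on the
  # standardized scale by construction)
  eta <- numeric(n)
  for (eff in config$effects) {
    x <- prot[, eff$protein_index]
    if (is.null(eff$subgroup_condition)) {
      eta <- eta + eff$log_hr_per_sd * x
    } else {
      m <- subgroup_membership(cohort, eff$subgroup_condition)
      eta <- eta + ifelse(m, eff$log_hr_per_sd, 0) * x
    }
  }

  # Weibull PH inversion: S(t|eta) = exp(-(t/scale)^shape * e^eta)
  scale <- config$baseline_hazard[[1]]
  shape <- config$baseline_hazard[[2]]
  u <- stats::runif(n)
  event_time <- scale * (-log(u) / exp(eta))^(1 / shape)
  cens <- if (config$dropout_rate > 0) {
    pmin(config$admin_censor_years, stats::rexp(n, config$dropout_rate))
  } else {
    rep(config$admin_censor_years, n)
  }
  cohort$follow_time <- pmin(event_time, cens)
  cohort$event <- as.integer(event_time <= cens)
  cohort$split <- factor(rep("unassigned", n),
                         levels = c("derivation", "validation", "unassigned"))

  cohort <- cbind(cohort, as.data.frame(prot))
  attr(cohort, "proteins_scaled") <- TRUE

  inc <- mean(cohort$event)
  if (inc < 0.001 || inc > 0.5) {
    warning(sprintf("empirical event incidence %.4f outside [0.001, 0.5]", inc))
  }
  cohort
}

#' Overlay MCAR missingness on a cohort
#'
#' Masks protein and clinical columns completely at random at the configured
#' rates.  `follow_time`, `event`, `sex`, `id`, `region`, `split` and the
#' derived `non_hdl` are never masked (`non_hdl` is recomputed by
#' [derive_variables()] after imputation).
#'
#' @param cohort a cohort table.
#' @param config a [sim_config()] supplying `missing_rate_proteins` and
#'   `missing_rate_clinical`.
#' @param seed integer seed for the masking draws.
#' @return the cohort with `NA`s inserted.
#' @export
apply_missingness <- function(cohort, config, seed = config$seed) {
  stopifnot(config$missing_rate_proteins >= 0, config$missing_rate_proteins < 1,
            config$missing_rate_clinical >= 0, config$missing_rate_clinical < 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- nrow(cohort)
  mask_cols <- function(cols, rate) {
    if (rate <= 0) return()
    for (cl in cols) {
      hit <- stats::runif(n) < rate
      cohort[[cl]][hit] <<- NA
    }
  }
  mask_cols(protein_cols(cohort), config$missing_rate_proteins)
  mask_cols(intersect(clinical_cols(), names(cohort)),
            config$missing_rate_clinical)
  cohort
}

#' Write / read a cohort table as delimited text
#'
#' Comma-separated, header row, UTF-8, `"NA"` for missing.  `write_cohort`
#' also writes a JSON sidecar (`<path>.json`) with the simulation config and
#' the planted-effect ground truth when a config is supplied.
#'
#' @param cohort a cohort table.
#' @param path output CSV path.
#' @param config optional [sim_config()] recorded in the sidecar.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: the cohort
#'   data.frame with factor levels and attributes restored.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  if (!is.null(config)) {
    side <- function(e) if (is.null(e$subgroup_condition)) NULL else
      list(variable = e$subgroup_condition$variable,
           side = e$subgroup_condition$side)
    truth <- lapply(config$effects, function(e)
      list(protein_index = e$protein_index,
           log_hr_per_sd = e$log_hr_per_sd,
           subgroup_condition = side(e)))
    meta <- unclass(config)
    meta$effects <- truth
    meta$proteins_scaled <- isTRUE(attr(cohort, "proteins_scaled"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                            fileEncoding = "UTF-8")
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  cohort$smoking <- factor(cohort$smoking,
                           levels = c("never", "previous", "current"))
  cohort$region <- factor(cohort$region)
  cohort$split <- factor(cohort$split,
                         levels = c("derivation", "validation", "unassigned"))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(cohort, "proteins_scaled") <- isTRUE(meta$proteins_scaled)
  }
  cohort
}
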
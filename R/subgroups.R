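#' Clinical subgroup stratification rules
#'
#' The stratified framework splits a cohort along the five SCORE2
#' stratification variables, each into two sides:
#' sex (female vs male), age (< 60 middle-aged vs >= 60 elderly),
#' smoking (never vs previous/current), systolic blood pressure
#' (< 140 vs >= 140 mmHg) and non-HDL cholesterol (< 4 vs >= 4 mmol/L).
#' A `subgroup_spec` names one side of one variable.
#'
#' @param variable one of `"sex"`, `"age"`, `"smoking"`, `"sbp"`, `"non_hdl"`.
#' @param side which side of the split; see Details for the valid names.
#'
#' @details Valid sides per variable:
#' * `sex`: `"female"`, `"male"`
#' * `age`: `"middle_aged"` (< 60 y), `"elderly"` (>= 60 y)
#' * `smoking`: `"non_smoking"` (never), `"smoking"` (previous or current)
#' * `sbp`: `"sbp_low"` (< 140 mmHg), `"sbp_high"` (>= 140 mmHg)
#' * `non_hdl`: `"non_hdl_low"` (< 4 mmol/L), `"non_hdl_high"` (>= 4 mmol/L)
#'
#' @return an object of class `subgroup_spec` with fields `name`, `variable`,
#'   `side`.
#' @export
#' @examples
#' subgroup_spec("sex", "female")
#' subgroup_spec("sbp", "sbp_high")
subgroup_spec <- function(variable, side) {
  variable <- match.arg(variable, names(.subgroup_sides))
  side <- match.arg(side, .subgroup_sides[[variable]])
  structure(list(name = side, variable = variable, side = side),
            class = "subgroup_spec")
}

.subgroup_sides <- list(
  sex     = c("female", "male"),
  age     = c("middle_aged", "elderly"),
  smoking = c("non_smoking", "smoking"),
  sbp     = c("sbp_low", "sbp_high"),
  non_hdl = c("non_hdl_low", "non_hdl_high")
)

#' @export
print.subgroup_spec <- function(x, ...) {
  cat("<subgroup_spec>", x$variable, "/", x$side, "\n")
  invisible(x)
}

#' The ten one-variable clinical subgroups
#'
#' @return named list of the ten `subgroup_spec` objects (both sides of each
#'   of the five stratification variables), in roster order.
#' @export
subgroup_roster <- function() {
  specs <- lapply(names(.subgroup_sides), function(v) {
    lapply(.subgroup_sides[[v]], function(s) subgroup_spec(v, s))
  })
  specs <- unlist(specs, recursive = FALSE)
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Membership of cohort rows in one subgroup side
#'
#' Boundary conventions follow the stratification rules: age 59 is
#' middle-aged, SBP 139 is the low side, non-HDL exactly 4.0 is the high side.
#'
#' @param cohort a cohort table (see [simulate_cohort()]).
#' @param spec a [subgroup_spec()].
#' @return logical vector, one element per row; `NA` where the stratification
#'   variable is missing.
#' @export
subgroup_membership <- function(cohort, spec) {
  stopifnot(inherits(spec, "subgroup_spec"))
  switch(spec$side,
    female       = cohort$sex == "female",
    male         = cohort$sex == "male",
    middle_aged  = cohort$age < 60,
    elderly      = cohort$age >= 60,
    non_smoking  = cohort$smoking == "never",
    smoking      = cohort$smoking %in% c("previous", "current"),
    sbp_low      = cohort$sbp < 140,
    sbp_high     = cohort$sbp >= 140,
    non_hdl_low  = cohort$non_hdl < 4,
    non_hdl_high = cohort$non_hdl >= 4
  )
}

#' Composite subgroup: a conjunction of one-variable sides
#'
#' @param ... `subgroup_spec` objects (or a single list of them), at most one
#'   per variable.
#' @param name optional label; defaults to the sides joined by `&`.
#' @return object of class `composite_subgroup`.
#' @export
#' @examples
#' # the high-risk composite: male smokers with elevated SBP and non-HDL
#' composite_subgroup(subgroup_spec("sex", "male"),
#'                    subgroup_spec("smoking", "smoking"),
#'                    subgroup_spec("sbp", "sbp_high"),
#'                    subgroup_spec("non_hdl", "non_hdl_high"))
composite_subgroup <- function(..., name = NULL) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "subgroup_spec")) {
    specs <- specs[[1]]
  }
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "subgroup_spec")))
  vars <- vapply(specs, `[[`, "", "variable")
  if (anyDuplicated(vars)) {
    stop("composite_subgroup: at most one side per variable")
  }
  if (is.null(name)) {
    name <- paste(vapply(specs, `[[`, "", "side"), collapse = "&")
  }
  structure(list(name = name, specs = specs), class = "composite_subgroup")
}

#' @rdname subgroup_membership
#' @export
composite_membership <- function(cohort, composite) {
  stopifnot(inherits(composite, "composite_subgroup"))
  m <- Reduce(`&`, lapply(composite$specs, subgroup_membership, cohort = cohort))
  m
}

#' Assign every participant to subgroup sides and composite cells
#'
#' Produces the per-row membership flags for the ten one-variable subgroups
#' plus the label of the participant's cell among the 2^5 = 32 composite
#' cells.  Each row belongs to exactly one side of each variable and exactly
#' one cell (given non-missing stratification variables, i.e. post-imputation).
#'
#' @param cohort a cohort table with `sex`, `age`, `smoking`, `sbp`,
#'   `non_hdl` non-missing.
#' @return data.frame with one logical column per subgroup side (named as in
#'   [subgroup_roster()]) and a `cell` factor with 32 levels
#'   (sides joined by `&` in variable order).
#' @export
assign_subgroups <- function(cohort) {
  roster <- subgroup_roster()
  flags <- vapply(roster, subgroup_membership, logical(nrow(cohort)),
                  cohort = cohort)
  flags <- as.data.frame(flags)
  if (anyNA(flags)) {
    stop("assign_subgroups: stratification variables contain missing values; impute first")
  }
  side_of <- function(v) {
    s <- .subgroup_sides[[v]]
    ifelse(flags[[s[1]]], s[1], s[2])
  }
  cell <- do.call(paste, c(lapply(names(.subgroup_sides), side_of), sep = "&"))
  flags$cell <- factor(cell, levels = .cell_levels())
  flags
}

#' All 32 composite subgroups of the stratification sweep
#'
#' @return named list of 32 `composite_subgroup` objects, one per cell of the
#'   full cross of the five binary stratification variables.
#' @export
composite_sweep <- function() {
  grid <- .cell_grid()
  out <- lapply(seq_len(nrow(grid)), function(i) {
    specs <- lapply(names(.subgroup_sides),
                    function(v) subgroup_spec(v, grid[i, v]))
    composite_subgroup(specs)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# full cross of the five binary variables, in a fixed canonical order
.cell_grid <- function() {
  grid <- do.call(expand.grid,
                  c(rev(.subgroup_sides),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  grid[, names(.subgroup_sides), drop = FALSE]
}

.cell_levels <- function() {
  apply(.cell_grid(), 1L, paste, collapse = "&")
}
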
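#' Panel-selection configuration
#'
#' @param auc_epsilon minimum AUC gain counting as an improvement
#'   (default 0.003).
#' @param plateau_length number of consecutive non-improving steps that
#'   stops the forward selection (default 4).
#' @param delong_alpha significance level of the DeLong test inside the
#'   stopping rule (default 0.05).
#' @param gbm_params gradient-boosting hyperparameters: list with `nrounds`,
#'   `max_depth`, `eta`, and optionally `subsample` / `colsample_bytree`
#'   (conservative defaults: 500 trees, depth 3, learning rate 0.05, no
#'   subsampling -- the learner is then fully deterministic; subsampling
#'   below 1 makes fits seed-dependent).
#' @param eval_scheme how the selection AUC is computed on the derivation
#'   rows: `"derivation_cv"` (out-of-fold prediction, default) or
#'   `"holdout_within_derivation"` (a single random split inside the
#'   derivation set).  In-sample AUC of a boosted tree is near 1 and would
#'   break the stopping rule, so both schemes score held-out rows.
#' @param cv_folds folds for `"derivation_cv"` (default 5).
#' @param holdout_fraction held-out fraction for the holdout scheme.
#' @param baseline comparison baseline of the stopping rule: the best panel
#'   so far (`"best"`, default) or the immediately preceding step
#'   (`"previous"`).
#' @param improvement_rule what counts as an improving step against the
#'   baseline: `"significant_and_material"` (default) requires the DeLong
#'   test to be significant at `delong_alpha` *and* the AUC gain to reach
#'   `auc_epsilon`; `"significant_or_material"` accepts either.  The strict
#'   default keeps panels minimal: a gain a paired DeLong test cannot
#'   distinguish from zero does not extend the panel.
#' @param seed integer seed controlling fold assignment and the learner.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(auc_epsilon = 0.003,
                             plateau_length = 4L,
                             delong_alpha = 0.05,
                             gbm_params = list(nrounds = 500L, max_depth = 3L,
                                               eta = 0.05),
                             eval_scheme = c("derivation_cv",
                                             "holdout_within_derivation"),
                             cv_folds = 5L,
                             holdout_fraction = 0.3,
                             baseline = c("best", "previous"),
                             improvement_rule = c("significant_and_material",
                                                  "significant_or_material"),
                             seed = 1L) {
  stopifnot(auc_epsilon > 0 || is.infinite(auc_epsilon),
            plateau_length >= 1L, delong_alpha > 0, delong_alpha < 1,
            cv_folds >= 2L, holdout_fraction > 0, holdout_fraction < 1)
  structure(list(
    auc_epsilon = auc_epsilon,
    plateau_length = as.integer(plateau_length),
    delong_alpha = delong_alpha,
    gbm_params = utils::modifyList(
      list(nrounds = 500L, max_depth = 3L, eta = 0.05), gbm_params),
    eval_scheme = match.arg(eval_scheme),
    cv_folds = as.integer(cv_folds),
    holdout_fraction = holdout_fraction,
    baseline = match.arg(baseline),
    improvement_rule = match.arg(improvement_rule),
    seed = as.integer(seed)
  ), class = "selection_config")
}

#' Train a gradient-boosting classifier
#'
#' Thin deterministic wrapper around [xgboost::xgb.train()] (binary logistic
#' objective, single thread, fixed seed).  Missing feature values are
#' handled natively by the tree learner.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param gbm_params list with `nrounds`, `max_depth`, `eta`.
#' @param seed integer seed.
#' @return an `xgb.Booster`.
#' @export
train_gbm <- function(x, y, gbm_params = list(), seed = 1L) {
  if (length(unique(y)) < 2L) stop("train_gbm: both classes required")
  gp <- utils::modifyList(list(nrounds = 500L, max_depth = 3L, eta = 0.05),
                          gbm_params)
  nrounds <- gp$nrounds
  gp$nrounds <- NULL
  params <- c(list(objective = "binary:logistic", nthread = 1, seed = seed), gp)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' @rdname train_gbm
#' @param model an `xgb.Booster` from [train_gbm()].
#' @param newx feature matrix with the same columns as at training.
#' @return predicted event probabilities.
#' @export
predict_gbm <- function(model, newx) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(newx), nthread = 1))
}

#' Rank candidate proteins by gradient-boosting importance
#'
#' Trains one classifier on all candidate proteins (protein features only)
#' and ranks them by total split-gain importance, descending; proteins the
#' model never split on receive gain 0; ties are broken by column position
#' for determinism.
#'
#' @param x numeric matrix of candidate protein columns (derivation rows).
#' @param y 0/1 event labels.
#' @param gbm_params,seed passed to [train_gbm()].
#' @return data.frame `protein`, `gain`, in rank order.
#' @export
rank_importance <- function(x, y, gbm_params = list(), seed = 1L) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1L)
  if (length(unique(y)) < 2L) stop("rank_importance: both classes required")
  if (ncol(x) == 1L) {
    return(data.frame(protein = colnames(x), gain = 1,
                      stringsAsFactors = FALSE))
  }
  model <- train_gbm(x, y, gbm_params, seed)
  imp <- tryCatch(xgboost::xgb.importance(model = model), error = function(e) {
    # some builds fail on degenerate models; aggregate gain from the dump
    tr <- xgboost::xgb.model.dt.tree(model = model)
    tr <- tr[tr$Feature != "Leaf", c("Feature", "Gain")]
    agg <- stats::aggregate(Gain ~ Feature, data = tr, FUN = sum)
    agg$Gain <- agg$Gain / sum(agg$Gain)
    agg
  })
  gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp) && nrow(imp) > 0) gain[imp$Feature] <- imp$Gain
  ord <- order(-gain, seq_along(gain))
  data.frame(protein = colnames(x)[ord], gain = unname(gain[ord]),
             stringsAsFactors = FALSE)
}

# out-of-fold (or holdout) selection scores for a feature subset
selection_scores <- function(x, y, config) {
  gp <- config$gbm_params
  n <- length(y)
  scores <- rep(NA_real_, n)
  if (config$eval_scheme == "derivation_cv") {
    folds <- make_folds(y, config$cv_folds, config$seed)
    for (k in seq_len(config$cv_folds)) {
      test <- folds == k
      model <- train_gbm(x[!test, , drop = FALSE], y[!test], gp, config$seed)
      scores[test] <- predict_gbm(model, x[test, , drop = FALSE])
    }
    eval_rows <- rep(TRUE, n)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
    test <- seq_len(n) %in% sample.int(n, round(config$holdout_fraction * n))
    if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L) {
      stop("selection_scores: holdout split left a single class")
    }
    model <- train_gbm(x[!test, , drop = FALSE], y[!test], gp, config$seed)
    scores[test] <- predict_gbm(model, x[test, , drop = FALSE])
    eval_rows <- test
  }
  list(scores = scores[eval_rows], eval_rows = eval_rows)
}

# stratified fold assignment, deterministic given seed
make_folds <- function(y, k, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Sequential forward panel selection with a DeLong/AUC plateau rule
#'
#' Adds importance-ranked candidates one at a time, retraining the
#' classifier on the top-k proteins and scoring held-out derivation rows at
#' each step.  Each step's AUC is compared against the baseline panel (the
#' best-so-far panel by default, or the previous step) with a paired DeLong
#' test; under the default improvement rule a step *improves* when the test
#' is significant at `delong_alpha` and the AUC gain reaches `auc_epsilon`
#' (see [selection_config()] for the alternative either/or rule).  Selection
#' stops after `plateau_length` consecutive non-improving steps; the
#' selected panel is the prefix ending at the last improving step.  If the
#' candidate list is exhausted before the plateau triggers, all candidates
#' are returned with a `no_plateau` flag.
#'
#' @param x numeric matrix whose columns are the candidates in importance
#'   order (derivation rows).
#' @param y 0/1 event labels.
#' @param config a [selection_config()].
#' @return list of class `panel_result`: `candidates`, `cumulative_auc`
#'   (AUC trace over evaluated steps), `stop_index`, `selected_panel`,
#'   `delong_p` (per-step p vs baseline), `no_plateau`, `eval_scheme`.
#' @export
forward_select <- function(x, y, config = selection_config()) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1L)
  candidates <- colnames(x)
  if (is.null(candidates)) candidates <- paste0("V", seq_len(ncol(x)))
  n_cand <- ncol(x)

  aucs <- numeric(0)
  pvals <- numeric(0)
  score_list <- list()
  best_idx <- 1L
  run <- 0L
  stopped <- FALSE
  eval_labels <- NULL

  for (k in seq_len(n_cand)) {
    sel <- selection_scores(x[, seq_len(k), drop = FALSE], y, config)
    if (is.null(eval_labels)) eval_labels <- y[sel$eval_rows]
    score_list[[k]] <- sel$scores
    aucs[k] <- roc_auc(sel$scores, eval_labels)
    if (k == 1L) {
      pvals[k] <- NA_real_
      next
    }
    base <- if (config$baseline == "best") best_idx else k - 1L
    cmp <- delong_compare(score_list[[base]], sel$scores, eval_labels)
    pvals[k] <- cmp$p
    gain <- aucs[k] - aucs[base]
    # significant: the step beats the baseline by a paired DeLong test
    # (a significantly WORSE step never counts); material: the gain
    # reaches auc_epsilon
    significant <- (cmp$p < config$delong_alpha) && (gain > 0)
    material <- gain >= config$auc_epsilon
    improved <- if (config$improvement_rule == "significant_and_material") {
      significant && material
    } else {
      significant || material
    }
    if (improved) {
      run <- 0L
      best_idx <- k
    } else {
      run <- run + 1L
    }
    if (run >= config$plateau_length) {
      stopped <- TRUE
      break
    }
  }

  stop_index <- best_idx
  structure(list(
    candidates = candidates,
    cumulative_auc = aucs,
    delong_p = pvals,
    stop_index = stop_index,
    selected_panel = candidates[seq_len(stop_index)],
    no_plateau = !stopped && n_cand > 1L,
    eval_scheme = config$eval_scheme
  ), class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("<panel_result> ", length(x$selected_panel), " of ", length(x$candidates),
      " candidates selected", if (x$no_plateau) " (no plateau reached)", "\n",
      sep = "")
  cat("panel:", paste(x$selected_panel, collapse = ", "), "\n")
  cat("AUC trace:", paste(sprintf("%.3f", x$cumulative_auc), collapse = " "), "\n")
  invisible(x)
}
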
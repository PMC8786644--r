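#' Stratified cross-validation folds
#'
#' Assigns each patient to one of `k` folds so that every fold holds
#' approximately the same proportion of censored and uncensored patients.
#'
#' @param event Event flags (1 = uncensored).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels in `1..k`, aligned with `event`.
#' @export
stratified_folds <- function(event, k, seed = 1L) {
  stopifnot(k >= 2)
  set.seed(seed)
  folds <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified train/test split
#'
#' Splits one cohort 80/20 (by default) stratified on event status, or a
#' list of cohorts where each cohort is split separately (stratification by
#' cohort-by-event), so training and test sets carry approximately the same
#' censoring proportions. Per-stratum test counts are `round(fraction * n)`.
#'
#' @param datasets A single [cohort_dataset()] or a list of them.
#' @param test_fraction Fraction of each stratum assigned to the test set
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` of patient ids
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(datasets, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (inherits(datasets, "cohort_dataset")) datasets <- list(datasets)
  set.seed(seed)
  train <- character(); test <- character()
  for (ds in datasets) {
    for (lev in unique(ds$clinical$event)) {
      ids <- ds$clinical$patient_id[ds$clinical$event == lev]
      n_test <- round(test_fraction * length(ids))
      if (length(ids) - n_test < 1L) {
        stop(sprintf("stratum too small in cohort %s (event=%s): %d patients",
                     ds$cohort, lev, length(ids)))
      }
      ts <- if (n_test > 0L) sample(ids, n_test) else character()
      test <- c(test, ts)
      train <- c(train, setdiff(ids, ts))
    }
  }
  list(train = train, test = test)
}

#' Cross-validated random-search hyperparameter tuning
#'
#' Evaluates each candidate hyperparameter set by stratified `k_folds`-fold
#' cross-validation on the training data, scoring each fold's held-out
#' split with the concordance index, and returns the candidate with the
#' highest mean CV C-index (ties broken by candidate order).
#'
#' @param expression Training patients-by-genes matrix (already restricted to
#'   the selected genes).
#' @param time,event Survival outcome aligned with rows.
#' @param candidates Data frame of hyperparameter sets
#'   (see [sample_hyperparameter_sets()]).
#' @param k_folds Folds (default 4).
#' @param seed Integer seed.
#' @return List with `best` (one-row data frame) and `cv_table`
#'   (`candidate_id`, `fold`, `c_index`; one row per candidate-fold pair).
#' @export
tune_hyperparameters <- function(expression, time, event, candidates,
                                 k_folds = 4L, seed = 1L) {
  stopifnot(nrow(candidates) >= 1)
  folds <- stratified_folds(event, k_folds, seed = derive_seed(seed, 0L))
  for (fold in seq_len(k_folds)) {
    if (!any(event[folds != fold] == 1) || !any(event[folds == fold] == 1)) {
      stop("fold without uncensored patients; reduce k_folds or enlarge data")
    }
  }
  cv <- expand.grid(candidate_id = candidates$candidate_id,
                    fold = seq_len(k_folds))
  cv$c_index <- NA_real_
  for (ci in seq_len(nrow(candidates))) {
    hp <- candidates[ci, , drop = FALSE]
    for (fold in seq_len(k_folds)) {
      tr <- folds != fold
      fit <- train_cox_boosting(expression[tr, , drop = FALSE],
                                time[tr], event[tr], hp = hp,
                                seed = derive_seed(seed, ci * 100L + fold))
      risks <- predict_risk(fit, expression[!tr, , drop = FALSE])
      cidx <- concordance_index(risks, time[!tr], event[!tr])
      cv$c_index[cv$candidate_id == hp$candidate_id & cv$fold == fold] <- cidx
    }
  }
  mean_ci <- tapply(cv$c_index, cv$candidate_id, mean)
  mean_ci <- mean_ci[as.character(candidates$candidate_id)]  # candidate order
  best <- candidates[which.max(mean_ci), , drop = FALSE]
  list(best = best, cv_table = cv, mean_c_index = mean_ci)
}

#' Default pipeline configuration
#'
#' Full-scale defaults mirror the analysis design (100 replications, 20%
#' test fraction, 500 selected genes, 500 hyperparameter candidates, 4-fold
#' CV, 20 size-limited models per selection fold); any entry can be
#' overridden for reduced-scale runs.
#'
#' @param ... Named overrides.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_replications = 100L, test_fraction = 0.2, n_select = 500L,
              k_folds = 4L, models_per_fold = 20L, n_candidates = 500L,
              hp_ranges = default_hp_ranges())
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

pool_cohorts <- function(datasets, ids) {
  X <- do.call(rbind, lapply(datasets, function(d) d$expression))
  clin <- do.call(rbind, lapply(datasets, function(d) d$clinical))
  keep <- clin$patient_id %in% ids
  list(expression = X[clin$patient_id[keep], , drop = FALSE],
       clinical = clin[keep, , drop = FALSE])
}

run_one_replication <- function(datasets, config, seed) {
  split <- stratified_split(datasets, config$test_fraction,
                            seed = derive_seed(seed, 1L))
  pooled <- pool_cohorts(datasets, split$train)
  fs <- embedded_feature_selection(pooled$expression, pooled$clinical$time,
                                   pooled$clinical$event,
                                   n_select = config$n_select,
                                   k_folds = config$k_folds,
                                   models_per_fold = config$models_per_fold,
                                   seed = derive_seed(seed, 2L))
  genes <- fs$selected_genes
  if (!length(genes)) stop("feature selection returned no genes")
  Xsel <- pooled$expression[, genes, drop = FALSE]
  candidates <- sample_hyperparameter_sets(config$n_candidates,
                                           config$hp_ranges,
                                           seed = derive_seed(seed, 3L))
  tuned <- tune_hyperparameters(Xsel, pooled$clinical$time,
                                pooled$clinical$event, candidates,
                                k_folds = config$k_folds,
                                seed = derive_seed(seed, 4L))
  model <- train_cox_boosting(Xsel, pooled$clinical$time,
                              pooled$clinical$event, hp = tuned$best,
                              seed = derive_seed(seed, 5L))
  per_cohort <- lapply(datasets, function(ds) {
    te <- intersect(split$test, ds$clinical$patient_id)
    risks <- predict_risk(model, ds$expression[te, genes, drop = FALSE])
    m <- match(te, ds$clinical$patient_id)
    concordance_index(risks, ds$clinical$time[m], ds$clinical$event[m])
  })
  list(split = split, selected_genes = genes, gains = fs$mean_gain[genes],
       hyperparameters = tuned$best, model = model,
       test_c_index = unlist(per_cohort), seed = seed)
}

#' Run single-cohort or pan-cancer training replications
#'
#' The replication loop: in each replication the data are split 80/20
#' stratified, the embedded feature selection picks the genes, random-search
#' cross-validation tunes the hyperparameters, a final boosted Cox model is
#' trained on the full training split, and test patients are scored with the
#' concordance index. In `single_cohort` mode each cohort gets its own model
#' per replication; in `pan_cancer` mode training patients are pooled across
#' cohorts (each cohort split 80/20 individually) and the one model is
#' evaluated per cohort on that cohort's test patients.
#'
#' Replication k's seed is derived from the master seed and k only, so its
#' result does not change when `n_replications` grows.
#'
#' @param datasets Named list of [cohort_dataset()] objects.
#' @param mode `"single_cohort"` or `"pan_cancer"`.
#' @param config Configuration from [pipeline_config()].
#' @param seed Master integer seed.
#' @return A `replication_set`: list with `results` (per replication: per
#'   cohort C-index, selected genes, gains, hyperparameters, the final
#'   model(s)) and `summary` (data frame `replication`, `mode`, `cohort`,
#'   `c_index`, `n_selected`).
#' @export
run_replications <- function(datasets, mode = c("pan_cancer", "single_cohort"),
                             config = pipeline_config(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, `[[`, "", "cohort")
  }
  results <- vector("list", config$n_replications)
  rows <- list()
  for (rep_k in seq_len(config$n_replications)) {
    rep_seed <- derive_seed(seed, rep_k)
    if (mode == "pan_cancer") {
      res <- run_one_replication(datasets, config, rep_seed)
      results[[rep_k]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        replication = rep_k, mode = mode,
        cohort = names(res$test_c_index),
        c_index = as.numeric(res$test_c_index),
        n_selected = length(res$selected_genes),
        stringsAsFactors = FALSE)
    } else {
      per_cohort <- lapply(names(datasets), function(co) {
        run_one_replication(datasets[co], config,
                            derive_seed(rep_seed, match(co, names(datasets))))
      })
      names(per_cohort) <- names(datasets)
      results[[rep_k]] <- per_cohort
      for (co in names(datasets)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replication = rep_k, mode = mode, cohort = co,
          c_index = as.numeric(per_cohort[[co]]$test_c_index),
          n_selected = length(per_cohort[[co]]$selected_genes),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = results, mode = mode,
                 summary = do.call(rbind, rows), seed = seed),
            class = "replication_set")
}

#' @export
print.replication_set <- function(x, ...) {
  cat(sprintf("<replication_set> mode %s: %d replications, mean C-index %.3f\n",
              x$mode, length(x$results), mean(x$summary$c_index)))
  invisible(x)
}

#' Extract per-replication gain maps from a replication set
#'
#' Returns the list of gene -> gain maps (mean selection gain of the selected
#' genes per replication), ready for [aggregate_importance()]. For
#' single-cohort runs, pass `cohort` to pick one cohort's replications.
#'
#' @param replications A `replication_set` from [run_replications()].
#' @param cohort Cohort name (required for single-cohort sets).
#' @return List of named numeric vectors.
#' @export
replication_gains <- function(replications, cohort = NULL) {
  stopifnot(inherits(replications, "replication_set"))
  if (replications$mode == "pan_cancer") {
    lapply(replications$results, `[[`, "gains")
  } else {
    if (is.null(cohort)) stop("cohort required for single-cohort sets")
    lapply(replications$results, function(r) r[[cohort]]$gains)
  }
}

#' Evaluate a trained model on held-out cohorts
#'
#' Scores cohorts that were never part of training (e.g. cohorts with fewer
#' than 20 uncensored patients) with a trained pan-cancer model and reports
#' the per-cohort concordance index.
#'
#' @param model A `boosted_cox` model.
#' @param heldout List of [cohort_dataset()] objects.
#' @return Data frame `cohort`, `n_patients`, `c_index` (one row per
#'   held-out cohort; empty for an empty list).
#' @export
predict_heldout <- function(model, heldout) {
  if (!length(heldout)) {
    return(data.frame(cohort = character(), n_patients = integer(),
                      c_index = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(heldout, function(ds) {
    risks <- predict_risk(model, ds$expression)
    data.frame(cohort = ds$cohort, n_patients = nrow(ds$expression),
               c_index = concordance_index(risks, ds$clinical$time,
                                           ds$clinical$event),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
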
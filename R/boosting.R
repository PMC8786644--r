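#' Random hyperparameter search space
#'
#' Default ranges for the random search used in hyperparameter tuning. The
#' ranges are a documented choice of this package: maximum tree depth 1-8,
#' 50-1000 boosting trees, learning rate log-uniform on \[0.01, 0.3\], row and
#' column subsampling on \[0.5, 1\], minimum child weight \[1, 10\], per-leaf
#' penalty gamma \[0, 5\] and weight penalty lambda \[0.5, 10\].
#'
#' @return Named list of 2-vectors (lower, upper) per hyperparameter.
#' @export
default_hp_ranges <- function() {
  list(max_depth = c(1L, 8L),
       n_trees = c(50L, 1000L),
       learning_rate = c(0.01, 0.3),
       subsample = c(0.5, 1),
       colsample_bytree = c(0.5, 1),
       min_child_weight = c(1, 10),
       gamma = c(0, 5),
       lambda = c(0.5, 10))
}

#' Draw random hyperparameter sets
#'
#' Draws `n` hyperparameter combinations uniformly from `ranges`
#' (learning rate log-uniformly), reproducibly under `seed`.
#'
#' @param n Number of sets to draw (default 500, the size of the random
#'   search).
#' @param ranges Search space as returned by [default_hp_ranges()].
#' @param seed Integer seed.
#' @return Data frame with one row per hyperparameter set and a
#'   `candidate_id` column.
#' @export
sample_hyperparameter_sets <- function(n = 500L, ranges = default_hp_ranges(),
                                       seed = 1L) {
  stopifnot(n >= 1)
  for (r in ranges) if (length(r) != 2L || r[2L] < r[1L]) stop("empty range")
  set.seed(seed)
  df <- data.frame(
    candidate_id = seq_len(n),
    max_depth = sample(seq(ranges$max_depth[1L], ranges$max_depth[2L]), n,
                       replace = TRUE),
    n_trees = sample(seq(ranges$n_trees[1L], ranges$n_trees[2L]), n,
                     replace = TRUE),
    learning_rate = exp(stats::runif(n, log(ranges$learning_rate[1L]),
                                     log(ranges$learning_rate[2L]))),
    subsample = stats::runif(n, ranges$subsample[1L], ranges$subsample[2L]),
    colsample_bytree = stats::runif(n, ranges$colsample_bytree[1L],
                                    ranges$colsample_bytree[2L]),
    min_child_weight = stats::runif(n, ranges$min_child_weight[1L],
                                    ranges$min_child_weight[2L]),
    gamma = stats::runif(n, ranges$gamma[1L], ranges$gamma[2L]),
    lambda = stats::runif(n, ranges$lambda[1L], ranges$lambda[2L]))
  df
}

cox_label <- function(time, event) ifelse(event == 1, time, -time)

#' Train a gradient-boosted Cox model
#'
#' Fits an additive regression-tree ensemble to the Cox negative partial
#' log-likelihood (`objective = survival:cox`), single-threaded and seeded so
#' training is reproducible. The prediction for a patient is the sum of the
#' selected leaf weights over all trees (a log-hazard-ratio score).
#'
#' @param expression Numeric patients-by-genes matrix restricted to the
#'   training genes.
#' @param time,event Survival outcome aligned with the matrix rows.
#' @param hp One-row data frame (or list) of hyperparameters; see
#'   [sample_hyperparameter_sets()]. Missing entries fall back to the
#'   backend defaults.
#' @param seed Integer seed.
#' @return A `boosted_cox` object (booster + feature names + metadata).
#' @export
train_cox_boosting <- function(expression, time, event, hp = list(), seed = 1L) {
  validate_expression(expression)
  check_survival_args(rep(0, nrow(expression)), time, event)
  hp <- as.list(hp)
  n_trees <- hp$n_trees %||% 100L
  if (n_trees < 1) stop("n_trees must be >= 1")
  params <- list(objective = "survival:cox",
                 nthread = 1L,
                 seed = as.integer(seed),
                 max_depth = as.integer(hp$max_depth %||% 6L),
                 eta = hp$learning_rate %||% 0.3,
                 subsample = hp$subsample %||% 1,
                 colsample_bytree = hp$colsample_bytree %||% 1,
                 min_child_weight = hp$min_child_weight %||% 1,
                 gamma = hp$gamma %||% 0,
                 lambda = hp$lambda %||% 1)
  dm <- xgboost::xgb.DMatrix(expression, label = cox_label(time, event))
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = as.integer(n_trees), verbose = 0)
  structure(list(booster = booster, feature_names = colnames(expression),
                 hp = hp, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "boosted_cox")
}

#' @export
print.boosted_cox <- function(x, ...) {
  cat(sprintf("<boosted_cox> %d trees over %d features\n",
              x$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Predict patient risk scores
#'
#' Returns the ensemble margin (sum of leaf weights), a log-hazard-ratio
#' risk score: higher means shorter predicted survival. Deterministic and
#' row-wise.
#'
#' @param model A `boosted_cox` model.
#' @param expression Patients-by-genes matrix containing all model features.
#' @param n_trees Optionally score with only the first `n_trees` trees.
#' @return Named numeric vector of risk scores (names = patient ids).
#' @export
predict_risk <- function(model, expression, n_trees = NULL) {
  stopifnot(inherits(model, "boosted_cox"))
  validate_expression(expression)
  missing <- setdiff(model$feature_names, colnames(expression))
  if (length(missing)) {
    stop("expression lacks model feature gene(s): ",
         paste(missing, collapse = ", "))
  }
  X <- expression[, model$feature_names, drop = FALSE]
  rng <- if (is.null(n_trees)) NULL else c(1L, as.integer(n_trees))
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X),
                      outputmargin = TRUE, iterationrange = rng)
  stats::setNames(as.numeric(p), rownames(X))
}

#' Per-feature split gain of a boosted model
#'
#' Gain of a feature is the average loss reduction over all tree splits that
#' use it. Features never used by any split are absent from the result
#' (treated as zero downstream).
#'
#' @param model A `boosted_cox` model.
#' @return Named numeric vector, gene -> mean split gain.
#' @export
feature_gain <- function(model) {
  stopifnot(inherits(model, "boosted_cox"))
  dump <- xgboost::xgb.dump(model$booster, with_stats = TRUE)
  splits <- grep("^[0-9]+:\\[", dump, value = TRUE)  # "k:[gene<thr] ...,gain=x,..."
  if (!length(splits)) return(stats::setNames(numeric(0), character(0)))
  feat <- sub("^[0-9]+:\\[([^<>]+)[<>].*$", "\\1", splits)
  gain <- as.numeric(sub("^.*gain=([-0-9.eE+]+),.*$", "\\1", splits))
  g <- tapply(gain, feat, mean)
  stats::setNames(as.numeric(g), names(g))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
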
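#' Zero-MAD gene filter
#'
#' Flags genes whose mean absolute deviation from the gene's mean is zero,
#' i.e. genes with constant expression. Such genes carry no information about
#' survival and are removed before feature selection. Idempotent.
#'
#' @param expression Patients-by-genes matrix.
#' @return Named logical vector over genes; `TRUE` = retained (MAD > 0).
#' @export
mad_filter <- function(expression) {
  mu <- colMeans(expression)
  mad_mean <- colMeans(abs(sweep(expression, 2L, mu)))
  stats::setNames(mad_mean > 0, colnames(expression))
}

#' Embedded cross-validated feature selection
#'
#' The gain-based feature-selection stage: a stratified `k_folds`-fold
#' cross-validation is run on the training data; within each fold, genes with
#' zero MAD on that fold's training portion are removed and
#' `models_per_fold` size-limited boosted Cox models are trained with
#' randomly drawn tree counts in \[5, 20\], depths in \[1, 3\] and
#' column-subsampling fractions in \[0.3, 1\] (the varied hyperparameters
#' that decorrelate the greedy split choices across models). Per-gene
#' split gain is averaged over all `k_folds * models_per_fold` models (genes
#' absent from a model count 0), and the `n_select` genes with the highest
#' mean gain are selected. Only genes with strictly positive mean gain are
#' eligible; ties are broken lexicographically by gene id.
#'
#' @param expression Training patients-by-genes matrix.
#' @param time,event Survival outcome aligned with rows.
#' @param n_select Number of genes to select (default 500).
#' @param k_folds Cross-validation folds (default 4).
#' @param models_per_fold Size-limited models per fold (default 20).
#' @param seed Integer seed.
#' @return A `feature_selection` object: list with `selected_genes` (ordered
#'   by descending mean gain), `mean_gain` (named vector over all genes) and
#'   `audit` (data frame of fold, model, n_trees, depth, gene, gain).
#' @export
embedded_feature_selection <- function(expression, time, event,
                                       n_select = 500L, k_folds = 4L,
                                       models_per_fold = 20L, seed = 1L) {
  validate_expression(expression)
  check_survival_args(rep(0, nrow(expression)), time, event)
  if (sum(event == 1) < k_folds) {
    stop("need at least one uncensored patient per fold")
  }
  folds <- stratified_folds(event, k_folds, seed = derive_seed(seed, 0L))
  genes <- colnames(expression)
  total_gain <- stats::setNames(numeric(length(genes)), genes)
  audit <- vector("list", k_folds * models_per_fold)
  n_models <- 0L
  for (fold in seq_len(k_folds)) {
    tr_idx <- which(folds != fold)
    if (!any(event[tr_idx] == 1)) stop("fold without uncensored patients")
    Xf <- expression[tr_idx, , drop = FALSE]
    keep <- mad_filter(Xf)
    Xf <- Xf[, keep, drop = FALSE]
    Xf <- Xf[, order(colnames(Xf)), drop = FALSE]  # column-order invariance
    set.seed(derive_seed(seed, fold))
    n_trees_draw <- sample(5:20, models_per_fold, replace = TRUE)
    depth_draw <- sample(1:3, models_per_fold, replace = TRUE)
    colsample_draw <- stats::runif(models_per_fold, 0.3, 1)
    for (mdl in seq_len(models_per_fold)) {
      n_models <- n_models + 1L
      fit <- train_cox_boosting(Xf, time[tr_idx], event[tr_idx],
                                hp = list(n_trees = n_trees_draw[mdl],
                                          max_depth = depth_draw[mdl],
                                          colsample_bytree = colsample_draw[mdl]),
                                seed = derive_seed(seed, fold * 1000L + mdl))
      g <- feature_gain(fit)
      if (length(g)) {
        total_gain[names(g)] <- total_gain[names(g)] + g
        audit[[n_models]] <- data.frame(fold = fold, model = mdl,
                                        n_trees = n_trees_draw[mdl],
                                        depth = depth_draw[mdl],
                                        gene = names(g),
                                        gain = as.numeric(g),
                                        stringsAsFactors = FALSE)
      }
    }
  }
  mean_gain <- total_gain / (k_folds * models_per_fold)
  eligible <- names(mean_gain)[mean_gain > 0]
  ord <- order(-mean_gain[eligible], eligible)   # desc gain, lexicographic ties
  selected <- eligible[ord][seq_len(min(n_select, length(eligible)))]
  structure(list(selected_genes = selected, mean_gain = mean_gain,
                 audit = do.call(rbind, audit[!vapply(audit, is.null, TRUE)])),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d genes selected (top mean gain %.4g)\n",
              length(x$selected_genes),
              if (length(x$selected_genes)) x$mean_gain[x$selected_genes[1L]] else NA))
  invisible(x)
}

#' Write a feature-selection result to TSV
#'
#' @param fs A `feature_selection` object.
#' @param path Output path; one row per gene with mean gain and selection
#'   flag.
#' @return `path`, invisibly.
#' @export
write_feature_selection <- function(fs, path) {
  df <- data.frame(gene = names(fs$mean_gain),
                   mean_gain = as.numeric(fs$mean_gain),
                   selected_flag = as.integer(names(fs$mean_gain) %in%
                                                fs$selected_genes),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$mean_gain, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
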
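#' Define ground truth for synthetic survival cohorts
#'
#' Fixes the prognostic structure that [generate_cohort()] and
#' [generate_pan_cancer()] simulate from: which genes carry survival signal,
#' their log-hazard effect sizes, which of them are shared across all cohorts
#' versus active in exactly one cohort, and the exponential event/censoring
#' rates.
#'
#' Effect sizes are drawn uniformly from `beta_range` in magnitude with random
#' sign, so informative genes can be protective or deleterious. A fraction
#' `zero_mad_fraction` of the non-informative genes is held constant
#' (zero mean absolute deviation) to exercise the MAD filter downstream.
#'
#' @param n_genes Total number of genes in the expression universe.
#' @param n_informative Number of genes with nonzero effect on the hazard.
#' @param cohorts Character vector of cohort labels.
#' @param shared_fraction Fraction of informative genes active in every
#'   cohort; the remainder are distributed round-robin, each active in
#'   exactly one cohort.
#' @param beta_range Magnitude range (log-hazard units per SD of expression)
#'   for the informative effect sizes.
#' @param baseline_rate Baseline event hazard, events per day.
#' @param censor_rate Independent censoring hazard, per day.
#' @param zero_mad_fraction Fraction of noise genes fixed to a constant value.
#' @param seed Integer seed; the truth is deterministic given it.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(n_genes, n_informative = 10L,
                            cohorts = "cohort_1", shared_fraction = 1,
                            beta_range = c(0.5, 1.0),
                            baseline_rate = 0.002, censor_rate = 0.002,
                            zero_mad_fraction = 0.05, seed = 1L) {
  stopifnot(n_genes >= n_informative, n_informative >= 0,
            shared_fraction >= 0, shared_fraction <= 1,
            baseline_rate > 0, censor_rate >= 0)
  cohorts <- as.character(cohorts)
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  informative <- sort(sample(gene_ids, n_informative))
  beta <- stats::setNames(
    stats::runif(n_informative, beta_range[1L], beta_range[2L]) *
      sample(c(-1, 1), n_informative, replace = TRUE),
    informative)
  n_shared <- round(shared_fraction * n_informative)
  shared <- informative[seq_len(n_shared)]
  specific <- stats::setNames(vector("list", length(cohorts)), cohorts)
  leftover <- setdiff(informative, shared)
  if (length(leftover)) {
    owner <- rep_len(cohorts, length(leftover))
    for (co in cohorts) specific[[co]] <- leftover[owner == co]
  } else {
    specific[] <- list(character())
  }
  noise <- setdiff(gene_ids, informative)
  n_const <- round(zero_mad_fraction * length(noise))
  constant_genes <- sort(sample(noise, n_const))
  # per-gene log-normal expression parameters, fixed across cohorts
  meanlog <- stats::setNames(stats::runif(n_genes, 0, 3), gene_ids)
  structure(list(gene_ids = gene_ids, informative_genes = informative,
                 beta = beta, shared_genes = shared,
                 cohort_specific = specific, cohorts = cohorts,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 constant_genes = constant_genes, meanlog = meanlog,
                 sdlog = 0.6, seed = seed),
            class = "synthetic_truth")
}

#' Simulate one censored survival cohort
#'
#' Expression is log-normal (FPKM-like, nonnegative); a configurable subset of
#' genes is constant. Survival follows an exponential proportional-hazards
#' model: the event time for patient i has rate
#' `baseline_rate * exp(sum_g beta_g * z_ig)` where `z_ig` is the within-cohort
#' standardized expression of active gene g, and censoring is an independent
#' exponential with rate `censor_rate`. The observed time is the minimum of
#' the two and `event = 1` iff death came first.
#'
#' Genes active in a cohort are the truth's shared genes plus that cohort's
#' specific genes (all informative genes if the cohort is not named in the
#' truth).
#'
#' @param n_patients Number of patients to simulate.
#' @param truth A [synthetic_truth()] object.
#' @param cohort Cohort label.
#' @param seed Integer seed.
#' @return A [cohort_dataset()].
#' @export
generate_cohort <- function(n_patients, truth, cohort = "cohort_1", seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_patients >= 1)
  set.seed(seed)
  genes <- truth$gene_ids
  n_genes <- length(genes)
  X <- matrix(stats::rlnorm(n_patients * n_genes,
                            meanlog = rep(truth$meanlog, each = n_patients),
                            sdlog = truth$sdlog),
              nrow = n_patients, ncol = n_genes,
              dimnames = list(sprintf("%s_p%04d", cohort, seq_len(n_patients)),
                              genes))
  if (length(truth$constant_genes)) {
    X[, truth$constant_genes] <- rep(exp(truth$meanlog[truth$constant_genes]),
                                     each = n_patients)
  }
  active <- if (cohort %in% names(truth$cohort_specific)) {
    c(truth$shared_genes, truth$cohort_specific[[cohort]])
  } else {
    truth$informative_genes
  }
  lp <- rep(0, n_patients)
  if (length(active)) {
    Z <- scale(X[, active, drop = FALSE])
    Z[is.nan(Z)] <- 0  # guards degenerate zero-variance draws
    lp <- as.numeric(Z %*% truth$beta[active])
  }
  t_event <- stats::rexp(n_patients, rate = truth$baseline_rate * exp(lp))
  t_cens <- if (truth$censor_rate > 0) {
    stats::rexp(n_patients, rate = truth$censor_rate)
  } else {
    rep(Inf, n_patients)
  }
  clinical <- data.frame(
    patient_id = rownames(X),
    cohort = cohort,
    age = round(stats::runif(n_patients, 40, 80)),
    gender = sample(c("female", "male"), n_patients, replace = TRUE),
    event = as.integer(t_event <= t_cens),
    time = pmin(t_event, t_cens),
    stringsAsFactors = FALSE)
  cohort_dataset(X, clinical, cohort)
}

#' Simulate a multi-cohort (pan-cancer-like) collection
#'
#' Draws a shared ground truth and one censored survival cohort per label.
#' A `shared_fraction` of the informative genes is active in every cohort
#' (the common survival signature); the rest are active in exactly one
#' cohort each (cohort-specific signal).
#'
#' @param n_cohorts Number of cohorts.
#' @param per_cohort_n Patients per cohort; recycled to length `n_cohorts`.
#' @param n_genes Genes in the expression universe.
#' @param n_informative Number of informative genes.
#' @param shared_fraction Fraction of informative genes shared by all cohorts.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synthetic_truth()]
#'   (`beta_range`, `baseline_rate`, `censor_rate`, `zero_mad_fraction`).
#' @return List with `cohorts` (named list of [cohort_dataset()]) and
#'   `truth` (the [synthetic_truth()]).
#' @export
generate_pan_cancer <- function(n_cohorts, per_cohort_n, n_genes = 200L,
                                n_informative = 10L, shared_fraction = 0.8,
                                seed = 1L, ...) {
  stopifnot(n_cohorts >= 1)
  labels <- sprintf("cohort_%02d", seq_len(n_cohorts))
  per_cohort_n <- rep_len(per_cohort_n, n_cohorts)
  truth <- synthetic_truth(n_genes = n_genes, n_informative = n_informative,
                           cohorts = labels, shared_fraction = shared_fraction,
                           seed = seed, ...)
  cohorts <- stats::setNames(vector("list", n_cohorts), labels)
  for (k in seq_len(n_cohorts)) {
    cohorts[[k]] <- generate_cohort(per_cohort_n[k], truth, labels[k],
                                    seed = derive_seed(seed, k))
  }
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a PPI-like network with a planted module
#'
#' Grows a scale-free-like random graph by preferential attachment, labels its
#' nodes with gene ids from the truth's universe, and additionally wires the
#' informative genes into a densely connected subgraph so that module
#' recovery has ground truth. The planted genes are placed on non-hub nodes
#' (degree at most the median), as most genes in real interactomes are, and
#' wired like a protein complex: a clique for up to 12 planted genes,
#' otherwise a ring plus enough random chords to give every planted gene
#' several planted neighbors. The result is simple and undirected.
#'
#' @param n_nodes Number of nodes.
#' @param attachment Edges added per new node during preferential attachment.
#' @param truth A [synthetic_truth()]; all informative genes are placed in the
#'   network.
#' @param seed Integer seed.
#' @return An undirected simple [igraph::graph] with gene-id vertex names.
#' @export
generate_ppi <- function(n_nodes, attachment = 3L, truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  inf <- truth$informative_genes
  if (n_nodes < length(inf)) stop("n_nodes < number of planted genes")
  if (attachment >= n_nodes) stop("attachment must be < n_nodes")
  if (n_nodes > length(truth$gene_ids)) {
    stop("n_nodes exceeds the gene universe; node labels are drawn from it")
  }
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
  deg <- igraph::degree(g)
  low <- which(deg <= stats::median(deg))
  inf_nodes <- if (length(inf)) sample(low, length(inf)) else integer()
  labels <- character(n_nodes)
  labels[inf_nodes] <- sample(inf)
  labels[setdiff(seq_len(n_nodes), inf_nodes)] <-
    sample(setdiff(truth$gene_ids, inf), n_nodes - length(inf))
  igraph::V(g)$name <- labels
  # wire planted genes into a dense connected neighborhood
  if (length(inf) >= 2L) {
    edges <- if (length(inf) <= 12L) {
      t(utils::combn(inf, 2L))
    } else {
      ring <- sample(inf)
      chords <- t(replicate(3L * length(inf), sample(inf, 2L)))
      rbind(cbind(ring, c(ring[-1L], ring[1L])), chords)
    }
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::simplify(g)
}

#' Write a synthetic ground truth table to TSV
#'
#' One row per gene in the universe with its effect size, shared flag and
#' owning cohort (empty for shared or noise genes).
#'
#' @param truth A [synthetic_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  owner <- stats::setNames(rep("", length(truth$gene_ids)), truth$gene_ids)
  for (co in names(truth$cohort_specific)) {
    owner[truth$cohort_specific[[co]]] <- co
  }
  df <- data.frame(
    gene = truth$gene_ids,
    beta = ifelse(truth$gene_ids %in% names(truth$beta),
                  truth$beta[truth$gene_ids], 0),
    shared_flag = as.integer(truth$gene_ids %in% truth$shared_genes),
    cohort = owner,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer mixing so that replication k's seed does not change
#' when the total number of replications does.
#'
#' @param seed Master integer seed.
#' @param index Positive integer index (replication, cohort, permutation...).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483647)
}
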
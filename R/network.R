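#' k-core decomposition
#'
#' Coreness of every node: the largest k such that the node belongs to the
#' maximal subgraph in which every node has degree >= k. Coreness is the
#' normalizer of the random walk (instead of degree) to counter the degree
#' bias of protein-interaction networks.
#'
#' @param network Undirected simple [igraph::graph].
#' @return Named integer vector, node -> coreness. Always <= degree.
#' @export
core_decomposition <- function(network) {
  stopifnot(igraph::is_igraph(network))
  core <- igraph::coreness(network)
  storage.mode(core) <- "integer"
  core
}

#' Coreness-normalized transition matrix
#'
#' Builds the column-stochastic random-walk matrix in which the mass leaving
#' node j is distributed over its neighbors proportionally to their coreness:
#' `W[i, j] = A_ij * c_i / sum_k (A_kj * c_k)`. On a graph with uniform
#' coreness this reduces to the classic uniform neighbor transition
#' `1/degree(j)`. Isolated nodes (or nodes whose neighbors all have coreness
#' 0) keep their mass through a self-transition so every column sums to 1.
#'
#' @param network Undirected simple [igraph::graph].
#' @param coreness Optional precomputed coreness vector (defaults to
#'   [core_decomposition()]).
#' @return Sparse column-stochastic matrix (class `dgCMatrix`) with node
#'   names on both dimensions.
#' @export
coreness_normalize <- function(network, coreness = core_decomposition(network)) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop("network vertices must be named")
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  C <- Matrix::Diagonal(x = as.numeric(coreness[nodes]))
  W <- C %*% A                       # W[i, j] = A_ij * c_i
  colsum <- Matrix::colSums(W)
  dead <- colsum == 0
  colsum[dead] <- 1
  W <- W %*% Matrix::Diagonal(x = 1 / colsum)
  if (any(dead)) {
    W <- W + Matrix::sparseMatrix(i = which(dead), j = which(dead), x = 1,
                                  dims = dim(A))
  }
  dimnames(W) <- list(nodes, nodes)
  methods::as(W, "CsparseMatrix")
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) * W %*% p + r * p0` until the L1 change falls below
#' `tol`. With restart probability `r = 1` the walk never moves and
#' `p == p0`; smaller `r` diffuses the initial weights further over the
#' network. Probability mass is conserved at every iteration.
#'
#' @param W Column-stochastic transition matrix
#'   (see [coreness_normalize()]).
#' @param p0 Nonnegative initial weights over nodes, summing to 1 (a vector
#'   aligned with `W`'s columns, or named).
#' @param restart Restart probability in (0, 1\] (default 0.8).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 10000).
#' @return Named steady-state vector summing to 1, with attributes
#'   `"iterations"` and `"residual"`.
#' @export
random_walk_with_restart <- function(W, p0, restart = 0.8, tol = 1e-6,
                                     max_iter = 10000L) {
  stopifnot(restart > 0, restart <= 1, all(p0 >= 0))
  if (!is.null(names(p0)) && !is.null(colnames(W))) {
    p0 <- p0[colnames(W)]
  }
  if (length(p0) != ncol(W)) stop("p0 length does not match the network")
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (W %*% p)) + restart * p0
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (resid < tol) {
      names(p) <- colnames(W)
      attr(p, "iterations") <- it
      attr(p, "residual") <- resid
      return(p)
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
               max_iter, resid))
}

#' Select in-network seed genes by importance weight
#'
#' Intersects a gene weight table with the network's nodes and returns the
#' `n_seeds` heaviest in-network genes (ties broken lexicographically).
#' Weighted genes absent from the network are recorded in the `"dropped"`
#' attribute. If fewer than `n_seeds` weighted genes are in the network, all
#' of them are returned with a warning.
#'
#' @param weights Named weight vector (gene -> summed gain), e.g. from
#'   [aggregate_importance()].
#' @param network Undirected [igraph::graph] with named vertices.
#' @param n_seeds Number of seed genes (default 100).
#' @return Character vector of seed gene ids, heaviest first, with attribute
#'   `"dropped"` (off-network weighted genes).
#' @export
select_seeds <- function(weights, network, n_seeds = 100L) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  nodes <- igraph::V(network)$name
  in_net <- names(weights)[names(weights) %in% nodes]
  dropped <- setdiff(names(weights), nodes)
  if (length(in_net) < n_seeds) {
    warning(sprintf("only %d weighted genes in the network (< %d seeds requested)",
                    length(in_net), n_seeds))
  }
  w <- weights[in_net]
  ord <- order(-w, names(w))
  seeds <- names(w)[ord][seq_len(min(n_seeds, length(w)))]
  attr(seeds, "dropped") <- dropped
  seeds
}

#' Permutation significance of propagated weights
#'
#' Empirical per-node p-values for the steady-state weights: in each
#' permutation the multiset of initial weights is randomly reassigned over
#' the nodes and propagated; the p-value of node v is
#' `(1 + #\{permutations with steady weight at v >= observed\}) /
#' (1 + n_permutations)`. Nodes significant at Benjamini-Hochberg FDR
#' `fdr` form the significant set used for module identification.
#'
#' @inheritParams random_walk_with_restart
#' @param n_permutations Number of weight permutations (default 1000).
#' @param fdr BH false-discovery-rate cutoff (default 0.05).
#' @param seed Integer master seed; per-permutation seeds are derived from
#'   it.
#' @return A `propagation_result`: list with `steady`, `initial`, `pvalues`,
#'   `fdr_adjusted`, `significant` (node names), `restart`, plus the
#'   coreness if supplied via attribute by callers.
#' @export
propagation_significance <- function(W, p0, restart = 0.8,
                                     n_permutations = 1000L, fdr = 0.05,
                                     tol = 1e-6, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  observed <- random_walk_with_restart(W, p0, restart, tol = tol)
  if (!is.null(names(p0)) && !is.null(colnames(W))) p0 <- p0[colnames(W)]
  n <- length(p0)
  exceed <- integer(n)
  for (perm in seq_len(n_permutations)) {
    set.seed(derive_seed(seed, perm))
    p_perm <- unname(p0)[sample.int(n)]   # unnamed: a true reassignment over nodes
    steady_perm <- random_walk_with_restart(W, p_perm, restart, tol = tol)
    exceed <- exceed + (as.numeric(steady_perm) >= as.numeric(observed))
  }
  pvalues <- (1 + exceed) / (1 + n_permutations)
  names(pvalues) <- colnames(W)
  adj <- stats::p.adjust(pvalues, method = "BH")
  structure(list(initial = stats::setNames(as.numeric(p0), colnames(W)),
                 steady = observed,
                 pvalues = pvalues,
                 fdr_adjusted = adj,
                 significant = names(adj)[adj <= fdr],
                 restart = restart,
                 n_permutations = as.integer(n_permutations)),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> %d nodes, restart %.2f, %d significant (of %d permutations)\n",
              length(x$steady), x$restart, length(x$significant),
              x$n_permutations))
  invisible(x)
}

#' Identify seed-anchored network modules
#'
#' Takes the subgraph induced by the seed genes together with the
#' significantly up-weighted genes and keeps its connected components that
#' contain at least one seed and at least two nodes. Non-seed members are
#' labeled `inferred` (they link seeds together); seeds falling into
#' discarded singletons are recorded in the `"dropped_seeds"` attribute.
#'
#' @param network Undirected [igraph::graph] with named vertices.
#' @param seeds Character vector of seed genes (subset of the network nodes).
#' @param significant Character vector of significant genes from
#'   [propagation_significance()].
#' @return A `module_set`: data frame with columns `module`, `gene`, `role`
#'   (`seed` or `inferred`), modules numbered by decreasing size; attribute
#'   `"dropped_seeds"` lists seeds not placed in any module.
#' @export
identify_modules <- function(network, seeds, significant) {
  nodes <- igraph::V(network)$name
  if (length(setdiff(seeds, nodes))) {
    stop("seed(s) not in the network: ",
         paste(setdiff(seeds, nodes), collapse = ", "))
  }
  members <- union(seeds, intersect(significant, nodes))
  sub <- igraph::induced_subgraph(network, members)
  comp <- igraph::components(sub)
  rows <- list()
  module_id <- 0L
  sizes <- order(-comp$csize)
  for (ci in sizes) {
    genes <- names(comp$membership)[comp$membership == ci]
    if (length(genes) < 2L || !any(genes %in% seeds)) next
    module_id <- module_id + 1L
    rows[[module_id]] <- data.frame(
      module = module_id,
      gene = sort(genes),
      role = ifelse(sort(genes) %in% seeds, "seed", "inferred"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(module = integer(), gene = character(), role = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dropped_seeds") <- setdiff(seeds, out$gene)
  class(out) <- c("module_set", class(out))
  out
}

#' Run the full network-propagation stage
#'
#' Convenience wrapper tying the stage together: coreness normalization, seed
#' selection from a gene weight table (initial weights = seed weights,
#' normalized to sum 1), random walk with restart, permutation significance,
#' and seed-anchored module identification.
#'
#' @param network Undirected simple [igraph::graph] with named vertices.
#' @param weights Named gene weight vector (summed gain).
#' @param n_seeds Number of seed genes (default 100).
#' @param restart Restart probability (default 0.8).
#' @param n_permutations Permutations for significance (default 1000).
#' @param fdr BH FDR cutoff (default 0.05).
#' @param seed Integer seed.
#' @return List with `seeds`, `coreness`, `propagation` (a
#'   `propagation_result`) and `modules` (a `module_set`).
#' @export
propagate_weights <- function(network, weights, n_seeds = 100L, restart = 0.8,
                              n_permutations = 1000L, fdr = 0.05, seed = 1L) {
  coreness <- core_decomposition(network)
  W <- coreness_normalize(network, coreness)
  seeds <- select_seeds(weights, network, n_seeds)
  p0 <- stats::setNames(numeric(ncol(W)), colnames(W))
  p0[seeds] <- weights[seeds]
  p0 <- p0 / sum(p0)
  prop <- propagation_significance(W, p0, restart = restart,
                                   n_permutations = n_permutations,
                                   fdr = fdr, seed = seed)
  modules <- identify_modules(network, seeds, prop$significant)
  list(seeds = seeds, coreness = coreness, propagation = prop,
       modules = modules)
}

#' Write propagation and module tables to TSV
#'
#' @param result List from [propagate_weights()].
#' @param propagation_path,modules_path Output paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
write_propagation <- function(result, propagation_path = NULL,
                              modules_path = NULL) {
  if (!is.null(propagation_path)) {
    prop <- result$propagation
    df <- data.frame(gene = names(prop$steady),
                     p0 = prop$initial,
                     p_steady = as.numeric(prop$steady),
                     coreness = result$coreness[names(prop$steady)],
                     pvalue = prop$pvalues,
                     fdr_adjusted = prop$fdr_adjusted,
                     significant_flag = as.integer(names(prop$steady) %in%
                                                     prop$significant),
                     stringsAsFactors = FALSE)
    utils::write.table(df[order(-df$p_steady), ], propagation_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(modules_path)) {
    utils::write.table(as.data.frame(result$modules), modules_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(propagation_path, modules_path))
}
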
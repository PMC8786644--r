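#' Aggregate per-replication feature gains
#'
#' Sums gain over training replications: a gene's weight is the sum of its
#' per-replication gains, counting 0 in replications where it was not among
#' the used features. Genes with total weight 0 are omitted. Order-invariant
#' over replications.
#'
#' @param per_replication_gains List of named numeric vectors (gene -> gain),
#'   one per replication.
#' @return Named nonnegative numeric vector (gene -> summed weight), sorted
#'   by decreasing weight.
#' @export
aggregate_importance <- function(per_replication_gains) {
  stopifnot(is.list(per_replication_gains), length(per_replication_gains) >= 1)
  genes <- unique(unlist(lapply(per_replication_gains, names)))
  total <- stats::setNames(numeric(length(genes)), genes)
  for (g in per_replication_gains) {
    if (length(g)) total[names(g)] <- total[names(g)] + g
  }
  total <- total[total > 0]
  total[order(-total, names(total))]
}

#' Build a genes-by-cohorts weight matrix
#'
#' Stacks per-cohort aggregated weights into a matrix over the union of
#' genes, with 0 where a gene carried no weight in a cohort.
#'
#' @param cohort_weights Named list (cohort -> named weight vector as from
#'   [aggregate_importance()]).
#' @return Nonnegative matrix, genes in rows, cohorts in columns.
#' @export
cohort_weight_matrix <- function(cohort_weights) {
  stopifnot(is.list(cohort_weights), length(cohort_weights) >= 1,
            !is.null(names(cohort_weights)))
  genes <- sort(unique(unlist(lapply(cohort_weights, names))))
  W <- matrix(0, nrow = length(genes), ncol = length(cohort_weights),
              dimnames = list(genes, names(cohort_weights)))
  for (co in names(cohort_weights)) {
    w <- cohort_weights[[co]]
    W[names(w), co] <- w
  }
  W
}

#' Cross-cohort entropy of feature-importance weights
#'
#' For each gene, its per-cohort weights are normalized to a probability
#' vector `P(g, i) = w(g, i) / sum_j w(g, j)` and scored with the base-2
#' Shannon entropy `H(g) = -sum_i P log2 P` (with `0 log2 0 = 0`). A gene
#' important in many cohorts with similar weight has high entropy (at most
#' `log2(n_cohorts)`, e.g. 4.64 bits for 25 cohorts); a gene weighted in a
#' single cohort has entropy 0. All-zero rows are dropped (such genes were
#' never features) and reported via the `"dropped"` attribute.
#'
#' @param weights Nonnegative genes-by-cohorts matrix
#'   (see [cohort_weight_matrix()]).
#' @return Data frame `gene`, `entropy` (bits), sorted by decreasing entropy,
#'   with the probability matrix in attribute `"probabilities"` and dropped
#'   gene ids in attribute `"dropped"`.
#' @export
entropy_scores <- function(weights) {
  stopifnot(is.matrix(weights), all(weights >= 0), !is.null(rownames(weights)))
  totals <- rowSums(weights)
  dropped <- rownames(weights)[totals == 0]
  if (length(dropped)) {
    message(length(dropped), " all-zero weight row(s) dropped")
    weights <- weights[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  P <- weights / totals
  H <- apply(P, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  out <- data.frame(gene = rownames(weights), entropy = as.numeric(H),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$entropy, out$gene), ]
  rownames(out) <- NULL
  attr(out, "probabilities") <- P
  attr(out, "dropped") <- dropped
  out
}

#' Percent reduction between two feature-set sizes
#'
#' Convenience for reporting how much a feature universe shrank, e.g. from
#' the union of single-cohort features to the pan-cancer features.
#'
#' @param from Original count.
#' @param to Reduced count.
#' @return Percent reduction, `100 * (1 - to/from)`.
#' @export
percent_reduction <- function(from, to) {
  stopifnot(from > 0, to >= 0)
  100 * (1 - to / from)
}

#' Fisher over-representation analysis
#'
#' One-sided Fisher's exact test (hypergeometric upper tail: probability of
#' an overlap at least as large as observed) of a query gene set against each
#' set in a collection, within an explicit gene universe. Sets are
#' intersected with the universe before testing. Benjamini-Hochberg FDR is
#' reported alongside the raw p-value.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param collections Named list of character vectors (the gene sets).
#' @param universe Character vector, the background gene universe.
#' @return Data frame with one row per set: `set`, `set_size`, `overlap`,
#'   `ratio` (overlap / set size), `overlap_genes` (comma-joined), `p_value`,
#'   `fdr`; sorted by p-value.
#' @export
ora_fisher <- function(query, collections, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  if (length(setdiff(query, universe))) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  }
  stopifnot(is.list(collections), !is.null(names(collections)))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collections), function(nm) {
    gs <- intersect(unique(collections[[nm]]), universe)
    ov <- intersect(query, gs)
    k <- length(ov)
    # P(X >= k), X ~ Hypergeometric(N, |gs|, q)
    p <- stats::phyper(k - 1L, length(gs), N - length(gs), q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = k,
               ratio = if (length(gs)) k / length(gs) else NA_real_,
               overlap_genes = paste(sort(ov), collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}

#' Read gene-set collections from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated, with set name,
#' description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("GMT lines need name, description, >= 1 gene")
  stats::setNames(lapply(parts, function(p) unique(p[-c(1L, 2L)])),
                  vapply(parts, `[[`, "", 1L))
}
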
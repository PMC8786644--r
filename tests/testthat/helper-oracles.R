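# Independent oracles, deliberately naive: each re-derives a quantity the
# package computes by a different route (enumeration, finite differences,
# dense linear algebra) so the implementation and the check never share code.

# C-index by explicit enumeration of ordered pairs: pair (i, j) counts when
# patient i died and strictly earlier than patient j's observed time.
oracle_cindex <- function(risks, time, event) {
  n <- length(risks)
  num <- 0L; den <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1L
        if ((time[i] - time[j]) * (risks[j] - risks[i]) > 0) num <- num + 1L
      }
    }
  }
  if (den == 0L) stop("no comparable pairs")
  num / den
}

# central finite differences on the loss
oracle_cox_gradient <- function(scores, time, event, h = 1e-6) {
  vapply(seq_along(scores), function(k) {
    up <- scores; up[k] <- up[k] + h
    dn <- scores; dn[k] <- dn[k] - h
    (cox_nll(up, time, event) - cox_nll(dn, time, event)) / (2 * h)
  }, numeric(1))
}

oracle_cox_curvature <- function(scores, time, event, h = 1e-4) {
  f0 <- cox_nll(scores, time, event)
  vapply(seq_along(scores), function(k) {
    up <- scores; up[k] <- up[k] + h
    dn <- scores; dn[k] <- dn[k] - h
    (cox_nll(up, time, event) + cox_nll(dn, time, event) - 2 * f0) / h^2
  }, numeric(1))
}

# k-core numbers by brute-force peeling on an adjacency matrix
oracle_coreness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      peel <- which(alive)[deg < k + 1L]
      if (!length(peel)) break
      core[peel] <- k
      alive[peel] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
  }
  stats::setNames(core, igraph::V(g)$name)
}

# RWR fixed point by dense linear solve: p = r (I - (1-r) W)^{-1} p0
oracle_rwr <- function(W, p0, r) {
  Wd <- as.matrix(W)
  n <- nrow(Wd)
  as.numeric(r * solve(diag(n) - (1 - r) * Wd, p0))
}

# hypergeometric upper tail by exact term-wise enumeration
oracle_hyper_upper <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(vapply(ks, function(k) {
    choose(set_size, k) * choose(universe_size - set_size, query_size - k)
  }, numeric(1))) / choose(universe_size, query_size)
}
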
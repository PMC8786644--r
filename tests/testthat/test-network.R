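ring_graph <- function(n) {
  igraph::make_ring(n) |>
    igraph::set_vertex_attr("name", value = sprintf("n%02d", seq_len(n)))
}

random_named_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

test_that("coreness matches canonical cases and the peeling oracle", {
  tri <- igraph::make_full_graph(3) |>
    igraph::set_vertex_attr("name", value = c("a", "b", "c"))
  expect_true(all(core_decomposition(tri) == 2))
  star <- igraph::make_star(5, mode = "undirected") |>
    igraph::set_vertex_attr("name", value = letters[1:5])
  expect_true(all(core_decomposition(star) == 1))
  for (seed in 1:4) {
    g <- random_named_graph(sample(20:100, 1), 0.08, seed)
    expect_identical(core_decomposition(g)[igraph::V(g)$name],
                     oracle_coreness(g))
    expect_true(all(core_decomposition(g) <= igraph::degree(g)))
  }
})

test_that("coreness normalization is column-stochastic with the right limits", {
  # uniform coreness reduces to uniform neighbor transition 1/degree
  ring <- ring_graph(6)
  W <- coreness_normalize(ring)
  expect_true(all(abs(Matrix::colSums(W) - 1) < 1e-12))
  expect_true(all(abs(W@x - 0.5) < 1e-12))

  # path a-b-c: column b splits 0.5/0.5
  path <- igraph::make_graph(~ a - b, b - c)
  Wp <- coreness_normalize(path)
  expect_equal(Wp["a", "b"], 0.5)
  expect_equal(Wp["c", "b"], 0.5)

  # mixed coreness on a 5-node toy graph, against hand arithmetic:
  # triangle a-b-c (coreness 2) with pendant d on c and pendant e on d
  g5 <- igraph::make_graph(~ a - b, b - c, a - c, c - d, d - e)
  core <- core_decomposition(g5)
  expect_identical(unname(core[c("a", "b", "c", "d", "e")]),
                   c(2L, 2L, 2L, 1L, 1L))
  W5 <- coreness_normalize(g5, core)
  # column c: neighbors a, b (coreness 2) and d (coreness 1) -> 2/5, 2/5, 1/5
  expect_equal(W5["a", "c"], 0.4)
  expect_equal(W5["b", "c"], 0.4)
  expect_equal(W5["d", "c"], 0.2)
  # column d: neighbors c (2) and e (1) -> 2/3, 1/3
  expect_equal(W5["c", "d"], 2 / 3)
  expect_equal(W5["e", "d"], 1 / 3)

  # isolated node keeps its mass via a self-transition
  iso <- igraph::make_graph(~ a - b) + igraph::vertices("z")
  Wi <- coreness_normalize(iso)
  expect_equal(Wi["z", "z"], 1)
  expect_true(all(abs(Matrix::colSums(Wi) - 1) < 1e-12))
})

test_that("random walk with restart conserves mass and solves the fixed point", {
  # pure restart never moves
  ring <- ring_graph(5)
  W <- coreness_normalize(ring)
  p0 <- stats::setNames(c(1, 0, 0, 0, 0), igraph::V(ring)$name)
  expect_equal(as.numeric(random_walk_with_restart(W, p0, restart = 1)),
               unname(p0))
  # two-node symmetry
  two <- igraph::make_graph(~ a - b)
  W2 <- coreness_normalize(two)
  st <- random_walk_with_restart(W2, c(a = 0.5, b = 0.5), 0.8)
  expect_equal(unname(st["a"]), 0.5, tolerance = 1e-9)

  # dense linear-solve oracle on larger random graphs
  for (seed in 1:3) {
    g <- random_named_graph(sample(50:200, 1), 0.05, seed + 10)
    Wg <- coreness_normalize(g)
    set.seed(seed)
    p0 <- runif(igraph::vcount(g)); p0 <- p0 / sum(p0)
    names(p0) <- igraph::V(g)$name
    st <- random_walk_with_restart(Wg, p0, 0.8, tol = 1e-12)
    expect_lt(max(abs(st - oracle_rwr(Wg, p0, 0.8))), 1e-8)
    expect_equal(sum(st), 1, tolerance = 1e-9)
  }

  # diffusion shrinks toward p0 as restart grows
  g <- random_named_graph(60, 0.08, 99)
  Wg <- coreness_normalize(g)
  p0 <- c(1, rep(0, 59)); names(p0) <- igraph::V(g)$name
  drift <- vapply(c(0.2, 0.5, 0.8, 0.99), function(r) {
    sum(abs(random_walk_with_restart(Wg, p0, r) - p0))
  }, numeric(1))
  expect_true(all(diff(drift) < 0))
})

test_that("seed selection takes the heaviest in-network genes and logs drops", {
  g <- random_named_graph(200, 0.05, 40)
  set.seed(41)
  w <- stats::setNames(runif(140), sample(igraph::V(g)$name, 140))
  names(w)[1:10] <- sprintf("off_net_%02d", 1:10)  # not in the graph
  seeds <- select_seeds(w, g, n_seeds = 100)
  expect_length(seeds, 100)
  expect_true(all(seeds %in% igraph::V(g)$name))
  expect_setequal(attr(seeds, "dropped"), names(w)[1:10])
  # exact top-k recovery on constructed weights
  in_net <- names(w)[-(1:10)]
  top <- in_net[order(-w[in_net], in_net)][1:100]
  expect_identical(unclass(seeds)[1:100], top)
  expect_warning(select_seeds(w[11:30], g, n_seeds = 100), "weighted genes")
})

test_that("permutation significance ranks constructed signal first", {
  # one loaded node on a symmetric ring: smallest p there
  ring <- ring_graph(12)
  W <- coreness_normalize(ring)
  p0 <- stats::setNames(c(0.9, rep(0.1 / 11, 11)), igraph::V(ring)$name)
  prop <- propagation_significance(W, p0, n_permutations = 200, seed = 7)
  expect_identical(names(which.min(prop$pvalues)), "n01")
  # exchangeable uniform weights: nothing can stand out
  pu <- stats::setNames(rep(1 / 12, 12), igraph::V(ring)$name)
  prop_u <- propagation_significance(W, pu, n_permutations = 50, seed = 7)
  expect_true(all(prop_u$pvalues == 1))
  expect_length(prop_u$significant, 0)
  expect_error(propagation_significance(W, pu, n_permutations = 0), "permutations")
})

test_that("modules are connected, disjoint, seed-anchored, and >= 2 genes", {
  g <- igraph::make_graph(~ A - C, C - B, D - E, F - G)
  mods <- identify_modules(g, seeds = c("A", "B", "D"), significant = "C")
  df <- as.data.frame(mods)
  expect_identical(sort(unique(df$module)), 1L)
  expect_setequal(df$gene, c("A", "B", "C"))
  expect_identical(df$role[df$gene == "C"], "inferred")
  expect_identical(sort(df$role), c("inferred", "seed", "seed"))
  expect_identical(attr(mods, "dropped_seeds"), "D")  # isolated seed dropped

  # a component with only inferred nodes is discarded
  mods2 <- identify_modules(g, seeds = "A", significant = c("C", "F", "G"))
  expect_false(any(c("F", "G") %in% as.data.frame(mods2)$gene))

  # structural invariants on randomized inputs
  for (seed in 1:4) {
    gr <- random_named_graph(80, 0.05, seed + 50)
    set.seed(seed)
    seeds <- sample(igraph::V(gr)$name, 12)
    signif <- sample(igraph::V(gr)$name, 20)
    ms <- as.data.frame(identify_modules(gr, seeds, signif))
    if (!nrow(ms)) next
    expect_false(anyDuplicated(ms$gene) > 0)  # disjoint
    for (mid in unique(ms$module)) {
      genes <- ms$gene[ms$module == mid]
      expect_gte(length(genes), 2)
      expect_true(any(genes %in% seeds))      # anchored
      sub <- igraph::induced_subgraph(gr, genes)
      expect_true(igraph::is_connected(sub))  # connected
    }
  }
})

test_that("the full propagation stage recovers a planted module", {
  truth <- synthetic_truth(400, n_informative = 10, seed = 60)
  g <- generate_ppi(100, 2, truth, seed = 60)
  set.seed(60)
  w <- stats::setNames(runif(50, 0, 0.2), sample(igraph::V(g)$name, 50))
  w[truth$informative_genes] <- 1
  res <- propagate_weights(g, w, n_seeds = 20, n_permutations = 1000, seed = 60)
  recovered <- mean(truth$informative_genes %in% res$propagation$significant)
  expect_gte(recovered, 0.8)
  expect_true(all(truth$informative_genes %in% res$modules$gene))
  p <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_propagation(res, p, m)
  expect_identical(nrow(read.delim(p)), as.integer(igraph::vcount(g)))
  expect_gt(nrow(read.delim(m)), 0)
})
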
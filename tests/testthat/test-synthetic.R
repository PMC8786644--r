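test_that("generators are deterministic under a fixed seed", {
  truth <- synthetic_truth(50, n_informative = 5, seed = 9)
  a <- generate_cohort(30, truth, "X", seed = 4)
  b <- generate_cohort(30, truth, "X", seed = 4)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)

  g1 <- generate_ppi(40, 2, truth, seed = 4)
  g2 <- generate_ppi(40, 2, truth, seed = 4)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("censoring machinery matches its closed form", {
  # no censoring process: every death observed
  t0 <- synthetic_truth(20, n_informative = 0, censor_rate = 0, seed = 2)
  ds0 <- generate_cohort(200, t0, seed = 2)
  expect_true(all(ds0$clinical$event == 1))

  # beta = 0, equal exponential rates: P(event) = l_e / (l_e + l_c) = 0.5
  t1 <- synthetic_truth(20, n_informative = 0, baseline_rate = 0.002,
                        censor_rate = 0.002, seed = 3)
  ds1 <- generate_cohort(10000, t1, seed = 3)
  expect_equal(mean(ds1$clinical$event), 0.5, tolerance = 0.02 / 0.5)

  # unequal rates: P(event) = 2/3
  t2 <- synthetic_truth(20, n_informative = 0, baseline_rate = 0.004,
                        censor_rate = 0.002, seed = 4)
  ds2 <- generate_cohort(10000, t2, seed = 4)
  expect_lt(abs(mean(ds2$clinical$event) - 2 / 3), 0.03)
})

test_that("planted effects drive the hazard in the right direction", {
  truth <- synthetic_truth(40, n_informative = 6, seed = 5,
                           beta_range = c(0.8, 1.2), censor_rate = 0.001)
  ds <- generate_cohort(800, truth, "cohort_1", seed = 5)
  active <- truth$informative_genes
  Z <- scale(ds$expression[, active])
  lp <- as.numeric(Z %*% truth$beta[active])
  unc <- ds$clinical$event == 1
  tau <- cor(lp[unc], ds$clinical$time[unc], method = "kendall")
  expect_lt(tau, 0)  # higher hazard, earlier death
})

test_that("shared/specific gene partition follows shared_fraction", {
  sim1 <- generate_pan_cancer(3, 20, n_genes = 40, n_informative = 9,
                              shared_fraction = 1, seed = 6)
  expect_setequal(sim1$truth$shared_genes, sim1$truth$informative_genes)
  expect_true(all(lengths(sim1$truth$cohort_specific) == 0))

  sim0 <- generate_pan_cancer(5, 20, n_genes = 60, n_informative = 10,
                              shared_fraction = 0, seed = 7)
  expect_length(sim0$truth$shared_genes, 0)
  expect_true(all(lengths(sim0$truth$cohort_specific) == 2))
  expect_setequal(unlist(sim0$truth$cohort_specific),
                  sim0$truth$informative_genes)

  # invariant: shared + specific = informative, disjointly
  sim <- generate_pan_cancer(4, 20, n_genes = 50, n_informative = 8,
                             shared_fraction = 0.5, seed = 8)
  expect_setequal(c(sim$truth$shared_genes, unlist(sim$truth$cohort_specific)),
                  sim$truth$informative_genes)
})

test_that("a 25-cohort simulation is fully trainable at the 20-uncensored rule", {
  sim <- generate_pan_cancer(25, 60, n_genes = 30, n_informative = 5, seed = 10)
  expr <- do.call(rbind, lapply(sim$cohorts, `[[`, "expression"))
  clin <- do.call(rbind, lapply(sim$cohorts, `[[`, "clinical"))
  parts <- assemble_cohorts(expr, clin)
  expect_length(parts$trainable, 25)
  expect_length(parts$heldout, 0)
})

test_that("the synthetic PPI is simple with a connected planted neighborhood", {
  truth <- synthetic_truth(200, n_informative = 10, seed = 11)
  g <- generate_ppi(120, 3, truth, seed = 11)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
  expect_true(all(truth$informative_genes %in% igraph::V(g)$name))
  sub <- igraph::induced_subgraph(g, truth$informative_genes)
  expect_true(igraph::is_connected(sub))

  expect_error(generate_ppi(5, 2, truth), "planted")
  expect_error(generate_ppi(150, 200, truth), "attachment")
})

test_that("ground-truth tables round-trip the planted structure", {
  sim <- generate_pan_cancer(2, 10, n_genes = 30, n_informative = 4,
                             shared_fraction = 0.5, seed = 12)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, p)
  df <- read.delim(p)
  expect_identical(nrow(df), 30L)
  expect_setequal(df$gene[df$beta != 0], sim$truth$informative_genes)
  expect_setequal(df$gene[df$shared_flag == 1], sim$truth$shared_genes)
})
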
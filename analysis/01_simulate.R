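#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
# Multi-cohort censored survival data with a partly shared prognostic
# signature, two small prediction-only cohorts, and a PPI-like network in
# which the planted genes form a connected module. All downstream scripts
# read the TSVs written here.

suppressMessages(library(pansurvnet))

seed <- 2026L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# 5 trainable cohorts x 80 patients over 300 genes, 10 prognostic genes of
# which 6 are shared across all cohorts and 4 are cohort-specific; ~50% censoring.
sim <- generate_pan_cancer(n_cohorts = 5, per_cohort_n = 80, n_genes = 300,
                           n_informative = 10, shared_fraction = 0.6,
                           seed = seed, beta_range = c(0.8, 1.2))

# two small prediction-only cohorts (below the 20-uncensored training
# threshold): one shares the planted signature, one carries no signal at all
heldout_shared <- generate_cohort(30, sim$truth, "heldout_shared",
                                  seed = derive_seed(seed, 100L))
null_truth <- synthetic_truth(300, n_informative = 0,
                              seed = derive_seed(seed, 102L))
heldout_null <- generate_cohort(30, null_truth, "heldout_null",
                                seed = derive_seed(seed, 101L))

all_ds <- c(sim$cohorts, list(heldout_shared = heldout_shared,
                              heldout_null = heldout_null))
expr <- do.call(rbind, lapply(all_ds, `[[`, "expression"))
clin <- do.call(rbind, lapply(all_ds, `[[`, "clinical"))
rownames(clin) <- NULL

write_expression_matrix(expr, file.path(out, "expression.tsv"))
utils::write.table(clin, file.path(out, "clinical.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_ground_truth(sim$truth, file.path(out, "ground_truth.tsv"))

ppi <- generate_ppi(n_nodes = 150, attachment = 2, truth = sim$truth,
                    seed = seed)
write_edge_list(ppi, file.path(out, "ppi_edges.tsv"))

parts <- assemble_cohorts(expr, clin)
message(sprintf("simulated %d patients in %d cohorts (%d trainable, %d held out)",
                nrow(expr), length(all_ds), length(parts$trainable),
                length(parts$heldout)))
message(sprintf("planted signature: %d genes (%d shared), PPI: %d nodes / %d edges",
                length(sim$truth$informative_genes),
                length(sim$truth$shared_genes),
                igraph::vcount(ppi), igraph::ecount(ppi)))
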
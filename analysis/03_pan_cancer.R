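#!/usr/bin/env Rscript
# Stage 3: pan-cancer training replications and held-out-cohort transfer.
# Training patients are pooled across the trainable cohorts (each cohort
# split 80/20 on its own); the single model per replication is evaluated on
# every cohort's test patients and, for the last replication's model, on the
# prediction-only cohorts that fell below the 20-uncensored threshold.

suppressMessages(library(pansurvnet))

seed <- 2026L
data_dir <- "results/data"
out <- "results/pan_cancer"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression_matrix(file.path(data_dir, "expression.tsv"))
clin <- read_clinical_table(file.path(data_dir, "clinical.tsv"))
parts <- assemble_cohorts(expr, clin)

cfg <- pipeline_config(
  n_replications = 5, n_select = 30, models_per_fold = 10, n_candidates = 8,
  hp_ranges = utils::modifyList(default_hp_ranges(),
                                list(n_trees = c(20L, 150L))))

reps <- run_replications(parts$trainable, "pan_cancer", cfg, seed = seed)
utils::write.table(reps$summary, file.path(out, "c_index.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# pan-cancer importance weights: gain summed over replications
weights <- aggregate_importance(replication_gains(reps))
write_gene_weights(weights, file.path(out, "weights_pan.tsv"))

# transfer to the held-out cohorts with the final replication's model
final_model <- reps$results[[cfg$n_replications]]$model
ho <- predict_heldout(final_model, parts$heldout)
utils::write.table(ho, file.path(out, "heldout_c_index.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("pan-cancer mean test C-index over %d replications: %.3f",
                cfg$n_replications, mean(reps$summary$c_index)))
single_path <- "results/single_cohort/c_index.tsv"
if (file.exists(single_path)) {
  single <- utils::read.delim(single_path)
  message(sprintf("single-cohort mean for comparison: %.3f",
                  mean(single$c_index)))
}
for (i in seq_len(nrow(ho))) {
  message(sprintf("held-out %s (n=%d): C-index %.3f",
                  ho$cohort[i], ho$n_patients[i], ho$c_index[i]))
}
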
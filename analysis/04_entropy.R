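#!/usr/bin/env Rscript
# Stage 4: cross-cohort entropy of the single-cohort importance weights.
# A gene weighted similarly in many cohorts scores high entropy (it
# generalizes); a gene weighted in one cohort scores zero. The top pan-cancer
# genes are expected to generalize better than the top single-cohort genes.

suppressMessages(library(pansurvnet))

out <- "results/entropy"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

single_dir <- "results/single_cohort"
files <- list.files(single_dir, pattern = "^weights_", full.names = TRUE)
stopifnot(length(files) >= 2)
cohorts <- sub("^weights_(.*)\\.tsv$", "\\1", basename(files))
weights <- stats::setNames(lapply(files, read_gene_weights), cohorts)

W <- cohort_weight_matrix(weights)
es <- entropy_scores(W)
utils::write.table(es, file.path(out, "entropy.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("%d genes scored over %d cohorts (max attainable entropy %.2f bits)",
                nrow(es), ncol(W), log2(ncol(W))))

# compare the top-20 pan-cancer genes with the top-20 single-cohort genes
pan <- read_gene_weights("results/pan_cancer/weights_pan.tsv")
single_total <- sort(rowSums(W), decreasing = TRUE)
top_pan <- intersect(names(sort(pan, decreasing = TRUE)), es$gene)[1:20]
top_single <- intersect(names(single_total), es$gene)[1:20]
H <- stats::setNames(es$entropy, es$gene)
message(sprintf("mean entropy, top-20 pan-cancer genes:    %.3f bits",
                mean(H[top_pan], na.rm = TRUE)))
message(sprintf("mean entropy, top-20 single-cohort genes: %.3f bits",
                mean(H[top_single], na.rm = TRUE)))
wt <- stats::wilcox.test(H[top_pan], H[top_single], alternative = "greater")
message(sprintf("one-sided Wilcoxon rank-sum p = %.3g", wt$p.value))
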
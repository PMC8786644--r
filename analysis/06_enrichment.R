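#!/usr/bin/env Rscript
# Stage 6: over-representation of the recovered module genes.
# A generic one-sided Fisher test of the module gene set against gene-set
# collections within an explicit universe (here: all network genes). The
# planted signature serves as the positive-control set; random sets of the
# same size as the planted one are the negative controls.

suppressMessages(library(pansurvnet))

seed <- 2026L
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ppi <- read_edge_list("results/data/ppi_edges.tsv")
universe <- igraph::V(ppi)$name
mods <- utils::read.delim("results/network/modules.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv")
planted <- intersect(truth$gene[truth$beta != 0], universe)

set.seed(seed)
collections <- c(
  list(planted_signature = planted),
  stats::setNames(lapply(1:5, function(i) sample(universe, length(planted))),
                  sprintf("random_set_%d", 1:5)))

# write and re-read the collections as GMT to exercise the standard format
gmt <- file.path(out, "collections.gmt")
writeLines(vapply(names(collections), function(nm) {
  paste(c(nm, "synthetic gene set", collections[[nm]]), collapse = "\t")
}, character(1)), gmt)
collections <- read_gmt(gmt)

query <- intersect(unique(mods$gene), universe)
res <- ora_fisher(query, collections, universe)
utils::write.table(res, file.path(out, "ora.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("query: %d module genes against %d sets in a %d-gene universe",
                length(query), length(collections), length(universe)))
top <- res[1, ]
message(sprintf("top set: %s (overlap %d/%d, p = %.3g, FDR = %.3g)",
                top$set, top$overlap, top$set_size, top$p_value, top$fdr))
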
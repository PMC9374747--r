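#!/usr/bin/env Rscript
# Step 4 — five-layer network assembly.
#
# Places responsive molecules on the InsulinSignal / TF / Enzyme /
# Metabolite layers, derives glucose-responsive Reaction nodes (reactions
# regulated by at least one responsive enzyme or metabolite), wires signed
# interlayer edges with per-genotype existence, and summarises regulation
# by source layer, T1/2 speed bin and top regulators.

suppressPackageStartupMessages(library(transomix))
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
kb <- read_knowledgebase("results/bundle/kb")
cms <- list()
for (layer in c("metabolite", "gene", "phospho"))
  cms[[layer]] <- read.delim(file.path("results/respond",
                                       paste0("response_classes_", layer, ".tsv")),
                             stringsAsFactors = FALSE)
edges <- read.delim("results/cluster/tf_gene_edges.tsv",
                    stringsAsFactors = FALSE)
net <- assemble_network(cms, kb, edges)
write.table(net$nodes, "results/network/nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$edges, "results/network/edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_network_gml(net, "results/network/network.gml")

summ <- regulation_summary(net)
cat("\nreactions regulated by Enzyme / Metabolite / both, per genotype:\n")
print(summ$by_source)
cat("\nreactions reached per regulator speed bin:\n")
print(summ$by_speed)
cat("\nregulators of more than 15 reactions:\n")
print(summ$top_regulators)
write.table(summ$by_source, "results/network/reactions_by_source.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
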
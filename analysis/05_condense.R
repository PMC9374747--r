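#!/usr/bin/env Rscript
# Step 5 — pathway-level condensation.
#
# Per genotype: regulator-pathway association tests (one-tailed Fisher,
# BH q <= 0.01) over all knowledge-base reactions, pathway selection
# (significant association OR top-10% regulated-reaction coverage by
# metabolites or enzyme genes), and the condensed network with weighted
# regulator -> pathway edges (metabolite edges kept at >= 5 regulated
# reactions; TFs kept at >= 5 regulated reactions in total).

suppressPackageStartupMessages(library(transomix))
dir.create("results/condensed", showWarnings = FALSE, recursive = TRUE)
kb <- read_knowledgebase("results/bundle/kb")
nodes <- read.delim("results/network/nodes.tsv", stringsAsFactors = FALSE)
edges <- read.delim("results/network/edges.tsv", stringsAsFactors = FALSE)
net <- structure(list(nodes = nodes, edges = edges),
                 class = "transomic_network")

for (g in c("WT", "OB")) {
  cn <- condense_network(net, kb, g)
  cat(sprintf("\n== %s: %d pathway nodes, %d regulators, %d edges\n",
              g, nrow(cn$pathways), nrow(cn$regulators), nrow(cn$edges)))
  print(cn$pathways[c("pathway_id", "class", "n_total", "n_by_metabolites",
                      "n_by_genes", "selected_by")])
  write.table(cn$edges, file.path("results/condensed",
                                  paste0("edges_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cn$coverage, file.path("results/condensed",
                                     paste0("coverage_", g, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nDone; condensed tables under results/condensed/\n")
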
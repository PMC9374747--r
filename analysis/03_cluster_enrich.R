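#!/usr/bin/env Rscript
# Step 3 — clustering and transcription-factor inference.
#
# Metabolites: geometric-mean/log2 normalization of the combined WT+OB
# traces and a Ward (Euclidean) dendrogram cut into 8 clusters. Genes:
# selection of baseline-different or responding genes, z-score
# normalization, Ward dendrogram, one-tailed Fisher motif enrichment at
# every node holding >= 100 genes (BH q <= 0.1) with the child-cluster
# exclusion rule, and TF -> gene edge inference. Checks whether the three
# planted TF clusters are recovered.

suppressPackageStartupMessages(library(transomix))
dir.create("results/cluster", showWarnings = FALSE, recursive = TRUE)

met_tc <- read_timecourse_table("results/bundle/metabolite.tsv", "metabolite")
met_mat <- normalize_metabolites(met_tc)
met_tree <- ward_tree(met_mat)
met_cl <- extract_clusters(met_tree, 8)
write.table(data.frame(molecule_id = names(met_cl), cluster = unname(met_cl)),
            "results/cluster/metabolite_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("metabolite cluster sizes (k = 8):\n")
print(table(met_cl))

gene_tc <- read_timecourse_table("results/bundle/gene.tsv", "gene")
kb <- read_knowledgebase("results/bundle/kb")
calls <- responsiveness_calls(gene_tc)
baseline <- baseline_difference_qvalues(gene_tc)
sel <- cluster_selection_filter(baseline, calls)
tree <- ward_tree(normalize_genes_zscore(gene_tc, sel))
enr <- enrich_tree_nodes(tree, kb$motif_targets, tree$leaves)
asg <- assign_tf_clusters(tree, enr)
edges <- infer_tf_gene_edges(asg, tree)
write.table(asg, "results/cluster/tf_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(edges, "results/cluster/tf_gene_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nassigned TF -> node pairs:\n")
print(asg[asg$assigned, c("tf_id", "node", "size", "odds_ratio", "q")])
cat(sprintf("\n%d TF-gene edges inferred for %d TFs\n",
            nrow(edges), length(unique(edges$tf_id))))
ptf <- read.delim("results/bundle/planted_tf_edges.tsv",
                  stringsAsFactors = FALSE)
planted <- split(ptf$gene_id, ptf$tf_id)
print(evaluate_tf_recovery(asg, tree, planted))
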
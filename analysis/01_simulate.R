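#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Draws the default study bundle: two genotypes (WT, ob/ob-like "OB")
# sampled at 0/20/60/120/240 min with n = 5 replicates; 104 metabolites of
# which 29 are planted responders (21 decreasing only in WT, 4 increasing
# and 4 decreasing only in OB), 700 genes containing three planted 120-gene
# co-regulated clusters driven by planted transcription factors, and 10
# phosphoproteins spanning signaling molecules, TFs and enzymes. Writes the
# pipeline input tables plus the planted truth under results/bundle/.

suppressPackageStartupMessages(library(transomix))
seed <- 1L
bundle <- generate_study_bundle(seed = seed)
write_study_bundle(bundle, "results/bundle")

tr <- bundle$truth
cat("Planted responders per layer:\n")
print(table(tr$layer, tr$pattern != "none"))
cat("\nMetabolite response composition (the study's Fig-2B-style split):\n")
met <- tr[tr$layer == "metabolite", ]
print(table(paste(met$pattern, met$direction_WT, met$direction_OB)))
cat("\nInputs written to results/bundle (seed", seed, ")\n")
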
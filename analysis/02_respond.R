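#!/usr/bin/env Rscript
# Step 2 — glucose-responsiveness calling.
#
# For every layer: detection filtering, log2 fold changes of replicate
# means versus the 0-min fasting baseline, per-time-point Welch (or scaled
# log2 Welch for counts) tests, Storey q-values, the q <= 0.1 and
# |log2FC| >= 0.585 conjunction, T1/2 half-times with rapid (< 20 min) /
# intermediate / slow (> 60 min) classes, and cross-genotype response
# classes. Compares the calls with the planted truth.

suppressPackageStartupMessages(library(transomix))
dir.create("results/respond", showWarnings = FALSE, recursive = TRUE)
truth <- read.delim("results/bundle/truth.tsv", stringsAsFactors = FALSE)

for (layer in c("metabolite", "gene", "phospho")) {
  tc <- read_timecourse_table(file.path("results/bundle",
                                        paste0(layer, ".tsv")), layer)
  calls <- responsiveness_calls(tc)
  cmap <- response_class_map(calls)
  write.table(calls, file.path("results/respond",
                               paste0("response_calls_", layer, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cmap, file.path("results/respond",
                              paste0("response_classes_", layer, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", layer, "classes:\n")
  print(table(cmap$class))
  m <- call_recovery_metrics(calls, truth[truth$layer == layer, ])
  cat(sprintf("recovery: sensitivity %.3f, direction %.3f, speed class %.3f\n",
              m$sensitivity, m$direction_accuracy, m$speed_accuracy))
}
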
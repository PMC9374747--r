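#' Run the full trans-omic pipeline on a study directory
#'
#' Orchestrates every stage over a directory of input tables (as written by
#' \code{\link{write_study_bundle}}): per-layer responsiveness calls and
#' cross-genotype classes; metabolite clustering; gene selection,
#' clustering, motif enrichment with child-cluster exclusion and TF-gene
#' edge inference; five-layer network assembly with validation; regulation
#' summaries; and per-genotype condensation. All artifacts are written
#' under \code{outdir} (TSV tables, GML networks and a JSON counts
#' summary). The run is deterministic given the inputs and
#' \code{config$random_seed}.
#'
#' @param input_dir directory with metabolite.tsv / gene.tsv / phospho.tsv
#'   (any subset; gene required for TF inference) and a kb/ subdirectory.
#' @param outdir output directory (created).
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list with calls, class maps, tree, enrichment,
#'   tf_gene_edges, network, summary and condensed networks.
#' @export
run_pipeline <- function(input_dir, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$random_seed)
  stage <- function(name, expr) {
    message("== stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tcs <- stage("read_inputs", {
    out <- list()
    for (layer in c("metabolite", "gene", "phospho")) {
      p <- file.path(input_dir, paste0(layer, ".tsv"))
      if (file.exists(p)) out[[layer]] <- read_timecourse_table(p, layer)
    }
    if (length(out) == 0L) stop("no omic tables found in ", input_dir)
    out
  })
  kb <- stage("read_knowledgebase", read_knowledgebase(file.path(input_dir, "kb")))

  calls <- list(); class_maps <- list()
  for (layer in names(tcs)) {
    calls[[layer]] <- stage(paste0("respond_", layer),
                            responsiveness_calls(tcs[[layer]], config))
    class_maps[[layer]] <- response_class_map(calls[[layer]])
    utils::write.table(calls[[layer]],
                       file.path(outdir, paste0("response_calls_", layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(class_maps[[layer]],
                       file.path(outdir, paste0("response_classes_", layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  met_clusters <- NULL
  if (!is.null(tcs$metabolite)) {
    met_clusters <- stage("cluster_metabolites", {
      mat <- normalize_metabolites(tcs$metabolite)
      if (nrow(mat) >= 2) {
        tree <- ward_tree(mat)
        k <- min(config$n_metabolite_clusters, nrow(mat))
        cl <- extract_clusters(tree, k)
        df <- data.frame(molecule_id = names(cl), cluster = unname(cl),
                         stringsAsFactors = FALSE)
        utils::write.table(df, file.path(outdir, "metabolite_clusters.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        df
      } else NULL
    })
  }

  tree <- NULL; enrichment <- NULL; assignments <- NULL
  tf_gene_edges <- data.frame(tf_id = character(0), gene_id = character(0))
  if (!is.null(tcs$gene)) {
    sel <- stage("select_genes", {
      baseline <- baseline_difference_qvalues(tcs$gene, config)
      cluster_selection_filter(baseline, calls$gene, config)
    })
    if (length(sel) >= 2) {
      tree <- stage("cluster_genes",
                    ward_tree(normalize_genes_zscore(tcs$gene, sel)))
      enrichment <- stage("enrich_motifs",
                          enrich_tree_nodes(tree, kb$motif_targets,
                                            tree$leaves, config))
      assignments <- stage("assign_tfs",
                           assign_tf_clusters(tree, enrichment, config))
      tf_gene_edges <- stage("infer_tf_edges",
                             infer_tf_gene_edges(assignments, tree))
      utils::write.table(assignments, file.path(outdir, "tf_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(tf_gene_edges, file.path(outdir, "tf_gene_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  net <- stage("assemble_network",
               assemble_network(class_maps, kb, tf_gene_edges, config))
  utils::write.table(net$nodes, file.path(outdir, "network_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, file.path(outdir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_gml(net, file.path(outdir, "network.gml"))

  summ <- stage("regulation_summary", regulation_summary(net, config))
  utils::write.table(summ$by_source, file.path(outdir, "reactions_by_source.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$by_speed, file.path(outdir, "reactions_by_speed.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summ$top_regulators))
    utils::write.table(summ$top_regulators,
                       file.path(outdir, "top_regulators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  condensed <- list()
  for (g in c("WT", "OB")) {
    condensed[[g]] <- stage(paste0("condense_", g),
                            condense_network(net, kb, g, config))
    utils::write.table(condensed[[g]]$edges,
                       file.path(outdir, paste0("condensed_edges_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(condensed[[g]]$coverage,
                       file.path(outdir, paste0("pathway_coverage_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  counts <- list(
    responsive = lapply(class_maps, function(m)
      as.list(table(factor(m$class, levels = c("WT_specific", "OB_specific",
                                               "common", "opposite", "none"))))),
    network = list(nodes_per_layer = as.list(table(net$nodes$layer)),
                   n_edges = nrow(net$edges)),
    reactions_by_source = summ$by_source,
    condensed = lapply(condensed, function(cn)
      list(n_pathways = nrow(cn$pathways), n_regulators = nrow(cn$regulators),
           n_edges = nrow(cn$edges))))
  jsonlite::write_json(counts, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls, class_maps = class_maps,
                 metabolite_clusters = met_clusters, tree = tree,
                 enrichment = enrichment, assignments = assignments,
                 tf_gene_edges = tf_gene_edges, network = net,
                 summary = summ, condensed = condensed))
}
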
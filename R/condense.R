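# Pathway-level condensation of the Reaction layer.
#
# Regulated-reaction sets per regulator and genotype. Metabolites regulate
# reactions directly (allosteric or substrate/product edges); transcription
# factors regulate reactions through the enzyme genes they control, counting
# only enzymes responsive at the transcript level (the condensed Enzyme layer
# excludes phosphorylation-only regulation); per-pathway gene coverage
# likewise counts transcript-level enzyme regulation.

regulator_reaction_sets <- function(net, genotype) {
  edges <- net$edges
  act <- edges[edges$target_layer == "Reaction" &
                 edges[[paste0("in_", genotype)]], , drop = FALSE]
  nodes <- net$nodes
  gene_basis <- nodes$id[nodes$layer == "Enzyme" & nodes$basis == "gene"]
  met <- lapply(split(act$target[act$source_layer == "Metabolite"],
                      act$source[act$source_layer == "Metabolite"]), unique)
  enz_act <- act[act$source_layer == "Enzyme" & act$source %in% gene_basis, ]
  enz <- lapply(split(enz_act$target, enz_act$source), unique)
  tf_edges <- edges[edges$regulation_type == "tf_to_enzyme_gene" &
                      edges[[paste0("in_", genotype)]], , drop = FALSE]
  tf <- lapply(split(tf_edges$target, tf_edges$source), function(enzs)
    unique(unlist(enz[intersect(enzs, names(enz))])))
  tf <- tf[lengths(tf) > 0]
  tf_enzymes <- lapply(split(tf_edges$target, tf_edges$source), unique)
  list(metabolites = met, enzymes = enz, tfs = tf, tf_enzymes = tf_enzymes)
}

#' Regulator-pathway association tests
#'
#' For each glucose-responsive regulator (metabolite or transcription
#' factor) and each pathway, tests whether the reactions the regulator
#' regulates are over-represented among the pathway's reactions, over the
#' universe of all knowledge-base reactions, with a one-tailed Fisher test.
#' p-values are Benjamini-Hochberg adjusted across all tested pairs and
#' called significant at q <= pathway_assoc_q (0.01 by default).
#'
#' @param net an assembled \code{transomic_network}.
#' @param kb a \code{knowledge_base}.
#' @param genotype "WT" or "OB".
#' @param config a \code{pipeline_config}.
#' @return data.frame(regulator, regulator_layer, pathway_id, overlap,
#'   n_regulated, n_pathway, p, q, significant).
#' @export
pathway_association_tests <- function(net, kb, genotype,
                                      config = pipeline_config()) {
  universe <- kb_reaction_ids(kb)
  pw_sets <- split(kb$reaction_pathways$reaction_id, kb$reaction_pathways$pathway_id)
  pw_sets <- lapply(pw_sets, unique)
  empty <- lengths(pw_sets) == 0L
  if (any(empty)) {
    warning("skipping pathway(s) with zero reactions: ",
            paste(names(pw_sets)[empty], collapse = ", "))
    pw_sets <- pw_sets[!empty]
  }
  sets <- regulator_reaction_sets(net, genotype)
  regs <- c(stats::setNames(sets$metabolites, names(sets$metabolites)),
            stats::setNames(sets$tfs, names(sets$tfs)))
  layers <- c(rep("Metabolite", length(sets$metabolites)),
              rep("TF", length(sets$tfs)))
  rows <- list()
  for (i in seq_along(regs)) {
    R <- intersect(regs[[i]], universe)
    for (pw in names(pw_sets)) {
      P <- pw_sets[[pw]]
      if (length(R) == 0L) {
        p <- 1; a <- 0L
      } else {
        fe <- fisher_enrichment(P, R, universe)
        p <- fe$p; a <- fe$table[["a"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        regulator = names(regs)[i], regulator_layer = layers[i],
        pathway_id = pw, overlap = a, n_regulated = length(R),
        n_pathway = length(P), p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(regulator = character(0), regulator_layer = character(0),
                      pathway_id = character(0), overlap = integer(0),
                      n_regulated = integer(0), n_pathway = integer(0),
                      p = numeric(0), q = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q <= config$pathway_assoc_q
  out
}

#' Per-pathway coverage by responsive metabolites and enzyme genes
#'
#' For each pathway, the number and fraction of its reactions regulated by
#' glucose-responsive metabolites and by glucose-responsive genes encoding
#' metabolic enzymes, in the given genotype.
#'
#' @param net an assembled \code{transomic_network}.
#' @param kb a \code{knowledge_base}.
#' @param genotype "WT" or "OB".
#' @return data.frame(pathway_id, class, n_total,
#'   n_by_metabolites, n_by_genes, frac_by_metabolites, frac_by_genes).
#' @export
pathway_coverage <- function(net, kb, genotype) {
  pw_sets <- split(kb$reaction_pathways$reaction_id, kb$reaction_pathways$pathway_id)
  pw_sets <- lapply(pw_sets, unique)
  cls <- stats::setNames(kb$pathway_class$class, kb$pathway_class$pathway_id)
  sets <- regulator_reaction_sets(net, genotype)
  met_rx <- unique(unlist(sets$metabolites))
  gene_rx <- unique(unlist(sets$enzymes))
  rows <- lapply(names(pw_sets), function(pw) {
    P <- pw_sets[[pw]]
    nm <- length(intersect(P, met_rx)); ng <- length(intersect(P, gene_rx))
    data.frame(pathway_id = pw,
               class = ifelse(pw %in% names(cls), cls[[pw]], "other"),
               n_total = length(P), n_by_metabolites = nm, n_by_genes = ng,
               frac_by_metabolites = nm / length(P),
               frac_by_genes = ng / length(P), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

top_fraction_ids <- function(coverage, column, fraction) {
  eligible <- coverage[coverage$n_by_metabolites + coverage$n_by_genes > 0, ,
                       drop = FALSE]
  if (nrow(eligible) == 0L) return(character(0))
  k <- ceiling(fraction * nrow(eligible))
  vals <- eligible[[column]]
  cut <- sort(vals, decreasing = TRUE)[k]
  eligible$pathway_id[vals >= cut & vals > 0]
}

#' Select the pathway nodes of the condensed network
#'
#' Union of (i) pathways with a significant association to any
#' glucose-responsive regulator and (ii) pathways in the top fraction
#' (10% by default) of the coverage ranking by metabolites or by enzyme
#' genes; the top set is the ceiling of the fraction times the number of
#' pathways with at least one regulated reaction, with ties included.
#'
#' @param associations output of \code{\link{pathway_association_tests}}.
#' @param coverage output of \code{\link{pathway_coverage}}.
#' @param config a \code{pipeline_config}.
#' @return data.frame(pathway_id, selected_by).
#' @export
select_pathway_nodes <- function(associations, coverage,
                                 config = pipeline_config()) {
  sig <- unique(associations$pathway_id[associations$significant])
  top_met <- top_fraction_ids(coverage, "frac_by_metabolites",
                              config$top_fraction_pathways)
  top_gene <- top_fraction_ids(coverage, "frac_by_genes",
                               config$top_fraction_pathways)
  ids <- union(sig, union(top_met, top_gene))
  if (length(ids) == 0L)
    return(data.frame(pathway_id = character(0), selected_by = character(0)))
  data.frame(pathway_id = ids,
             selected_by = vapply(ids, function(p) paste(
               c(if (p %in% sig) "association",
                 if (p %in% top_met) "top_metabolite_coverage",
                 if (p %in% top_gene) "top_gene_coverage"), collapse = ";"), ""),
             stringsAsFactors = FALSE)
}

#' Condense the Reaction layer into a Pathway layer
#'
#' Groups reactions into the selected pathway nodes and wires regulators to
#' pathways with weighted edges (weight = number of regulated reactions in
#' the pathway). Metabolite-to-pathway edges regulating fewer than
#' \code{min_reactions_per_condensed_edge} (5) reactions are removed;
#' metabolite regulators are kept only when significantly associated with
#' at least one selected pathway; transcription factors are kept only when
#' they regulate at least \code{min_reactions_per_tf_node} (5) metabolic
#' reactions in total (or enzymes, under the "enzymes" criterion), and
#' their pathway edges are not subject to the per-edge filter.
#'
#' @param net an assembled \code{transomic_network}.
#' @param kb a \code{knowledge_base}.
#' @param genotype "WT" or "OB".
#' @param config a \code{pipeline_config}.
#' @return a \code{condensed_network}: list(genotype, pathways, regulators,
#'   edges, associations, coverage).
#' @export
condense_network <- function(net, kb, genotype, config = pipeline_config()) {
  assoc <- pathway_association_tests(net, kb, genotype, config)
  coverage <- pathway_coverage(net, kb, genotype)
  selected <- select_pathway_nodes(assoc, coverage, config)
  pw_sets <- split(kb$reaction_pathways$reaction_id, kb$reaction_pathways$pathway_id)
  pw_sets <- lapply(pw_sets[selected$pathway_id], unique)
  sets <- regulator_reaction_sets(net, genotype)
  sig_assoc <- assoc[assoc$significant & assoc$pathway_id %in% selected$pathway_id, ]
  kept_mets <- unique(sig_assoc$regulator[sig_assoc$regulator_layer == "Metabolite"])
  tf_totals <- if (config$tf_condense_criterion == "reactions")
    lengths(sets$tfs) else lengths(sets$tf_enzymes[names(sets$tfs)])
  kept_tfs <- names(sets$tfs)[tf_totals >= config$min_reactions_per_tf_node]
  edge_rows <- list()
  add_edges <- function(ids, setlist, layer, min_weight) {
    for (r in ids) {
      R <- setlist[[r]]
      for (pw in names(pw_sets)) {
        w <- length(intersect(R, pw_sets[[pw]]))
        if (w >= min_weight && w > 0) {
          edge_rows[[length(edge_rows) + 1L]] <<- data.frame(
            regulator = r, regulator_layer = layer, pathway_id = pw,
            weight = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  add_edges(kept_mets, sets$metabolites, "Metabolite",
            config$min_reactions_per_condensed_edge)
  add_edges(kept_tfs, sets$tfs, "TF", 1L)
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(regulator = character(0), regulator_layer = character(0),
               pathway_id = character(0), weight = integer(0))
  if (nrow(edges)) {
    cm <- net$nodes$response_class[match(edges$regulator, net$nodes$id)]
    edges$genotype_class <- cm
  } else edges$genotype_class <- character(0)
  pw_cov <- coverage[match(selected$pathway_id, coverage$pathway_id), , drop = FALSE]
  pathways <- cbind(selected, pw_cov[setdiff(names(pw_cov), "pathway_id")])
  regulators <- data.frame(
    regulator = c(kept_mets, kept_tfs),
    layer = c(rep("Metabolite", length(kept_mets)), rep("TF", length(kept_tfs))),
    n_reactions = c(lengths(sets$metabolites[kept_mets]),
                    lengths(sets$tfs[kept_tfs])), stringsAsFactors = FALSE)
  structure(list(genotype = genotype, pathways = pathways,
                 regulators = regulators, edges = edges,
                 associations = assoc, coverage = coverage),
            class = "condensed_network")
}

#' @export
print.condensed_network <- function(x, ...) {
  cat(sprintf("<condensed_network> genotype=%s  %d pathways, %d regulators, %d edges\n",
              x$genotype, nrow(x$pathways), nrow(x$regulators), nrow(x$edges)))
  invisible(x)
}
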
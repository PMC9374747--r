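LAYERS <- c("InsulinSignal", "TF", "Enzyme", "Reaction", "Metabolite")
ALLOWED_LAYER_PAIRS <- data.frame(
  source_layer = c("InsulinSignal", "InsulinSignal", "TF", "Enzyme", "Metabolite"),
  target_layer = c("TF", "Enzyme", "Enzyme", "Reaction", "Reaction"),
  stringsAsFactors = FALSE)

#' Sign of an interlayer regulatory connection
#'
#' Positive when regulator and regulated molecule change in the same
#' direction (both increase or both decrease), negative when they change in
#' opposite directions.
#' @param regulator_direction,target_direction "increase" or "decrease".
#' @return "positive" or "negative".
#' @export
edge_sign <- function(regulator_direction, target_direction) {
  ok <- c("increase", "decrease")
  if (!regulator_direction %in% ok || !target_direction %in% ok)
    stop("directions must be 'increase' or 'decrease'")
  if (regulator_direction == target_direction) "positive" else "negative"
}

node_row <- function(id, layer, cm_row, basis) {
  data.frame(id = id, layer = layer, response_class = cm_row$class,
             direction_WT = cm_row$direction_WT, direction_OB = cm_row$direction_OB,
             t_half_WT = cm_row$t_half_WT, t_half_OB = cm_row$t_half_OB,
             speed_WT = cm_row$speed_WT, speed_OB = cm_row$speed_OB,
             responsive_WT = cm_row$responsive_WT,
             responsive_OB = cm_row$responsive_OB,
             basis = basis, stringsAsFactors = FALSE)
}

#' Assign glucose-responsive molecules to network layers
#'
#' Metabolite nodes are the responsive metabolites; Enzyme nodes the
#' metabolic-enzyme genes that are responsive at the transcript level or
#' carry responsive phosphorylation; TF nodes the transcription factors
#' responsive at the transcript level or with responsive phosphorylation;
#' InsulinSignal nodes the signaling molecules with responsive
#' phosphorylation. Roles come from the knowledge base and must be
#' disjoint. When both transcript and phosphorylation respond for the same
#' protein, the transcript basis wins and the phosphorylation is recorded
#' in \code{phospho_responsive}.
#'
#' @param class_maps list(metabolite, gene, phospho) of
#'   \code{\link{response_class_map}} outputs.
#' @param kb a \code{knowledge_base}.
#' @return node data.frame (one row per node).
#' @export
assign_layer_nodes <- function(class_maps, kb) {
  roles <- kb_roles(kb)
  overlap <- c(intersect(roles$tf_ids, roles$enzyme_ids),
               intersect(roles$tf_ids, roles$signal_ids),
               intersect(roles$enzyme_ids, roles$signal_ids))
  if (length(overlap))
    stop("molecule claimed in two layers: ", paste(unique(overlap), collapse = ", "))
  empty_map <- cm_empty_map()
  for (nm in c("metabolite", "gene", "phospho"))
    if (is.null(class_maps[[nm]])) class_maps[[nm]] <- empty_map
  rows <- list()
  cm <- class_maps$metabolite
  for (i in which(cm$class != "none"))
    rows[[length(rows) + 1L]] <- node_row(cm$molecule_id[i], "Metabolite",
                                          cm[i, ], "metabolite")
  gm <- class_maps$gene
  for (i in which(gm$class != "none")) {
    id <- gm$molecule_id[i]
    if (id %in% roles$enzyme_ids)
      rows[[length(rows) + 1L]] <- node_row(id, "Enzyme", gm[i, ], "gene")
    else if (id %in% roles$tf_ids)
      rows[[length(rows) + 1L]] <- node_row(id, "TF", gm[i, ], "gene")
  }
  nodes <- if (length(rows)) do.call(rbind, rows) else empty_nodes_frame()
  nodes$phospho_responsive <- logical(nrow(nodes))
  pm <- class_maps$phospho
  if (!is.null(pm)) {
    for (i in which(pm$class != "none")) {
      id <- pm$molecule_id[i]
      layer <- if (id %in% roles$signal_ids) "InsulinSignal"
      else if (id %in% roles$tf_ids) "TF"
      else if (id %in% roles$enzyme_ids) "Enzyme"
      else NA_character_
      if (is.na(layer)) next
      hit <- which(nodes$id == id & nodes$layer == layer)
      if (length(hit)) {
        nodes$phospho_responsive[hit] <- TRUE
      } else {
        nr <- node_row(id, layer, pm[i, ], "phospho")
        nr$phospho_responsive <- TRUE
        nodes <- rbind(nodes, nr)
      }
    }
  }
  message(sprintf("layer nodes: %d Metabolite, %d Enzyme, %d TF, %d InsulinSignal",
                  sum(nodes$layer == "Metabolite"), sum(nodes$layer == "Enzyme"),
                  sum(nodes$layer == "TF"), sum(nodes$layer == "InsulinSignal")))
  nodes
}

cm_empty_map <- function() {
  data.frame(molecule_id = character(0), class = character(0),
             direction_WT = character(0), direction_OB = character(0),
             t_half_WT = numeric(0), t_half_OB = numeric(0),
             speed_WT = character(0), speed_OB = character(0),
             responsive_WT = logical(0), responsive_OB = logical(0),
             stringsAsFactors = FALSE)
}

empty_nodes_frame <- function() {
  data.frame(id = character(0), layer = character(0),
             response_class = character(0), direction_WT = character(0),
             direction_OB = character(0), t_half_WT = numeric(0),
             t_half_OB = numeric(0), speed_WT = character(0),
             speed_OB = character(0), responsive_WT = logical(0),
             responsive_OB = logical(0), basis = character(0),
             stringsAsFactors = FALSE)
}

reaction_edge_rows <- function(src_ids, reaction_ids, type, nodes, src_layer) {
  idx <- match(src_ids, nodes$id)
  data.frame(source = src_ids, target = reaction_ids,
             source_layer = src_layer, target_layer = "Reaction",
             regulation_type = type,
             sign_WT = NA_character_, sign_OB = NA_character_,
             sign = "not_applicable",
             genotype_class = nodes$response_class[idx],
             in_WT = nodes$responsive_WT[idx], in_OB = nodes$responsive_OB[idx],
             repressor = NA, stringsAsFactors = FALSE)
}

#' Derive glucose-responsive reaction nodes and their regulating edges
#'
#' A metabolic reaction becomes a Reaction node iff at least one
#' glucose-responsive enzyme maps to it, or a glucose-responsive metabolite
#' regulates it allosterically or as substrate/product (reversibility being
#' undetermined, a reaction is assumed regulated by both its substrates and
#' products). Edges carry the regulator's response class; reaction nodes
#' themselves carry no direction.
#'
#' @param nodes node table from \code{\link{assign_layer_nodes}}.
#' @param kb a \code{knowledge_base}.
#' @return list(reaction_ids, edges).
#' @export
derive_reaction_nodes <- function(nodes, kb) {
  enz <- nodes$id[nodes$layer == "Enzyme"]
  met <- nodes$id[nodes$layer == "Metabolite"]
  ed <- list()
  er <- kb$enzyme_reactions[kb$enzyme_reactions$gene_id %in% enz, ]
  if (nrow(er))
    ed$enzyme <- reaction_edge_rows(er$gene_id, er$reaction_id,
                                    "enzyme_to_reaction", nodes, "Enzyme")
  al <- kb$allosteric[kb$allosteric$metabolite_id %in% met, ]
  if (nrow(al))
    ed$allosteric <- reaction_edge_rows(
      al$metabolite_id, al$reaction_id,
      ifelse(al$mode == "activator", "allosteric_activator", "allosteric_inhibitor"),
      nodes, "Metabolite")
  rm_ <- kb$reaction_metabolites[kb$reaction_metabolites$metabolite_id %in% met, ]
  if (nrow(rm_)) {
    sp <- unique(rm_[c("reaction_id", "metabolite_id")])
    ed$subprod <- reaction_edge_rows(sp$metabolite_id, sp$reaction_id,
                                     "substrate_or_product", nodes, "Metabolite")
  }
  edges <- if (length(ed)) unique(do.call(rbind, ed)) else
    empty_edges_frame()
  list(reaction_ids = unique(edges$target), edges = edges)
}

empty_edges_frame <- function() {
  data.frame(source = character(0), target = character(0),
             source_layer = character(0), target_layer = character(0),
             regulation_type = character(0), sign_WT = character(0),
             sign_OB = character(0), sign = character(0),
             genotype_class = character(0), in_WT = logical(0),
             in_OB = logical(0), repressor = logical(0),
             stringsAsFactors = FALSE)
}

signed_edge_row <- function(src, tgt, type, s_layer, t_layer,
                            src_resp, src_dir, tgt_resp, tgt_dir, repressor) {
  in_g <- c(WT = src_resp[["WT"]] && tgt_resp[["WT"]],
            OB = src_resp[["OB"]] && tgt_resp[["OB"]])
  if (!any(in_g)) return(NULL)
  sgn <- c(WT = NA_character_, OB = NA_character_)
  for (g in c("WT", "OB")) if (in_g[[g]])
    sgn[[g]] <- edge_sign(src_dir[[g]], tgt_dir[[g]])
  gclass <- if (all(in_g)) {
    if (sgn[["WT"]] == sgn[["OB"]]) "common" else "opposite"
  } else if (in_g[["WT"]]) "WT_specific" else "OB_specific"
  overall <- if (all(in_g)) {
    if (sgn[["WT"]] == sgn[["OB"]]) sgn[["WT"]] else "not_applicable"
  } else if (in_g[["WT"]]) sgn[["WT"]] else sgn[["OB"]]
  data.frame(source = src, target = tgt, source_layer = s_layer,
             target_layer = t_layer, regulation_type = type,
             sign_WT = sgn[["WT"]], sign_OB = sgn[["OB"]], sign = overall,
             genotype_class = gclass, in_WT = in_g[["WT"]], in_OB = in_g[["OB"]],
             repressor = repressor, stringsAsFactors = FALSE)
}

#' Build the signed interlayer edges among the upper layers
#'
#' Kinase-to-TF and kinase-to-enzyme edges come from the knowledge base's
#' kinase-target map; TF-to-enzyme edges from the inferred TF-gene
#' regulatory connections restricted to metabolic-enzyme genes. An edge
#' exists in a genotype only when both endpoints respond in it; the sign is
#' the direction concordance evaluated per genotype; the genotype class is
#' the conjunction rule (common only when present in both genotypes with
#' the same sign, opposite when present in both with conflicting signs).
#' TF repressor status is carried as an annotation and does not flip the
#' concordance sign.
#'
#' @param nodes node table.
#' @param kb a \code{knowledge_base}.
#' @param tf_gene_edges data.frame(tf_id, gene_id) of inferred connections.
#' @param gene_class_map gene-layer \code{\link{response_class_map}} (used
#'   for the transcript-level direction of TF targets).
#' @return edge data.frame.
#' @export
build_interlayer_edges <- function(nodes, kb, tf_gene_edges, gene_class_map) {
  getnode <- function(id, layer) {
    i <- which(nodes$id == id & nodes$layer == layer)
    if (length(i) == 0L) return(NULL)
    nodes[i[1], ]
  }
  resp_of <- function(row) c(WT = isTRUE(row$responsive_WT),
                             OB = isTRUE(row$responsive_OB))
  dir_of <- function(row) c(WT = row$direction_WT, OB = row$direction_OB)
  repr <- stats::setNames(kb$tf_mode$mode, kb$tf_mode$tf_id)
  out <- list()
  kt <- unique(kb$kinase_targets)
  for (i in seq_len(nrow(kt))) {
    src <- getnode(kt$signal_id[i], "InsulinSignal")
    t_layer <- if (kt$target_type[i] == "tf") "TF" else "Enzyme"
    tgt <- getnode(kt$target_id[i], t_layer)
    if (is.null(src) || is.null(tgt)) next
    out[[length(out) + 1L]] <- signed_edge_row(
      src$id, tgt$id,
      if (t_layer == "TF") "kinase_to_tf" else "kinase_to_enzyme",
      "InsulinSignal", t_layer,
      resp_of(src), dir_of(src), resp_of(tgt), dir_of(tgt), NA)
  }
  if (!is.null(tf_gene_edges) && nrow(tf_gene_edges)) {
    te <- unique(tf_gene_edges)
    for (i in seq_len(nrow(te))) {
      src <- getnode(te$tf_id[i], "TF")
      tgt <- getnode(te$gene_id[i], "Enzyme")
      if (is.null(src) || is.null(tgt)) next
      # TF edges act on transcription: the target must respond at the
      # transcript level, and signing uses the transcript direction
      gi <- which(gene_class_map$molecule_id == tgt$id)
      if (length(gi) == 0L) next
      g <- gene_class_map[gi[1], ]
      out[[length(out) + 1L]] <- signed_edge_row(
        src$id, tgt$id, "tf_to_enzyme_gene", "TF", "Enzyme",
        resp_of(src), dir_of(src),
        c(WT = isTRUE(g$responsive_WT), OB = isTRUE(g$responsive_OB)),
        c(WT = g$direction_WT, OB = g$direction_OB),
        identical(unname(repr[te$tf_id[i]]), "repressor"))
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else empty_edges_frame()
}

#' Assemble the five-layer glucose-responsive trans-omic network
#'
#' Runs layer-node assignment, reaction-node derivation and signed
#' interlayer edge construction, then validates the result.
#'
#' @param class_maps list(metabolite, gene, phospho) response class maps.
#' @param kb a \code{knowledge_base}.
#' @param tf_gene_edges inferred TF-gene connections.
#' @param config a \code{pipeline_config}.
#' @return a \code{transomic_network}: list(nodes, edges).
#' @export
assemble_network <- function(class_maps, kb, tf_gene_edges = NULL,
                             config = pipeline_config()) {
  nodes <- assign_layer_nodes(class_maps, kb)
  rx <- derive_reaction_nodes(nodes, kb)
  gene_map <- if (is.null(class_maps$gene)) cm_empty_map() else class_maps$gene
  signed <- build_interlayer_edges(nodes, kb, tf_gene_edges, gene_map)
  if (length(rx$reaction_ids)) {
    rnodes <- data.frame(id = rx$reaction_ids, layer = "Reaction",
                         response_class = "none",
                         direction_WT = "none", direction_OB = "none",
                         t_half_WT = NA_real_, t_half_OB = NA_real_,
                         speed_WT = "undefined", speed_OB = "undefined",
                         responsive_WT = NA, responsive_OB = NA,
                         basis = "reaction", phospho_responsive = FALSE,
                         stringsAsFactors = FALSE)
    nodes <- rbind(nodes, rnodes)
  }
  edges <- rbind(signed, rx$edges)
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "transomic_network")
  validate_network(net)
  message(sprintf("assembled network: %d nodes, %d edges",
                  nrow(nodes), nrow(edges)))
  net
}

#' @export
print.transomic_network <- function(x, ...) {
  cat(sprintf("<transomic_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$layer))
  invisible(x)
}

#' Validate a trans-omic network's structural invariants
#'
#' Checks the allowed layer pairs (InsulinSignal to TF/Enzyme, TF to
#' Enzyme, Enzyme/Metabolite to Reaction), that every Reaction node has at
#' least one incoming regulatory edge, that signs appear only on edges
#' among the signed layers, and that every edge's endpoints are responsive
#' in each genotype the edge exists in (the regulator alone, for Reaction
#' targets).
#' @param net a \code{transomic_network}.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (nrow(edges)) {
    pair <- paste(edges$source_layer, edges$target_layer)
    okpair <- paste(ALLOWED_LAYER_PAIRS$source_layer, ALLOWED_LAYER_PAIRS$target_layer)
    if (!all(pair %in% okpair))
      stop("edge between disallowed layers: ", pair[!pair %in% okpair][1])
    to_rx <- edges$target_layer == "Reaction"
    if (any(edges$sign[to_rx] != "not_applicable"))
      stop("edges into the Reaction layer must carry no sign")
    if (any(!edges$in_WT & !edges$in_OB))
      stop("edge present in neither genotype")
    resp <- function(ids, layer, g) {
      i <- match(paste(ids, layer), paste(nodes$id, nodes$layer))
      nodes[[paste0("responsive_", g)]][i]
    }
    for (g in c("WT", "OB")) {
      act <- edges[[paste0("in_", g)]]
      if (any(act & !resp(edges$source, edges$source_layer, g)))
        stop("edge regulator not responsive in ", g)
      sub <- act & !to_rx
      if (any(sub & !resp(edges$target, edges$target_layer, g)))
        stop("edge target not responsive in ", g)
    }
  }
  rx_nodes <- nodes$id[nodes$layer == "Reaction"]
  fed <- unique(edges$target[edges$target_layer == "Reaction"])
  if (!all(rx_nodes %in% fed))
    stop("Reaction node without incoming regulation: ",
         setdiff(rx_nodes, fed)[1])
  invisible(TRUE)
}

#' Regulation summaries of an assembled network
#'
#' Per genotype: (i) counts of reaction nodes regulated by the Enzyme layer
#' only, the Metabolite layer only, or both; (ii) counts of reactions
#' reached by regulators in each T1/2 speed bin; (iii) the regulators
#' (metabolites directly, transcription factors through their enzyme
#' targets) whose regulated-reaction count strictly exceeds the display
#' threshold.
#'
#' @param net a \code{transomic_network}.
#' @param config a \code{pipeline_config}.
#' @return list(by_source, by_speed, top_regulators) data frames.
#' @export
regulation_summary <- function(net, config = pipeline_config()) {
  nodes <- net$nodes; edges <- net$edges
  rx_edges <- edges[edges$target_layer == "Reaction", , drop = FALSE]
  by_source <- list(); by_speed <- list(); top <- list()
  for (g in c("WT", "OB")) {
    act <- rx_edges[rx_edges[[paste0("in_", g)]], , drop = FALSE]
    per_rx <- split(act$source_layer, act$target)
    kinds <- vapply(per_rx, function(l) {
      has_e <- "Enzyme" %in% l; has_m <- "Metabolite" %in% l
      if (has_e && has_m) "both" else if (has_e) "enzyme_only" else "metabolite_only"
    }, "")
    by_source[[g]] <- data.frame(
      genotype = g,
      enzyme_only = sum(kinds == "enzyme_only"),
      metabolite_only = sum(kinds == "metabolite_only"),
      both = sum(kinds == "both"),
      n_reactions = length(kinds), stringsAsFactors = FALSE)
    spd <- nodes[[paste0("speed_", g)]][match(paste(act$source, act$source_layer),
                                              paste(nodes$id, nodes$layer))]
    for (bin in c("rapid", "intermediate", "slow")) {
      by_speed[[paste(g, bin)]] <- data.frame(
        genotype = g, speed = bin,
        n_reactions = length(unique(act$target[spd == bin])),
        stringsAsFactors = FALSE)
    }
    met_counts <- vapply(split(act$target[act$source_layer == "Metabolite"],
                               act$source[act$source_layer == "Metabolite"]),
                         function(x) length(unique(x)), 0L)
    tf_edges <- edges[edges$regulation_type == "tf_to_enzyme_gene" &
                        edges[[paste0("in_", g)]], , drop = FALSE]
    enz_rx <- split(act$target[act$source_layer == "Enzyme"],
                    act$source[act$source_layer == "Enzyme"])
    tf_counts <- vapply(split(tf_edges$target, tf_edges$source), function(enzs)
      length(unique(unlist(enz_rx[enzs]))), 0L)
    thr <- config$display_min_reactions_top_regulators
    reg <- rbind(
      if (length(met_counts)) data.frame(genotype = g, regulator = names(met_counts),
                                         layer = "Metabolite",
                                         n_reactions = as.integer(met_counts),
                                         stringsAsFactors = FALSE),
      if (length(tf_counts)) data.frame(genotype = g, regulator = names(tf_counts),
                                        layer = "TF",
                                        n_reactions = as.integer(tf_counts),
                                        stringsAsFactors = FALSE))
    if (!is.null(reg)) {
      reg <- reg[reg$n_reactions > thr, , drop = FALSE]
      top[[g]] <- reg[order(-reg$n_reactions), , drop = FALSE]
    }
  }
  list(by_source = do.call(rbind, c(by_source, list(make.row.names = FALSE))),
       by_speed = do.call(rbind, c(by_speed, list(make.row.names = FALSE))),
       top_regulators = do.call(rbind, c(top, list(make.row.names = FALSE))))
}
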
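#' One-tailed Fisher enrichment of a motif in a cluster
#'
#' Builds the 2x2 table (in-cluster with motif, in-cluster without,
#' out-of-cluster with, out-of-cluster without) over the background
#' universe, and returns the enrichment-direction hypergeometric tail
#' p-value P[X >= a] together with the sample odds ratio (a*d)/(b*c).
#' Zero cells give exact 0 or Inf odds ratios; no continuity correction is
#' applied, so ties between clusters compare exactly.
#'
#' @param cluster_genes genes in the cluster (subset of background).
#' @param motif_genes genes carrying the motif (subset of background).
#' @param background the gene universe.
#' @return list(odds_ratio, p, table) with table = c(a, b, c, d).
#' @export
fisher_enrichment <- function(cluster_genes, motif_genes, background) {
  background <- unique(background)
  cluster_genes <- unique(cluster_genes)
  motif_genes <- unique(motif_genes)
  if (length(background) == 0L) stop("empty background")
  if (length(cluster_genes) == 0L) stop("empty cluster")
  if (!all(cluster_genes %in% background) || !all(motif_genes %in% background))
    stop("cluster and motif genes must be subsets of the background")
  N <- length(background)
  K <- length(motif_genes)
  n <- length(cluster_genes)
  a <- length(intersect(cluster_genes, motif_genes))
  b <- n - a
  cc <- K - a
  d <- N - n - cc
  orat <- if (b == 0 || cc == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  list(odds_ratio = orat, p = p, table = c(a = a, b = b, c = cc, d = d))
}

#' Motif enrichment at every large dendrogram node
#'
#' Evaluates \code{\link{fisher_enrichment}} for every transcription-factor
#' motif at every internal tree node holding at least
#' \code{min_cluster_size_for_enrichment} genes, adjusts the p-values with
#' Benjamini-Hochberg across all (TF, node) tests, and marks enrichment at
#' q <= enrichment_q.
#'
#' @param tree a \code{cluster_tree} over the selected genes.
#' @param motif_targets data.frame(tf_id, gene_id).
#' @param background gene universe (the clustered genes).
#' @param config a \code{pipeline_config}.
#' @return data.frame(tf_id, node, size, a, b, c, d, odds_ratio, p, q,
#'   enriched).
#' @export
enrich_tree_nodes <- function(tree, motif_targets, background,
                              config = pipeline_config()) {
  nodes <- tree_node_leaves(tree)
  sizes <- lengths(nodes$leaves)
  test_nodes <- which(sizes >= config$min_cluster_size_for_enrichment)
  background <- intersect(unique(background), tree$leaves)
  tf_sets <- split(motif_targets$gene_id, motif_targets$tf_id)
  tf_sets <- lapply(tf_sets, function(g) intersect(unique(g), background))
  rows <- list()
  for (nd in test_nodes) {
    cl <- intersect(nodes$leaves[[nd]], background)
    if (length(cl) == 0L || length(cl) == length(background)) next
    for (tf in names(tf_sets)) {
      fe <- fisher_enrichment(cl, tf_sets[[tf]], background)
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, node = nd, size = length(cl),
        a = fe$table[["a"]], b = fe$table[["b"]],
        c = fe$table[["c"]], d = fe$table[["d"]],
        odds_ratio = fe$odds_ratio, p = fe$p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tf_id = character(0), node = integer(0),
                      size = integer(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out$enriched <- out$q <= config$enrichment_q
  message(sprintf("motif enrichment: %d tests on %d nodes, %d enriched",
                  nrow(out), length(test_nodes), sum(out$enriched)))
  out
}

#' Assign transcription factors to dendrogram nodes with child exclusion
#'
#' A TF is assigned to a node when (i) its motif is significantly enriched
#' there and (ii) no descendant node above the size threshold is more
#' enriched for that motif (strictly greater odds ratio by default, or
#' strictly smaller p-value with the "p_value" comparator); ties keep the
#' ancestor. This avoids attributing to a broad cluster a signal that is
#' concentrated in one of its large sub-clusters.
#'
#' @param tree a \code{cluster_tree}.
#' @param enrichment output of \code{\link{enrich_tree_nodes}}.
#' @param config a \code{pipeline_config}.
#' @return the enrichment table with columns \code{excluded_by_child}
#'   (node index or NA) and \code{assigned}.
#' @export
assign_tf_clusters <- function(tree, enrichment, config = pipeline_config()) {
  nodes <- tree_node_leaves(tree)
  enrichment$excluded_by_child <- NA_integer_
  enrichment$assigned <- FALSE
  if (nrow(enrichment) == 0L) return(enrichment)
  better <- function(child_val, parent_val) {
    if (config$enrichment_comparator == "odds_ratio") {
      # NaN odds ratios (degenerate tables) never beat the parent
      !is.nan(child_val) && !is.nan(parent_val) && child_val > parent_val ||
        (!is.nan(child_val) && is.nan(parent_val))
    } else {
      child_val < parent_val
    }
  }
  metric <- if (config$enrichment_comparator == "odds_ratio")
    enrichment$odds_ratio else enrichment$p
  for (i in which(enrichment$enriched)) {
    nd <- enrichment$node[i]
    tf <- enrichment$tf_id[i]
    desc <- nodes$children[[nd]]
    cand <- which(enrichment$tf_id == tf & enrichment$node %in% desc)
    for (j in cand) {
      if (better(metric[j], metric[i])) {
        enrichment$excluded_by_child[i] <- enrichment$node[j]
        break
      }
    }
    enrichment$assigned[i] <- is.na(enrichment$excluded_by_child[i])
  }
  enrichment
}

#' Infer TF-to-gene regulatory edges from node assignments
#'
#' One edge from each assigned transcription factor to every gene in its
#' assigned node(s); duplicates collapse.
#' @param assignments output of \code{\link{assign_tf_clusters}}.
#' @param tree the \code{cluster_tree} the assignments refer to.
#' @return data.frame(tf_id, gene_id), deduplicated.
#' @export
infer_tf_gene_edges <- function(assignments, tree) {
  nodes <- tree_node_leaves(tree)
  sel <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(tf_id = character(0), gene_id = character(0)))
  rows <- lapply(seq_len(nrow(sel)), function(i)
    data.frame(tf_id = sel$tf_id[i], gene_id = nodes$leaves[[sel$node[i]]],
               stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Validate inferred targets against external (ChIP-derived) target sets
#'
#' One-tailed Fisher overlap test per transcription factor between the
#' inferred target genes and an externally derived target set, with
#' Benjamini-Hochberg adjustment across TFs and a significance flag at
#' q <= 0.1.
#'
#' @param inferred named list of inferred target-gene vectors per TF.
#' @param external named list of external target-gene vectors per TF.
#' @param background gene universe.
#' @param q_cutoff significance threshold on q.
#' @return data.frame(tf_id, n_inferred, n_external, overlap, odds_ratio,
#'   p, q, significant).
#' @export
validate_against_external_targets <- function(inferred, external, background,
                                              q_cutoff = 0.1) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  tfs <- intersect(names(inferred), names(external))
  rows <- lapply(tfs, function(tf) {
    inf <- intersect(unique(inferred[[tf]]), background)
    ext <- intersect(unique(external[[tf]]), background)
    if (length(inf) == 0L) {
      return(data.frame(tf_id = tf, n_inferred = 0L, n_external = length(ext),
                        overlap = 0L, odds_ratio = NA_real_, p = 1,
                        stringsAsFactors = FALSE))
    }
    fe <- fisher_enrichment(inf, ext, background)
    data.frame(tf_id = tf, n_inferred = length(inf), n_external = length(ext),
               overlap = fe$table[["a"]], odds_ratio = fe$odds_ratio, p = fe$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q <= q_cutoff
  out
}
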
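#' Combined WT+OB log-ratio matrix for metabolites
#'
#' Each metabolite's WT and OB mean time courses are divided by the
#' geometric mean of the two genotypes' fasting (0-min) means, then
#' log2-transformed, and the two traces are concatenated (WT block first).
#' Metabolites with a zero or missing fasting mean in either genotype are
#' excluded with a warning.
#'
#' @param tc a metabolite \code{omics_timecourse}.
#' @return numeric matrix, rows = molecules, columns = WT times then OB
#'   times.
#' @export
normalize_metabolites <- function(tc) {
  mt <- tc_mean_traces(tc)
  times <- as.character(tc_times(tc))
  gm <- sqrt(mt[, "WT", "0"] * mt[, "OB", "0"])
  ok <- is.finite(gm) & gm > 0
  if (any(!ok))
    warning(sum(!ok), " molecule(s) excluded: zero or missing fasting mean")
  mat <- cbind(log2(genotype_trace_matrix(mt, "WT")[ok, , drop = FALSE] / gm[ok]),
               log2(genotype_trace_matrix(mt, "OB")[ok, , drop = FALSE] / gm[ok]))
  colnames(mat) <- c(paste0("WT_", times), paste0("OB_", times))
  rownames(mat) <- tc_molecules(tc)[ok]
  mat
}

# molecule x time matrix of one genotype's mean traces
genotype_trace_matrix <- function(mt, genotype) {
  m <- mt[, genotype, , drop = FALSE]
  dim(m) <- dim(mt)[c(1, 3)]
  dimnames(m) <- dimnames(mt)[c(1, 3)]
  m
}

#' Combined WT+OB z-scored matrix for genes
#'
#' Each gene's concatenated (WT, OB) mean time course is centred on its own
#' mean and divided by its standard deviation (z-score normalization).
#' Constant traces are excluded with a warning.
#'
#' @param tc a gene \code{omics_timecourse}.
#' @param gene_ids optional subset of molecules to normalize.
#' @return numeric matrix with row mean 0 and sd 1.
#' @export
normalize_genes_zscore <- function(tc, gene_ids = NULL) {
  mt <- tc_mean_traces(tc)
  times <- as.character(tc_times(tc))
  mat <- cbind(genotype_trace_matrix(mt, "WT"), genotype_trace_matrix(mt, "OB"))
  colnames(mat) <- c(paste0("WT_", times), paste0("OB_", times))
  rownames(mat) <- tc_molecules(tc)
  if (!is.null(gene_ids)) mat <- mat[rownames(mat) %in% gene_ids, , drop = FALSE]
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  ok <- is.finite(sdv) & sdv > 0 & !apply(mat, 1, anyNA)
  if (any(!ok))
    warning(sum(!ok), " gene(s) excluded: constant or incomplete trace")
  (mat[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
}

#' Select genes for the clustering analysis
#'
#' Union of genes that differ between genotypes at the fasting baseline
#' (q <= q_threshold in the 0-min WT-versus-OB test) and genes with a
#' significant response at any post-administration time point in either
#' genotype (q <= q_threshold; no fold-change condition here).
#'
#' @param baseline data.frame(molecule_id, q) from
#'   \code{\link{baseline_difference_qvalues}}.
#' @param calls responsiveness calls for the gene layer.
#' @param config a \code{pipeline_config}.
#' @return character vector of selected gene ids.
#' @export
cluster_selection_filter <- function(baseline, calls,
                                     config = pipeline_config()) {
  base_sel <- baseline$molecule_id[!is.na(baseline$q) &
                                     baseline$q <= config$q_threshold]
  qcols <- grep("^q_", names(calls), value = TRUE)
  any_sig <- apply(calls[qcols], 1, function(v)
    any(!is.na(v) & v <= config$q_threshold))
  resp_sel <- unique(calls$molecule_id[any_sig])
  sel <- union(base_sel, resp_sel)
  message(sprintf("cluster selection: %d genes (%d baseline-different, %d responding)",
                  length(sel), length(base_sel), length(resp_sel)))
  sel
}

#' Ward dendrogram on Euclidean distances
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion on Euclidean distances (hclust method "ward.D2", whose
#' Lance-Williams update operates on squared distances). Merge heights are
#' non-decreasing.
#'
#' @param mat numeric matrix (rows clustered); no missing values.
#' @return a \code{cluster_tree}: the hclust object plus leaf labels.
#' @export
ward_tree <- function(mat) {
  if (anyNA(mat)) stop("matrix contains missing values; normalize first")
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  structure(list(hclust = hc, leaves = rownames(mat)), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %d merges\n",
              length(x$leaves), nrow(x$hclust$merge)))
  invisible(x)
}

#' Cut a dendrogram into k disjoint clusters
#'
#' @param tree a \code{cluster_tree}.
#' @param k number of clusters (1..number of leaves).
#' @return named integer vector: cluster index per leaf.
#' @export
extract_clusters <- function(tree, k) {
  n <- length(tree$leaves)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  stats::cutree(tree$hclust, k = k)
}

#' Leaf sets of every internal dendrogram node
#'
#' Enumerates each internal merge node of the tree with the ids of its
#' descendant leaves; node i corresponds to row i of the hclust merge
#' matrix. Used to test motif enrichment at every node above the size
#' threshold rather than at one fixed cut.
#'
#' @param tree a \code{cluster_tree}.
#' @return list with elements \code{leaves} (list of leaf-id vectors per
#'   node) and \code{children} (list of internal-node children indices per
#'   node, descendants excluded).
#' @export
tree_node_leaves <- function(tree) {
  merge <- tree$hclust$merge
  labels <- tree$hclust$labels
  n <- nrow(merge)
  leaves <- vector("list", n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    lv <- character(0)
    ch <- integer(0)
    for (side in 1:2) {
      m <- merge[i, side]
      if (m < 0) {
        lv <- c(lv, labels[-m])
      } else {
        lv <- c(lv, leaves[[m]])
        ch <- c(ch, m, children[[m]])
      }
    }
    leaves[[i]] <- lv
    children[[i]] <- ch
  }
  list(leaves = leaves, children = children)
}
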
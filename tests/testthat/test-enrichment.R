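test_that("Fisher enrichment reproduces the worked 2x2 table", {
  bg <- paste0("g", 1:100)
  cluster <- bg[1:10]
  motif <- c(bg[1:4], bg[11:16])      # 4 in-cluster hits, 10 total
  fe <- fisher_enrichment(cluster, motif, bg)
  expect_equal(fe$odds_ratio, (4 * 84) / (6 * 6), tolerance = 1e-12)
  expect_equal(fe$p, hyper_tail_oracle(4, 10, 10, 100), tolerance = 1e-14)
})

test_that("proportional hits give odds ratio 1 and zero hits give p = 1", {
  bg <- paste0("g", 1:100)
  cluster <- bg[1:20]
  motif <- c(bg[1:4], bg[21:36])      # 20% rate inside and outside
  expect_equal(fisher_enrichment(cluster, motif, bg)$odds_ratio, 1)
  none <- fisher_enrichment(cluster, bg[50:59], bg)
  expect_equal(none$p, 1)
  expect_equal(none$odds_ratio, 0)
  expect_error(fisher_enrichment(character(0), motif, bg), "empty cluster")
  expect_error(fisher_enrichment(cluster, motif, character(0)), "empty background|subsets")
})

test_that("zero-cell odds ratios are exact 0 or Inf without correction", {
  bg <- paste0("g", 1:20)
  expect_equal(fisher_enrichment(bg[1:5], bg[1:5], bg)$odds_ratio, Inf)
  expect_equal(fisher_enrichment(bg[1:5], bg[6:10], bg)$odds_ratio, 0)
})

test_that("child-cluster exclusion follows the strictly-greater rule", {
  # hand-built tree: two tight 6-leaf groups that merge last
  set.seed(31)
  mat <- rbind(matrix(rnorm(18, 0, 0.05), 6, 3),
               matrix(rnorm(18, 9, 0.05), 6, 3))
  rownames(mat) <- paste0("g", 1:12)
  tree <- ward_tree(mat)
  nodes <- tree_node_leaves(tree)
  cfg <- pipeline_config(min_cluster_size_for_enrichment = 3)
  parent <- which(lengths(nodes$leaves) == 12)        # root
  child <- which(vapply(nodes$leaves, function(l)
    setequal(l, paste0("g", 1:6)), TRUE))
  mk_enrich <- function(or_parent, or_child) {
    data.frame(tf_id = "tf1", node = c(parent, child), size = c(12, 6),
               a = 0, b = 0, c = 0, d = 0,
               odds_ratio = c(or_parent, or_child), p = c(0.001, 0.001),
               q = c(0.001, 0.001), enriched = TRUE)
  }
  res <- assign_tf_clusters(tree, mk_enrich(3, 5), cfg)
  expect_false(res$assigned[res$node == parent])
  expect_equal(res$excluded_by_child[res$node == parent], child)
  expect_true(res$assigned[res$node == child])
  # tie keeps the ancestor
  tie <- assign_tf_clusters(tree, mk_enrich(4, 4), cfg)
  expect_true(tie$assigned[tie$node == parent])
  # children below the size threshold cannot exclude
  big <- pipeline_config(min_cluster_size_for_enrichment = 8)
  solo <- mk_enrich(3, 5)[1, , drop = FALSE]   # only the parent was testable
  res2 <- assign_tf_clusters(tree, solo, big)
  expect_true(res2$assigned)
})

test_that("no assigned node has a larger-odds descendant after exclusion", {
  set.seed(32)
  for (rep in 1:5) {
    mat <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
    tree <- ward_tree(mat)
    bg <- rownames(mat)
    motif <- data.frame(tf_id = "tf1",
                        gene_id = sample(bg, 8))
    cfg <- pipeline_config(min_cluster_size_for_enrichment = 4,
                           enrichment_q = 0.9)
    enr <- suppressMessages(enrich_tree_nodes(tree, motif, bg, cfg))
    asg <- assign_tf_clusters(tree, enr, cfg)
    nodes <- tree_node_leaves(tree)
    for (i in which(asg$assigned)) {
      desc <- nodes$children[[asg$node[i]]]
      rivals <- asg$odds_ratio[asg$tf_id == asg$tf_id[i] & asg$node %in% desc]
      rivals <- rivals[!is.nan(rivals)]
      if (length(rivals) && !is.nan(asg$odds_ratio[i]))
        expect_lte(max(rivals), asg$odds_ratio[i] + 1e-12)
    }
  }
})

test_that("TF-gene edges enumerate assigned cluster members once", {
  set.seed(33)
  mat <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("g", 1:12), NULL))
  tree <- ward_tree(mat)
  nodes <- tree_node_leaves(tree)
  nd <- which(lengths(nodes$leaves) == 12)
  asg <- data.frame(tf_id = "tf1", node = nd, size = 12, a = 0, b = 0,
                    c = 0, d = 0, odds_ratio = 2, p = 0.01, q = 0.01,
                    enriched = TRUE, excluded_by_child = NA_integer_,
                    assigned = TRUE)
  edges <- infer_tf_gene_edges(asg, tree)
  expect_equal(nrow(edges), 12L)
  expect_setequal(edges$gene_id, paste0("g", 1:12))
  none <- infer_tf_gene_edges(asg[0, ], tree)
  expect_equal(nrow(none), 0L)
  # duplicated assignment rows collapse to the same edge set
  edges2 <- infer_tf_gene_edges(rbind(asg, asg), tree)
  expect_equal(nrow(edges2), 12L)
})

test_that("external-target validation flags perfect overlap, not disjoint sets", {
  bg <- paste0("g", 1:1000)
  res <- validate_against_external_targets(
    inferred = list(tfX = bg[1:50], tfY = bg[1:50], tfZ = bg[101:150]),
    external = list(tfX = bg[1:50], tfY = bg[51:100], tfZ = bg),
    background = bg)
  expect_true(res$significant[res$tf_id == "tfX"])
  expect_lt(res$p[res$tf_id == "tfX"], 1e-20)
  expect_equal(res$p[res$tf_id == "tfY"], 1)   # disjoint
  expect_equal(res$p[res$tf_id == "tfZ"], 1)   # external = background
})
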
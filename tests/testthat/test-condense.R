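# A compact hand-wired network for condensation: 40 reactions, pathway pw1
# holding R01..R08 and pw2 holding R09..R40. Metabolite metX regulates the
# first n_pw1 reactions of pw1 and the first n_pw2 of pw2; TF tfX drives
# responsive enzyme genes covering tf_reactions = c(in pw1, in pw2).
condense_fixture <- function(n_pw1 = 6, n_pw2 = 2, tf_reactions = c(4, 2)) {
  n_rx <- 40
  rx <- sprintf("R%02d", 1:n_rx)
  er <- data.frame(gene_id = sprintf("e%02d", 1:n_rx), reaction_id = rx)
  rpw <- data.frame(reaction_id = rx,
                    pathway_id = c(rep("pw1", 8), rep("pw2", 32)))
  met_rx <- c(rx[seq_len(n_pw1)], rx[8 + seq_len(n_pw2)])
  kb <- knowledge_base(
    enzyme_reactions = er,
    reaction_metabolites = data.frame(
      reaction_id = met_rx, metabolite_id = rep("metX", length(met_rx)),
      role = "substrate"),
    allosteric = data.frame(metabolite_id = character(0),
                            reaction_id = character(0), mode = character(0)),
    motif_targets = data.frame(tf_id = "tfX", gene_id = "e01"),
    background_genes = c(er$gene_id, "tfX"),
    kinase_targets = data.frame(signal_id = character(0),
                                target_id = character(0),
                                target_type = character(0)),
    tf_mode = data.frame(tf_id = "tfX", mode = "activator"),
    reaction_pathways = rpw,
    pathway_class = data.frame(pathway_id = c("pw1", "pw2"),
                               class = c("carbohydrate", "lipid")))
  tf_enz <- c(sprintf("e%02d", seq_len(tf_reactions[1])),
              sprintf("e%02d", 8 + seq_len(tf_reactions[2])))
  cms <- list(
    metabolite = cm_row("metX", "WT_specific", dwt = "decrease", swt = "rapid"),
    gene = rbind(cm_row("tfX", "WT_specific", dwt = "increase", swt = "rapid"),
                 do.call(rbind, lapply(tf_enz, function(e)
                   cm_row(e, "WT_specific", dwt = "increase", swt = "rapid")))),
    phospho = NULL)
  net <- suppressMessages(assemble_network(
    cms, kb, data.frame(tf_id = "tfX", gene_id = tf_enz)))
  list(net = net, kb = kb)
}

test_that("pathway association tests match the hypergeometric oracle", {
  fx <- condense_fixture(n_pw1 = 6, n_pw2 = 0)
  assoc <- pathway_association_tests(fx$net, fx$kb, "WT")
  met_pw1 <- assoc[assoc$regulator == "metX" & assoc$pathway_id == "pw1", ]
  # universe 40 reactions, pathway 8, metX regulates 6, all inside pw1
  expect_equal(met_pw1$overlap, 6L)
  expect_equal(met_pw1$p, hyper_tail_oracle(6, 6, 8, 40), tolerance = 1e-14)
  expect_true(met_pw1$significant)
  # no OB activity -> no regulators tested
  expect_equal(nrow(pathway_association_tests(fx$net, fx$kb, "OB")), 0L)
})

test_that("the significant q <= 0.01 set agrees with an independent BH pass", {
  fx <- condense_fixture()
  assoc <- pathway_association_tests(fx$net, fx$kb, "WT")
  expect_equal(assoc$q, bh_oracle(assoc$p), tolerance = 1e-12)
  expect_equal(assoc$significant, bh_oracle(assoc$p) <= 0.01)
})

test_that("pathway selection unions association and top-coverage rules", {
  fx <- condense_fixture(n_pw1 = 6, n_pw2 = 2)
  cfg <- pipeline_config()
  assoc <- pathway_association_tests(fx$net, fx$kb, "WT", cfg)
  cov <- pathway_coverage(fx$net, fx$kb, "WT")
  expect_equal(cov$n_total, c(8, 32))
  expect_equal(cov$frac_by_metabolites, c(6 / 8, 2 / 32))
  expect_equal(cov$frac_by_genes, c(4 / 8, 2 / 32))
  sel <- select_pathway_nodes(assoc, cov, cfg)
  # pw1 qualifies by association and tops both coverage rankings
  expect_true("pw1" %in% sel$pathway_id)
  expect_match(sel$selected_by[sel$pathway_id == "pw1"], "association")
  # enlarging the fraction never drops a selected pathway
  sel_all <- select_pathway_nodes(assoc, cov,
                                  pipeline_config(top_fraction_pathways = 1))
  expect_true(all(sel$pathway_id %in% sel_all$pathway_id))
  expect_setequal(sel_all$pathway_id, c("pw1", "pw2"))
})

test_that("metabolite-pathway edges respect the >= 5 reaction boundary", {
  keeps <- function(n_pw1) {
    fx <- condense_fixture(n_pw1 = n_pw1, n_pw2 = 0)
    cn <- condense_network(fx$net, fx$kb, "WT")
    cn$edges[cn$edges$regulator == "metX" & cn$edges$pathway_id == "pw1", ]
  }
  e5 <- keeps(5)
  expect_equal(nrow(e5), 1L)        # weight exactly 5 survives
  expect_equal(e5$weight, 5L)
  expect_equal(nrow(keeps(4)), 0L)  # fewer than five removed
})

test_that("metabolites without a significant pathway association are dropped", {
  # metX spread thin: 2 reactions in pw1, 3 in pw2 -> proportional, n.s.
  fx <- condense_fixture(n_pw1 = 2, n_pw2 = 3, tf_reactions = c(4, 2))
  cn <- condense_network(fx$net, fx$kb, "WT",
                         pipeline_config(top_fraction_pathways = 1))
  expect_false("metX" %in% cn$regulators$regulator)
})

test_that("TF inclusion counts total reactions, with edges unfiltered", {
  fx <- condense_fixture(n_pw1 = 6, n_pw2 = 2, tf_reactions = c(4, 2))
  cfg <- pipeline_config(top_fraction_pathways = 1)  # both pathways selected
  cn <- condense_network(fx$net, fx$kb, "WT", cfg)
  # tfX regulates 6 reactions total (4 in pw1 + 2 in pw2) -> node kept
  expect_true("tfX" %in% cn$regulators$regulator)
  tfe <- cn$edges[cn$edges$regulator == "tfX", ]
  # both pathway edges retained despite weights 4 and 2 < 5
  expect_equal(tfe$weight[order(tfe$pathway_id)], c(4L, 2L))
  # under the enzymes criterion the same TF counts 6 enzymes -> still kept
  cn2 <- condense_network(fx$net, fx$kb, "WT",
                          pipeline_config(top_fraction_pathways = 1,
                                          tf_condense_criterion = "enzymes"))
  expect_true("tfX" %in% cn2$regulators$regulator)
  # a TF regulating only 4 reactions is dropped
  fx4 <- condense_fixture(n_pw1 = 6, n_pw2 = 2, tf_reactions = c(4, 0))
  cn4 <- condense_network(fx4$net, fx4$kb, "WT", cfg)
  expect_false("tfX" %in% cn4$regulators$regulator)
})

test_that("pathway grouping conserves regulated-reaction counts before filtering", {
  b <- generate_study_bundle(seed = 9, n_genes = 400, planted_cluster_size = 60,
                             n_reactions = 80, n_pathways = 8)
  cm <- truth_to_calls(b$truth)
  net <- suppressMessages(assemble_network(cm, b$kb, b$planted_tf_edges))
  pw <- b$kb$reaction_pathways
  for (g in c("WT", "OB")) {
    sets <- transomix:::regulator_reaction_sets(net, g)
    for (m in names(sets$metabolites)) {
      R <- sets$metabolites[[m]]
      w_sum <- sum(vapply(unique(pw$pathway_id), function(p)
        length(intersect(R, unique(pw$reaction_id[pw$pathway_id == p]))), 0L))
      # multi-membership: each pathway-annotated reaction counts once per
      # pathway it belongs to
      expect_equal(w_sum, sum(vapply(intersect(R, unique(pw$reaction_id)),
                                     function(r) length(unique(
                                       pw$pathway_id[pw$reaction_id == r])), 0L)))
    }
  }
})
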
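test_that("edge signs follow direction concordance and flip symmetry", {
  expect_equal(edge_sign("increase", "increase"), "positive")
  expect_equal(edge_sign("decrease", "decrease"), "positive")
  expect_equal(edge_sign("increase", "decrease"), "negative")
  expect_equal(edge_sign("decrease", "increase"), "negative")
  flip <- function(d) if (d == "increase") "decrease" else "increase"
  for (a in c("increase", "decrease")) for (b in c("increase", "decrease"))
    expect_equal(edge_sign(a, b), edge_sign(flip(a), flip(b)))
  expect_error(edge_sign("none", "increase"), "directions")
})

test_that("layer assignment partitions molecules by knowledge-base role", {
  kb <- tiny_kb()
  cms <- list(
    metabolite = rbind(cm_row("mA", "WT_specific", dwt = "decrease", swt = "rapid"),
                       cm_row("mZ", "none")),
    gene = rbind(cm_row("e1", "common", dwt = "increase", dob = "increase"),
                 cm_row("tf1", "WT_specific", dwt = "increase"),
                 cm_row("g9", "OB_specific", dob = "decrease")),
    phospho = rbind(cm_row("s1", "common", dwt = "increase", dob = "increase"),
                    cm_row("e2", "OB_specific", dob = "increase")))
  nodes <- suppressMessages(assign_layer_nodes(cms, kb))
  lay <- function(id) nodes$layer[nodes$id == id]
  expect_equal(lay("mA"), "Metabolite")
  expect_equal(lay("e1"), "Enzyme")          # enzyme role, not TF
  expect_equal(lay("tf1"), "TF")
  expect_equal(lay("s1"), "InsulinSignal")
  expect_equal(lay("e2"), "Enzyme")          # phospho route into Enzyme
  expect_equal(nodes$basis[nodes$id == "e2"], "phospho")
  expect_false("mZ" %in% nodes$id)           # non-responsive -> no node
  expect_false("g9" %in% nodes$id)           # no role -> no node
  # overlapping roles are an error
  kb_bad <- tiny_kb()
  kb_bad$tf_mode <- rbind(kb_bad$tf_mode, data.frame(tf_id = "e1", mode = "unknown"))
  expect_error(suppressMessages(assign_layer_nodes(cms, kb_bad)), "two layers")
})

test_that("reaction nodes exist only when a responsive regulator feeds them", {
  kb <- tiny_kb()
  cms <- list(
    metabolite = rbind(cm_row("mC", "WT_specific", dwt = "decrease")),
    gene = rbind(cm_row("e1", "common", dwt = "increase", dob = "increase")),
    phospho = NULL)
  nodes <- suppressMessages(assign_layer_nodes(cms, kb))
  rx <- derive_reaction_nodes(nodes, kb)
  # e1 -> R1 (enzyme route); mC is product of R3 -> substrate_or_product edge
  expect_setequal(rx$reaction_ids, c("R1", "R3"))
  expect_false("R2" %in% rx$reaction_ids)    # only non-responsive regulators
  e_r3 <- rx$edges[rx$edges$target == "R3", ]
  expect_equal(e_r3$regulation_type, "substrate_or_product")
  expect_equal(e_r3$genotype_class, "WT_specific")
  e_r1 <- rx$edges[rx$edges$target == "R1", ]
  expect_equal(e_r1$regulation_type, "enzyme_to_reaction")
})

test_that("allosteric and substrate roles of one metabolite give two edges", {
  kb <- tiny_kb()
  # make mA also substrate of R2 (it is already allosteric inhibitor of R2)
  kb$reaction_metabolites <- rbind(kb$reaction_metabolites,
                                   data.frame(reaction_id = "R2",
                                              metabolite_id = "mA",
                                              role = "substrate"))
  cms <- list(metabolite = rbind(cm_row("mA", "WT_specific", dwt = "decrease")),
              gene = cm_row("zz", "none"), phospho = NULL)
  nodes <- suppressMessages(assign_layer_nodes(cms, kb))
  rx <- derive_reaction_nodes(nodes, kb)
  types <- rx$edges$regulation_type[rx$edges$target == "R2"]
  expect_setequal(types, c("allosteric_inhibitor", "substrate_or_product"))
})

test_that("signed edges exist per genotype with conjunction classes", {
  kb <- tiny_kb()
  cms <- list(
    metabolite = cm_row("none0", "none"),
    gene = rbind(cm_row("tf1", "common", dwt = "increase", dob = "increase"),
                 cm_row("e1", "opposite", dwt = "increase", dob = "decrease"),
                 cm_row("e2", "WT_specific", dwt = "increase")),
    phospho = NULL)
  nodes <- suppressMessages(assign_layer_nodes(cms, kb))
  tf_edges <- data.frame(tf_id = "tf1", gene_id = c("e1", "e2"))
  edges <- build_interlayer_edges(nodes, kb, tf_edges, cms$gene)
  e1 <- edges[edges$target == "e1", ]
  expect_equal(e1$sign_WT, "positive")
  expect_equal(e1$sign_OB, "negative")
  expect_equal(e1$genotype_class, "opposite")
  expect_equal(e1$sign, "not_applicable")
  e2 <- edges[edges$target == "e2", ]
  expect_equal(e2$genotype_class, "WT_specific")
  expect_equal(e2$sign, "positive")
  expect_false(e2$in_OB)
})

test_that("edges require both endpoints responsive in the genotype", {
  kb <- tiny_kb()
  cms <- list(
    metabolite = cm_row("none0", "none"),
    gene = rbind(cm_row("tf1", "WT_specific", dwt = "increase"),
                 cm_row("e1", "OB_specific", dob = "increase")),
    phospho = NULL)
  nodes <- suppressMessages(assign_layer_nodes(cms, kb))
  edges <- build_interlayer_edges(nodes, kb,
                                  data.frame(tf_id = "tf1", gene_id = "e1"),
                                  cms$gene)
  expect_equal(nrow(edges), 0L)  # disjoint genotypes -> no edge
})

test_that("assembled networks validate and summarise Fig-5-style counts", {
  kb <- tiny_kb()
  cms <- list(
    metabolite = rbind(cm_row("mA", "WT_specific", dwt = "decrease", swt = "rapid"),
                       cm_row("mC", "WT_specific", dwt = "decrease", swt = "rapid")),
    gene = rbind(cm_row("tf1", "WT_specific", dwt = "increase", swt = "rapid"),
                 cm_row("e1", "WT_specific", dwt = "increase", swt = "slow"),
                 cm_row("e2", "WT_specific", dwt = "increase", swt = "rapid")),
    phospho = rbind(cm_row("s1", "WT_specific", dwt = "increase", swt = "rapid")))
  net <- suppressMessages(assemble_network(
    cms, kb, data.frame(tf_id = "tf1", gene_id = c("e1", "e2"))))
  expect_true(validate_network(net))
  # R1: e1 (enzyme) + mA/mB substrate-product (mA responsive) -> both
  # R2: e2 enzyme + mA allosteric -> both; R3: e2 enzyme + mC product -> both
  summ <- regulation_summary(net)
  wt <- summ$by_source[summ$by_source$genotype == "WT", ]
  expect_equal(wt$n_reactions, 3)
  expect_equal(wt$enzyme_only + wt$metabolite_only + wt$both, wt$n_reactions)
  expect_equal(wt$both, 3)
  ob <- summ$by_source[summ$by_source$genotype == "OB", ]
  expect_equal(ob$n_reactions, 0)
  # all regulators rapid except e1 -> rapid bin covers all three reactions
  spd <- summ$by_speed
  expect_equal(spd$n_reactions[spd$genotype == "WT" & spd$speed == "rapid"], 3)
  expect_equal(spd$n_reactions[spd$genotype == "WT" & spd$speed == "slow"], 1)
})

test_that("top-regulator listing is strict about the display threshold", {
  edges <- do.call(rbind, c(
    lapply(1:16, function(i) data.frame(
      source = "metBig", target = paste0("R", i), source_layer = "Metabolite",
      target_layer = "Reaction", regulation_type = "substrate_or_product",
      sign_WT = NA, sign_OB = NA, sign = "not_applicable",
      genotype_class = "WT_specific", in_WT = TRUE, in_OB = FALSE,
      repressor = NA, stringsAsFactors = FALSE)),
    lapply(1:15, function(i) data.frame(
      source = "metSmall", target = paste0("R", i), source_layer = "Metabolite",
      target_layer = "Reaction", regulation_type = "substrate_or_product",
      sign_WT = NA, sign_OB = NA, sign = "not_applicable",
      genotype_class = "WT_specific", in_WT = TRUE, in_OB = FALSE,
      repressor = NA, stringsAsFactors = FALSE))))
  nodes <- do.call(rbind, c(
    list(data.frame(id = c("metBig", "metSmall"), layer = "Metabolite",
                    response_class = "WT_specific", direction_WT = "decrease",
                    direction_OB = "none", t_half_WT = 5, t_half_OB = NA,
                    speed_WT = "rapid", speed_OB = "undefined",
                    responsive_WT = TRUE, responsive_OB = FALSE,
                    basis = "metabolite", phospho_responsive = FALSE,
                    stringsAsFactors = FALSE)),
    lapply(1:16, function(i) data.frame(
      id = paste0("R", i), layer = "Reaction", response_class = "none",
      direction_WT = "none", direction_OB = "none", t_half_WT = NA,
      t_half_OB = NA, speed_WT = "undefined", speed_OB = "undefined",
      responsive_WT = NA, responsive_OB = NA, basis = "reaction",
      phospho_responsive = FALSE, stringsAsFactors = FALSE))))
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "transomic_network")
  top <- regulation_summary(net)$top_regulators
  expect_equal(top$regulator, "metBig")   # "more than 15" is strict
})

test_that("network validation catches layer and responsiveness violations", {
  kb <- tiny_kb()
  cms <- list(metabolite = cm_row("mA", "WT_specific", dwt = "decrease"),
              gene = cm_row("e1", "WT_specific", dwt = "increase"),
              phospho = NULL)
  net <- suppressMessages(assemble_network(cms, kb, NULL))
  bad <- net
  bad$edges$source_layer[1] <- "Reaction"
  expect_error(validate_network(bad), "disallowed")
  bad2 <- net
  bad2$edges$in_OB[1] <- TRUE   # regulator not responsive in OB
  expect_error(validate_network(bad2), "not responsive")
})

test_that("GML round trip preserves the attributed graph", {
  b <- generate_study_bundle(seed = 5, n_genes = 400, planted_cluster_size = 60,
                             n_reactions = 60)
  cm <- truth_to_calls(b$truth)
  net <- suppressMessages(assemble_network(cm, b$kb, b$planted_tf_edges))
  f <- withr::local_tempfile(fileext = ".gml")
  write_network_gml(net, f)
  net2 <- read_network_gml(f)
  drop_p <- function(df) df[setdiff(names(df), "phospho_responsive")]
  o <- function(df, keys) {
    df <- df[do.call(order, df[keys]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(o(drop_p(net$nodes), c("id", "layer")),
               o(drop_p(net2$nodes), c("id", "layer")))
  keys <- c("source", "target", "regulation_type")
  expect_equal(o(net$edges, keys), o(net2$edges, keys))
  # empty network still writes valid GML
  empty <- structure(list(nodes = net$nodes[0, ], edges = net$edges[0, ]),
                     class = "transomic_network")
  f2 <- withr::local_tempfile(fileext = ".gml")
  write_network_gml(empty, f2)
  expect_equal(nrow(read_network_gml(f2)$nodes), 0L)
})
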
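test_that("generation is deterministic and layer streams are independent", {
  a <- generate_timecourses(n_metabolites = 20, n_genes = 30, n_phospho = 5,
                            seed = 17)
  b <- generate_timecourses(n_metabolites = 20, n_genes = 30, n_phospho = 5,
                            seed = 17)
  expect_identical(a$timecourses$metabolite$values, b$timecourses$metabolite$values)
  expect_identical(a$timecourses$gene$values, b$timecourses$gene$values)
  expect_identical(a$truth, b$truth)
  c2 <- generate_timecourses(n_metabolites = 20, n_genes = 30, n_phospho = 5,
                             seed = 18)
  expect_false(identical(a$timecourses$metabolite$values,
                         c2$timecourses$metabolite$values))
  # the metabolite table does not depend on whether genes were generated
  m_only <- generate_timecourses(n_metabolites = 20, n_genes = 0, n_phospho = 0,
                                 seed = 17)
  expect_identical(m_only$timecourses$metabolite$values,
                   a$timecourses$metabolite$values)
})

test_that("the default bundle mirrors the study's composition", {
  b <- generate_study_bundle(seed = 4)
  expect_equal(length(tc_molecules(b$timecourses$metabolite)), 104L)
  expect_equal(length(tc_molecules(b$timecourses$phospho)), 10L)
  met <- b$truth[b$truth$layer == "metabolite", ]
  expect_equal(sum(met$pattern != "none"), 29L)
  expect_equal(sum(met$pattern == "WT_specific" & met$direction_WT == "decrease"), 21L)
  expect_equal(sum(met$pattern == "OB_specific" & met$direction_OB == "increase"), 4L)
  expect_equal(sum(met$pattern == "OB_specific" & met$direction_OB == "decrease"), 4L)
  expect_equal(sum(met$pattern %in% c("common", "opposite")), 0L)
  # planted clusters are disjoint and at least the configured size
  cl <- b$planted_tf_clusters
  expect_equal(lengths(cl), c(120L, 120L, 120L), ignore_attr = TRUE)
  expect_equal(length(unique(unlist(cl))), 360L)
  # planted amplitudes clear the fold-change threshold by construction
  resp <- b$truth[b$truth$pattern != "none", ]
  expect_true(all(abs(resp$amplitude_log2) >= 0.585 + 0.5))
  expect_s3_class(b$kb, "knowledge_base")
})

test_that("trajectories cross half amplitude exactly at the planted time", {
  dev <- function(t, A, th) A * (1 - 2^(-t / th))
  for (th in c(10, 40, 120)) {
    tt <- seq(0, 240, by = 0.1)
    d <- dev(tt, 1.5, th)
    crossing <- tt[which(d >= 0.75)[1]]
    expect_equal(crossing, th, tolerance = 0.2)
  }
})

test_that("planted half-times are recovered within 10 minutes", {
  # rapid responders with a known 10-min half-time, across many seeds
  hits <- 0L; total <- 0L
  for (seed in 1:25) {
    truth <- data.frame(molecule_id = sprintf("m%02d", 1:20), layer = "metabolite",
                        pattern = "common", direction_WT = "increase",
                        direction_OB = "increase", amplitude_log2 = 1.5,
                        t_half_true = 10, speed_true = "rapid",
                        stringsAsFactors = FALSE)
    sim <- generate_timecourses(n_metabolites = 20, n_genes = 0, n_phospho = 0,
                                seed = seed, planted = list(metabolite = truth))
    calls <- suppressMessages(responsiveness_calls(sim$timecourses$metabolite))
    est <- calls$t_half[calls$responsive]
    hits <- hits + sum(abs(est - 10) <= 10, na.rm = TRUE)
    total <- total + sum(!is.na(est))
  }
  expect_gt(total, 400)
  expect_gte(hits / total, 0.9)
})

test_that("a zero-responder generator stays below the fold threshold in expectation", {
  sim <- generate_timecourses(n_metabolites = 60, n_genes = 0, n_phospho = 0,
                              frac_responsive = c(metabolite = 0), seed = 31)
  fc <- log2_fold_changes(sim$timecourses$metabolite)
  # mean |log2FC| of null molecules is far below 0.585 (noise CV 0.2, n = 5)
  expect_lt(mean(abs(fc$log2fc), na.rm = TRUE), 0.3)
  expect_equal(sum(sim$truth$pattern != "none"), 0L)
})

test_that("assembling from truth labels reproduces the planted network exactly", {
  for (seed in c(2, 8)) {
    b <- generate_study_bundle(seed = seed, n_genes = 450,
                               planted_cluster_size = 70, n_reactions = 90)
    cm <- truth_to_calls(b$truth)
    net <- suppressMessages(assemble_network(cm, b$kb, b$planted_tf_edges))
    ep <- edge_set_precision(net$edges, b$planted_network)
    expect_equal(ep$precision, 1)
    expect_equal(ep$recall, 1)
    # attributes agree too
    a <- net$edges; p <- b$planted_network
    a$k <- paste(a$source, a$target, a$regulation_type)
    p$k <- paste(p$source, p$target, p$regulation_type)
    m <- merge(a, p, by = "k")
    expect_equal(nrow(m), nrow(p))
    expect_equal(m$in_WT.x, m$in_WT.y)
    expect_equal(m$in_OB.x, m$in_OB.y)
    expect_equal(m$sign_WT.x, m$sign_WT.y)
    expect_equal(m$sign_OB.x, m$sign_OB.y)
  }
})

test_that("bundle truth wires detectable motif enrichment at planted nodes", {
  b <- generate_study_bundle(seed = 12)
  mt <- b$kb$motif_targets
  for (tf in names(b$planted_tf_clusters)) {
    cl <- b$planted_tf_clusters[[tf]]
    hits_in <- sum(mt$gene_id[mt$tf_id == tf] %in% cl)
    rate_in <- hits_in / length(cl)
    bg <- setdiff(b$kb$background_genes, cl)
    rate_out <- sum(mt$gene_id[mt$tf_id == tf] %in% bg) / length(bg)
    expect_gt(rate_in, 0.25)
    expect_lt(rate_out, 0.12)
  }
})
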
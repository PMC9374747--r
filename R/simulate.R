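# Synthetic multi-omic study generator with planted ground truth.
#
# The generator emulates the statistical shape of the study: 5 sampling
# times (0/20/60/120/240 min), n = 5 replicates per genotype and time, two
# genotypes (WT, OB), ~104 metabolites, 10 phosphoproteins and a
# configurable number of genes. Planted responders follow a saturating
# exponential deviation on the log2 scale, d(t) = A * (1 - 2^(-t/t_half)),
# so the half-amplitude time of the log2 trace equals t_half by
# construction. Metabolite and phosphorylation noise is lognormal with a
# given CV; gene counts are negative binomial with a given dispersion.

# independent, reproducible sub-stream per table derived from one seed
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h * 31) %% 2147483647)
}

T_HALF_BANDS <- list(rapid = c(5, 15), intermediate = c(30, 50),
                     slow = c(90, 200))

random_truth <- function(ids, layer, frac_responsive,
                         pattern_weights = c(WT_specific = 0.3, OB_specific = 0.3,
                                             common = 0.3, opposite = 0.1),
                         amplitude_log2 = 1.5) {
  n <- length(ids)
  truth <- data.frame(molecule_id = ids, layer = layer, pattern = "none",
                      direction_WT = "none", direction_OB = "none",
                      amplitude_log2 = 0, t_half_true = NA_real_,
                      speed_true = "undefined", stringsAsFactors = FALSE)
  n_resp <- round(frac_responsive * n)
  if (n_resp == 0L) return(truth)
  idx <- sample.int(n, n_resp)
  pat <- sample(names(pattern_weights), n_resp, replace = TRUE,
                prob = pattern_weights)
  base_dir <- sample(c("increase", "decrease"), n_resp, replace = TRUE)
  cls <- sample(names(T_HALF_BANDS), n_resp, replace = TRUE)
  th <- vapply(cls, function(cl)
    stats::runif(1, T_HALF_BANDS[[cl]][1], T_HALF_BANDS[[cl]][2]), 0)
  truth$pattern[idx] <- pat
  truth$amplitude_log2[idx] <- amplitude_log2
  truth$t_half_true[idx] <- th
  truth$speed_true[idx] <- cls
  flip <- c(increase = "decrease", decrease = "increase")
  truth$direction_WT[idx] <- ifelse(pat %in% c("WT_specific", "common", "opposite"),
                                    base_dir, "none")
  truth$direction_OB[idx] <- ifelse(pat == "OB_specific", base_dir,
                                    ifelse(pat == "common", base_dir,
                                           ifelse(pat == "opposite",
                                                  flip[base_dir], "none")))
  truth
}

log2_deviation <- function(direction, amplitude, t_half, times) {
  if (direction == "none" || is.na(t_half)) return(rep(0, length(times)))
  s <- if (direction == "increase") 1 else -1
  s * amplitude * (1 - 2^(-times / t_half))
}

simulate_abundance_layer <- function(truth, times, n_rep, cv, missing_rate,
                                     baseline_meanlog = log(100),
                                     baseline_sdlog = 0.6) {
  ids <- truth$molecule_id
  sdlog <- sqrt(log(1 + cv^2))
  baseline <- stats::rlnorm(length(ids), baseline_meanlog, baseline_sdlog)
  vals <- array(NA_real_, dim = c(length(ids), 2, length(times), n_rep),
                dimnames = list(ids, c("WT", "OB"), as.character(times), NULL))
  for (i in seq_along(ids)) {
    for (g in c("WT", "OB")) {
      dev <- log2_deviation(truth[[paste0("direction_", g)]][i],
                            truth$amplitude_log2[i], truth$t_half_true[i], times)
      mu <- baseline[i] * 2^dev
      vals[i, g, , ] <- mu * stats::rlnorm(length(times) * n_rep, 0, sdlog)
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(vals)) < missing_rate
    vals[drop] <- NA_real_
  }
  vals
}

simulate_count_layer <- function(truth, times, n_rep, nb_dispersion,
                                 baseline_meanlog = log(300),
                                 baseline_sdlog = 0.7) {
  ids <- truth$molecule_id
  baseline <- stats::rlnorm(length(ids), baseline_meanlog, baseline_sdlog)
  vals <- array(NA_real_, dim = c(length(ids), 2, length(times), n_rep),
                dimnames = list(ids, c("WT", "OB"), as.character(times), NULL))
  for (i in seq_along(ids)) {
    for (g in c("WT", "OB")) {
      dev <- log2_deviation(truth[[paste0("direction_", g)]][i],
                            truth$amplitude_log2[i], truth$t_half_true[i], times)
      mu <- baseline[i] * 2^dev
      vals[i, g, , ] <- stats::rnbinom(length(times) * n_rep,
                                       mu = rep(mu, n_rep),
                                       size = 1 / nb_dispersion)
    }
  }
  vals
}

#' Generate synthetic omic time courses with planted responders
#'
#' Draws one \code{omics_timecourse} per layer under the study's sampling
#' design (5 times including the 0-min baseline, n = 5 replicates per
#' genotype and time) with planted glucose responders of known pattern,
#' direction, amplitude and half-time.
#'
#' @param n_metabolites,n_genes,n_phospho molecules per layer (a layer with
#'   0 molecules is omitted).
#' @param frac_responsive named fractions of planted responders per layer.
#' @param amplitude_log2 planted absolute log2 amplitude.
#' @param cv lognormal coefficient of variation for abundance layers.
#' @param nb_dispersion negative-binomial dispersion for gene counts.
#' @param missing_rate missing-completely-at-random cell rate (abundance
#'   layers).
#' @param times sampling minutes (must start at 0).
#' @param n_replicates replicates per genotype and time.
#' @param seed integer seed; each layer derives its own sub-stream so
#'   single tables can be regenerated in isolation.
#' @param planted optional named list of per-layer truth data frames (as
#'   returned in \code{$truth}) overriding random planting.
#' @return list(timecourses = list per layer, truth = combined truth
#'   data.frame).
#' @export
generate_timecourses <- function(n_metabolites = 104, n_genes = 1000,
                                 n_phospho = 10,
                                 frac_responsive = c(metabolite = 0.28,
                                                     gene = 0.25, phospho = 0.6),
                                 amplitude_log2 = 1.5, cv = 0.2,
                                 nb_dispersion = 0.04, missing_rate = 0.02,
                                 times = c(0, 20, 60, 120, 240),
                                 n_replicates = 5, seed = 1L,
                                 planted = NULL) {
  stopifnot(times[1] == 0, all(frac_responsive >= 0 & frac_responsive <= 1),
            cv > 0, nb_dispersion > 0)
  counts <- c(metabolite = n_metabolites, gene = n_genes, phospho = n_phospho)
  prefixes <- c(metabolite = "met", gene = "g", phospho = "p")
  tcs <- list(); truths <- list()
  for (layer in names(counts)) {
    if (counts[[layer]] == 0L) next
    set.seed(sub_seed(seed, paste0("truth_", layer)))
    tr <- if (!is.null(planted[[layer]])) planted[[layer]]
    else random_truth(sprintf("%s%04d", prefixes[[layer]], seq_len(counts[[layer]])),
                      layer, frac_responsive[[layer]],
                      amplitude_log2 = amplitude_log2)
    tr$layer <- layer
    set.seed(sub_seed(seed, paste0("values_", layer)))
    vals <- if (layer == "gene")
      simulate_count_layer(tr, times, n_replicates, nb_dispersion)
    else
      simulate_abundance_layer(tr, times, n_replicates, cv, missing_rate)
    tcs[[layer]] <- omics_timecourse(vals, layer)
    truths[[layer]] <- tr
  }
  list(timecourses = tcs,
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))))
}

#' Generate a synthetic regulatory knowledge base
#'
#' Random but referentially intact wiring emulating the shapes of the
#' pathway-database tables: every reaction has at least one enzyme gene,
#' substrates/products and pathway memberships (with overlap), allosteric
#' effectors at a given density, motif targets with optional planted
#' enriched clusters, kinase targets, TF modes and pathway classes.
#'
#' @param gene_ids,metabolite_ids identifier pools.
#' @param enzyme_gene_ids genes acting as metabolic enzymes (disjoint from
#'   \code{tf_ids}).
#' @param tf_ids transcription-factor identifiers.
#' @param signal_ids insulin-signaling molecule identifiers.
#' @param n_reactions,n_pathways sizes of the reaction and pathway sets.
#' @param allosteric_density probability a reaction has an allosteric
#'   effector.
#' @param planted_tf_clusters named list tf_id -> gene vector to enrich.
#' @param motif_in_rate,motif_bg_rate motif frequencies inside planted
#'   clusters and in the background.
#' @param seed integer seed.
#' @return a validated \code{knowledge_base}.
#' @export
generate_knowledgebase <- function(gene_ids, metabolite_ids, enzyme_gene_ids,
                                   tf_ids, signal_ids,
                                   n_reactions = 150, n_pathways = 12,
                                   allosteric_density = 0.4,
                                   planted_tf_clusters = NULL,
                                   motif_in_rate = 0.4, motif_bg_rate = 0.05,
                                   seed = 1L) {
  stopifnot(allosteric_density >= 0, allosteric_density <= 1,
            length(intersect(tf_ids, enzyme_gene_ids)) == 0)
  set.seed(sub_seed(seed, "knowledgebase"))
  rx <- sprintf("R%04d", seq_len(n_reactions))
  pw <- sprintf("pw%02d", seq_len(n_pathways))
  # every reaction gets one enzyme; enzymes may cover several reactions
  er <- data.frame(gene_id = sample(enzyme_gene_ids, n_reactions, replace = TRUE),
                   reaction_id = rx, stringsAsFactors = FALSE)
  extra <- stats::runif(n_reactions) < 0.3
  if (any(extra))
    er <- rbind(er, data.frame(
      gene_id = sample(enzyme_gene_ids, sum(extra), replace = TRUE),
      reaction_id = rx[extra], stringsAsFactors = FALSE))
  rmet <- do.call(rbind, lapply(rx, function(r) {
    subs <- sample(metabolite_ids, sample(1:2, 1))
    prods <- sample(setdiff(metabolite_ids, subs), sample(1:2, 1))
    rbind(data.frame(reaction_id = r, metabolite_id = subs, role = "substrate",
                     stringsAsFactors = FALSE),
          data.frame(reaction_id = r, metabolite_id = prods, role = "product",
                     stringsAsFactors = FALSE))
  }))
  allo_rx <- rx[stats::runif(n_reactions) < allosteric_density]
  allosteric <- if (length(allo_rx)) data.frame(
    metabolite_id = sample(metabolite_ids, length(allo_rx), replace = TRUE),
    reaction_id = allo_rx,
    mode = sample(c("activator", "inhibitor"), length(allo_rx), replace = TRUE),
    stringsAsFactors = FALSE)
  else data.frame(metabolite_id = character(0), reaction_id = character(0),
                  mode = character(0), stringsAsFactors = FALSE)
  rpw <- data.frame(reaction_id = rx,
                    pathway_id = sample(pw, n_reactions, replace = TRUE),
                    stringsAsFactors = FALSE)
  second <- stats::runif(n_reactions) < 0.15
  if (any(second))
    rpw <- rbind(rpw, data.frame(
      reaction_id = rx[second],
      pathway_id = sample(pw, sum(second), replace = TRUE),
      stringsAsFactors = FALSE))
  pwc <- data.frame(pathway_id = pw,
                    class = sample(c("carbohydrate", "lipid", "amino_acid", "other"),
                                   n_pathways, replace = TRUE),
                    stringsAsFactors = FALSE)
  mt_rows <- lapply(tf_ids, function(tf) {
    inset <- planted_tf_clusters[[tf]]
    if (is.null(inset)) inset <- character(0)
    bg <- setdiff(gene_ids, inset)
    hits <- c(inset[stats::runif(length(inset)) < motif_in_rate],
              bg[stats::runif(length(bg)) < motif_bg_rate])
    if (length(hits) == 0L) return(NULL)
    data.frame(tf_id = tf, gene_id = hits, stringsAsFactors = FALSE)
  })
  motif <- do.call(rbind, mt_rows)
  if (is.null(motif))
    motif <- data.frame(tf_id = character(0), gene_id = character(0))
  kt <- do.call(rbind, lapply(signal_ids, function(s) rbind(
    data.frame(signal_id = s,
               target_id = sample(tf_ids, min(2, length(tf_ids))),
               target_type = "tf", stringsAsFactors = FALSE),
    data.frame(signal_id = s,
               target_id = sample(enzyme_gene_ids, min(3, length(enzyme_gene_ids))),
               target_type = "enzyme", stringsAsFactors = FALSE))))
  tfm <- data.frame(tf_id = tf_ids,
                    mode = sample(c("activator", "repressor", "unknown"),
                                  length(tf_ids), replace = TRUE),
                    stringsAsFactors = FALSE)
  knowledge_base(er, rmet, allosteric, motif, gene_ids, kt, tfm, rpw, pwc)
}

#' Response class maps implied by a planted truth table
#'
#' Converts the generator's truth into the per-layer class maps that the
#' assembler consumes ("perfect calls").
#' @param truth the \code{$truth} data.frame of a generated bundle.
#' @return named list of class-map data frames per layer.
#' @export
truth_to_calls <- function(truth) {
  out <- list()
  for (layer in unique(truth$layer)) {
    tr <- truth[truth$layer == layer, ]
    out[[layer]] <- data.frame(
      molecule_id = tr$molecule_id, class = tr$pattern,
      direction_WT = tr$direction_WT, direction_OB = tr$direction_OB,
      t_half_WT = ifelse(tr$direction_WT == "none", NA_real_, tr$t_half_true),
      t_half_OB = ifelse(tr$direction_OB == "none", NA_real_, tr$t_half_true),
      speed_WT = ifelse(tr$direction_WT == "none", "undefined", tr$speed_true),
      speed_OB = ifelse(tr$direction_OB == "none", "undefined", tr$speed_true),
      responsive_WT = tr$direction_WT != "none",
      responsive_OB = tr$direction_OB != "none",
      stringsAsFactors = FALSE)
  }
  out
}

# Planted network oracle: the exact edge set the assembler should output
# under perfect calls, derived by direct set logic over truth + KB tables
# (kept independent of assemble_network's construction path).
planted_network_edges <- function(truth, kb, tf_gene_edges) {
  cm <- truth_to_calls(truth)
  roles <- kb_roles(kb)
  look <- function(layer) {
    m <- cm[[layer]]
    if (is.null(m)) m <- data.frame(molecule_id = character(0))
    m
  }
  gene <- look("gene"); met <- look("metabolite"); pho <- look("phospho")
  resp <- function(map, ids, g) {
    i <- match(ids, map$molecule_id)
    out <- map[[paste0("responsive_", g)]][i]
    out[is.na(out)] <- FALSE
    out
  }
  dirn <- function(map, ids, g) map[[paste0("direction_", g)]][match(ids, map$molecule_id)]
  # node membership by role
  enz_gene <- gene$molecule_id[gene$class != "none" &
                                 gene$molecule_id %in% roles$enzyme_ids]
  enz_pho <- pho$molecule_id[pho$class != "none" &
                               pho$molecule_id %in% roles$enzyme_ids]
  enz_all <- union(enz_gene, enz_pho)
  tf_gene <- gene$molecule_id[gene$class != "none" &
                                gene$molecule_id %in% roles$tf_ids]
  tf_pho <- pho$molecule_id[pho$class != "none" &
                              pho$molecule_id %in% roles$tf_ids]
  tf_all <- union(tf_gene, tf_pho)
  sig_all <- pho$molecule_id[pho$class != "none" &
                               pho$molecule_id %in% roles$signal_ids]
  met_all <- met$molecule_id[met$class != "none"]
  # node-level responsiveness/direction: transcript basis wins
  node_resp <- function(ids, g) {
    g_r <- resp(gene, ids, g)
    p_r <- resp(pho, ids, g)
    from_gene <- ids %in% gene$molecule_id[gene$class != "none"]
    ifelse(from_gene, g_r, p_r)
  }
  node_dir <- function(ids, g) {
    from_gene <- ids %in% gene$molecule_id[gene$class != "none"]
    ifelse(from_gene, dirn(gene, ids, g), dirn(pho, ids, g))
  }
  ed <- list()
  mk <- function(src, tgt, type, sl, tl, iw, io, sw = NA_character_,
                 so = NA_character_) {
    keep <- iw | io
    if (!any(keep)) return(NULL)
    data.frame(source = src, target = tgt, source_layer = sl, target_layer = tl,
               regulation_type = type, in_WT = iw, in_OB = io,
               sign_WT = sw, sign_OB = so,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  er <- kb$enzyme_reactions[kb$enzyme_reactions$gene_id %in% enz_all, ]
  if (nrow(er))
    ed$er <- mk(er$gene_id, er$reaction_id, "enzyme_to_reaction",
                "Enzyme", "Reaction",
                node_resp(er$gene_id, "WT"), node_resp(er$gene_id, "OB"))
  al <- kb$allosteric[kb$allosteric$metabolite_id %in% met_all, ]
  if (nrow(al))
    ed$al <- mk(al$metabolite_id, al$reaction_id,
                ifelse(al$mode == "activator", "allosteric_activator",
                       "allosteric_inhibitor"), "Metabolite", "Reaction",
                resp(met, al$metabolite_id, "WT"), resp(met, al$metabolite_id, "OB"))
  sp <- unique(kb$reaction_metabolites[kb$reaction_metabolites$metabolite_id %in%
                                         met_all, c("reaction_id", "metabolite_id")])
  if (nrow(sp))
    ed$sp <- mk(sp$metabolite_id, sp$reaction_id, "substrate_or_product",
                "Metabolite", "Reaction",
                resp(met, sp$metabolite_id, "WT"), resp(met, sp$metabolite_id, "OB"))
  sgn <- function(a, b) ifelse(a == b, "positive", "negative")
  kt <- kb$kinase_targets[kb$kinase_targets$signal_id %in% sig_all, ]
  if (nrow(kt)) {
    tl <- ifelse(kt$target_type == "tf", "TF", "Enzyme")
    in_node <- ifelse(kt$target_type == "tf", kt$target_id %in% tf_all,
                      kt$target_id %in% enz_all)
    kt <- kt[in_node, ]; tl <- tl[in_node]
    if (nrow(kt)) {
      iw <- resp(pho, kt$signal_id, "WT") & node_resp(kt$target_id, "WT")
      io <- resp(pho, kt$signal_id, "OB") & node_resp(kt$target_id, "OB")
      ed$kt <- mk(kt$signal_id, kt$target_id,
                  ifelse(tl == "TF", "kinase_to_tf", "kinase_to_enzyme"),
                  "InsulinSignal", tl, iw, io,
                  ifelse(iw, sgn(dirn(pho, kt$signal_id, "WT"),
                                 node_dir(kt$target_id, "WT")), NA),
                  ifelse(io, sgn(dirn(pho, kt$signal_id, "OB"),
                                 node_dir(kt$target_id, "OB")), NA))
    }
  }
  te <- tf_gene_edges[tf_gene_edges$tf_id %in% tf_all &
                        tf_gene_edges$gene_id %in% enz_all, , drop = FALSE]
  if (nrow(te)) {
    iw <- node_resp(te$tf_id, "WT") & resp(gene, te$gene_id, "WT")
    io <- node_resp(te$tf_id, "OB") & resp(gene, te$gene_id, "OB")
    ed$te <- mk(te$tf_id, te$gene_id, "tf_to_enzyme_gene", "TF", "Enzyme",
                iw, io,
                ifelse(iw, sgn(node_dir(te$tf_id, "WT"), dirn(gene, te$gene_id, "WT")), NA),
                ifelse(io, sgn(node_dir(te$tf_id, "OB"), dirn(gene, te$gene_id, "OB")), NA))
  }
  edges <- do.call(rbind, c(ed, list(make.row.names = FALSE)))
  unique(edges)
}

#' Generate a coherent synthetic study bundle with planted truth
#'
#' One call yields the three omic time-course tables, a matching knowledge
#' base, the planted truth, the planted TF-to-gene regulatory edges, and
#' the planted network edge set the assembler should reproduce under
#' perfect calls. The default composition mirrors the study's shape: 104
#' metabolites of which 29 respond (21 decreasing only in WT, 4 increasing
#' and 4 decreasing only in OB, none in common), 10 phosphoproteins with
#' mixed response classes including opposite responses, and a gene layer
#' containing three planted ~120-gene co-regulated clusters driven by
#' planted transcription factors (motif frequency 0.4 inside the cluster
#' versus 0.05 in the background).
#'
#' @param seed integer seed.
#' @param n_genes total genes (must exceed 3 * planted_cluster_size).
#' @param n_metabolites metabolites (default 104).
#' @param planted_cluster_size genes per planted TF cluster.
#' @param n_reactions,n_pathways knowledge-base sizes.
#' @param frac_other_gene_responders fraction of non-cluster genes planted
#'   as responders with random patterns.
#' @param cv,nb_dispersion,missing_rate noise settings (see
#'   \code{\link{generate_timecourses}}).
#' @param amplitude_log2 planted absolute log2 amplitude.
#' @return list(timecourses, kb, truth, planted_tf_clusters,
#'   planted_tf_edges, planted_network, config-like parameters).
#' @export
generate_study_bundle <- function(seed = 1L, n_genes = 700, n_metabolites = 104,
                                  planted_cluster_size = 120,
                                  n_reactions = 150, n_pathways = 12,
                                  frac_other_gene_responders = 0.15,
                                  cv = 0.2, nb_dispersion = 0.04,
                                  missing_rate = 0.02, amplitude_log2 = 1.5) {
  stopifnot(n_genes > 3 * planted_cluster_size + 20)
  times <- c(0, 20, 60, 120, 240)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  met_ids <- sprintf("met%03d", seq_len(n_metabolites))
  set.seed(sub_seed(seed, "design"))
  tf_ids <- c("tfA", "tfB", "tfC", sprintf("tfD%02d", 1:7))
  # TF genes are genes too: reserve the last 10 gene ids for them
  tf_gene_ids <- utils::tail(gene_ids, 10)
  names(tf_gene_ids) <- tf_ids
  plain_genes <- utils::head(gene_ids, n_genes - 10)
  cluster_genes <- split(plain_genes[seq_len(3 * planted_cluster_size)],
                         rep(1:3, each = planted_cluster_size))
  planted_clusters <- stats::setNames(cluster_genes, c("tfA", "tfB", "tfC"))
  planted_clusters <- lapply(planted_clusters, function(g)
    stats::setNames(g, NULL))
  rest <- plain_genes[-seq_len(3 * planted_cluster_size)]

  gene_truth <- data.frame(molecule_id = gene_ids, layer = "gene",
                           pattern = "none", direction_WT = "none",
                           direction_OB = "none", amplitude_log2 = 0,
                           t_half_true = NA_real_, speed_true = "undefined",
                           stringsAsFactors = FALSE)
  set_truth <- function(truth, ids, pattern, dir_wt, dir_ob, band) {
    i <- match(ids, truth$molecule_id)
    truth$pattern[i] <- pattern
    truth$direction_WT[i] <- dir_wt
    truth$direction_OB[i] <- dir_ob
    truth$amplitude_log2[i] <- amplitude_log2
    truth$t_half_true[i] <- stats::runif(length(i), T_HALF_BANDS[[band]][1],
                                         T_HALF_BANDS[[band]][2])
    truth$speed_true[i] <- band
    truth
  }
  # planted co-regulated clusters with distinct temporal fingerprints
  gene_truth <- set_truth(gene_truth, planted_clusters$tfA, "common",
                          "increase", "increase", "rapid")
  gene_truth <- set_truth(gene_truth, planted_clusters$tfB, "WT_specific",
                          "increase", "none", "intermediate")
  gene_truth <- set_truth(gene_truth, planted_clusters$tfC, "OB_specific",
                          "none", "decrease", "slow")
  # planted TFs respond in the genotypes their clusters respond in
  gene_truth <- set_truth(gene_truth, tf_gene_ids["tfA"], "common",
                          "increase", "increase", "rapid")
  gene_truth <- set_truth(gene_truth, tf_gene_ids["tfB"], "WT_specific",
                          "increase", "none", "rapid")
  gene_truth <- set_truth(gene_truth, tf_gene_ids["tfC"], "OB_specific",
                          "none", "decrease", "rapid")
  n_other <- round(frac_other_gene_responders * length(rest))
  if (n_other > 0) {
    other <- sample(rest, n_other)
    ot <- random_truth(other, "gene", 1, amplitude_log2 = amplitude_log2)
    gene_truth[match(other, gene_truth$molecule_id), names(ot)] <- ot
  }

  # metabolite composition mirrors the observed class counts
  met_truth <- data.frame(molecule_id = met_ids, layer = "metabolite",
                          pattern = "none", direction_WT = "none",
                          direction_OB = "none", amplitude_log2 = 0,
                          t_half_true = NA_real_, speed_true = "undefined",
                          stringsAsFactors = FALSE)
  resp_ids <- sample(met_ids, 29)
  bands <- sample(c("rapid", "intermediate", "slow"), 29, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  grp <- rep(c("wt_dec", "ob_inc", "ob_dec"), c(21, 4, 4))
  for (k in seq_along(resp_ids)) {
    args <- switch(grp[k],
                   wt_dec = list("WT_specific", "decrease", "none"),
                   ob_inc = list("OB_specific", "none", "increase"),
                   ob_dec = list("OB_specific", "none", "decrease"))
    met_truth <- set_truth(met_truth, resp_ids[k], args[[1]], args[[2]],
                           args[[3]], bands[k])
  }

  # phospho layer: 4 signaling molecules, 3 TF proteins, 3 enzyme proteins
  signal_ids <- c("sigA", "sigB", "sigC", "sigD")
  # enzymes: majority of each planted cluster plus a random slice of the rest
  enz_cluster <- unlist(lapply(planted_clusters, function(g)
    sample(g, round(0.6 * length(g)))))
  enz_rest <- sample(rest, min(120, length(rest)))
  enzyme_gene_ids <- unique(c(enz_cluster, enz_rest))
  pho_enz <- sample(enzyme_gene_ids, 3)
  pho_ids <- c(signal_ids, tf_gene_ids[c("tfA", "tfB", "tfC")], pho_enz)
  pho_truth <- data.frame(molecule_id = pho_ids, layer = "phospho",
                          pattern = "none", direction_WT = "none",
                          direction_OB = "none", amplitude_log2 = 0,
                          t_half_true = NA_real_, speed_true = "undefined",
                          stringsAsFactors = FALSE)
  pho_truth <- set_truth(pho_truth, "sigA", "common", "increase", "increase", "rapid")
  pho_truth <- set_truth(pho_truth, "sigB", "WT_specific", "increase", "none", "rapid")
  pho_truth <- set_truth(pho_truth, "sigC", "OB_specific", "none", "increase", "intermediate")
  pho_truth <- set_truth(pho_truth, tf_gene_ids[["tfB"]], "opposite",
                         "increase", "decrease", "rapid")
  pho_truth <- set_truth(pho_truth, pho_enz[1], "WT_specific", "decrease",
                         "none", "rapid")
  pho_truth <- set_truth(pho_truth, pho_enz[2], "opposite", "decrease",
                         "increase", "intermediate")

  planted <- list(gene = gene_truth, metabolite = met_truth, phospho = pho_truth)
  sim <- generate_timecourses(n_metabolites = n_metabolites, n_genes = n_genes,
                              n_phospho = length(pho_ids),
                              amplitude_log2 = amplitude_log2, cv = cv,
                              nb_dispersion = nb_dispersion,
                              missing_rate = missing_rate, times = times,
                              seed = seed, planted = planted)
  kb <- generate_knowledgebase(gene_ids, met_ids, enzyme_gene_ids,
                               tf_ids = unname(tf_gene_ids),
                               signal_ids = signal_ids,
                               n_reactions = n_reactions,
                               n_pathways = n_pathways,
                               planted_tf_clusters = stats::setNames(
                                 planted_clusters[c("tfA", "tfB", "tfC")],
                                 tf_gene_ids[c("tfA", "tfB", "tfC")]),
                               seed = seed)
  planted_tf_edges <- do.call(rbind, lapply(c("tfA", "tfB", "tfC"), function(tf)
    data.frame(tf_id = tf_gene_ids[[tf]], gene_id = planted_clusters[[tf]],
               stringsAsFactors = FALSE)))
  planted_net <- planted_network_edges(sim$truth, kb, planted_tf_edges)
  list(timecourses = sim$timecourses, kb = kb, truth = sim$truth,
       planted_tf_clusters = stats::setNames(
         planted_clusters[c("tfA", "tfB", "tfC")],
         tf_gene_ids[c("tfA", "tfB", "tfC")]),
       planted_tf_edges = planted_tf_edges,
       planted_network = planted_net,
       times = times, seed = seed)
}

#' Write a study bundle to disk as pipeline inputs
#'
#' Writes metabolite.tsv, gene.tsv, phospho.tsv, the knowledge-base tables
#' under kb/, the planted TF edges and a truth table (TSV).
#' @param bundle output of \code{\link{generate_study_bundle}}.
#' @param dir output directory.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(bundle$timecourses))
    write_timecourse_table(bundle$timecourses[[layer]],
                           file.path(dir, paste0(layer, ".tsv")))
  write_knowledgebase(bundle$kb, file.path(dir, "kb"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$planted_tf_edges,
                     file.path(dir, "planted_tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Recovery metrics of responsiveness calls against planted truth
#'
#' @param calls \code{\link{responsiveness_calls}} output for one layer (or
#'   several stacked layers).
#' @param truth the planted truth table.
#' @return list(sensitivity, direction_accuracy, speed_accuracy,
#'   false_positive_rate, n_planted, n_called).
#' @export
call_recovery_metrics <- function(calls, truth) {
  key <- paste(calls$molecule_id, calls$genotype)
  n_tp <- 0L; n_planted <- 0L; n_dir_ok <- 0L; n_speed_ok <- 0L
  n_speed_evald <- 0L; n_fp <- 0L; n_null <- 0L
  for (g in c("WT", "OB")) {
    tr_dir <- truth[[paste0("direction_", g)]]
    planted <- tr_dir != "none"
    i <- match(paste(truth$molecule_id, g), key)
    called <- calls$responsive[i]
    called[is.na(called)] <- FALSE
    n_planted <- n_planted + sum(planted, na.rm = TRUE)
    tp <- planted & called
    n_tp <- n_tp + sum(tp, na.rm = TRUE)
    n_dir_ok <- n_dir_ok + sum(tp & calls$direction[i] == tr_dir, na.rm = TRUE)
    sp <- tp & calls$speed[i] != "undefined"
    n_speed_evald <- n_speed_evald + sum(sp, na.rm = TRUE)
    n_speed_ok <- n_speed_ok + sum(sp & calls$speed[i] == truth$speed_true,
                                   na.rm = TRUE)
    n_null <- n_null + sum(!planted, na.rm = TRUE)
    n_fp <- n_fp + sum(!planted & called, na.rm = TRUE)
  }
  list(sensitivity = n_tp / n_planted,
       direction_accuracy = n_dir_ok / max(n_tp, 1L),
       speed_accuracy = n_speed_ok / max(n_speed_evald, 1L),
       false_positive_rate = n_fp / max(n_null, 1L),
       n_planted = n_planted, n_called = n_tp)
}

#' Did the motif inference recover the planted TF clusters?
#'
#' A planted TF counts as recovered when it is assigned to at least one
#' dendrogram node that covers its planted cluster with the given recall
#' and precision.
#' @param assignments \code{\link{assign_tf_clusters}} output.
#' @param tree the \code{cluster_tree}.
#' @param planted_clusters named list tf_id -> planted gene vector.
#' @param precision,recall minimum overlap fractions.
#' @return named logical per planted TF.
#' @export
evaluate_tf_recovery <- function(assignments, tree, planted_clusters,
                                 precision = 0.8, recall = 0.8) {
  nodes <- tree_node_leaves(tree)
  vapply(names(planted_clusters), function(tf) {
    planted <- planted_clusters[[tf]]
    rows <- assignments[assignments$assigned & assignments$tf_id == tf, ,
                        drop = FALSE]
    if (nrow(rows) == 0L) return(FALSE)
    any(vapply(rows$node, function(nd) {
      lv <- nodes$leaves[[nd]]
      ov <- length(intersect(lv, planted))
      ov / length(planted) >= recall && ov / length(lv) >= precision
    }, TRUE))
  }, TRUE)
}

edge_key <- function(edges)
  paste(edges$source, edges$target, edges$regulation_type, sep = "|")

#' Precision and recall of an assembled edge set against the planted one
#'
#' Edges are identified by (source, target, regulation type).
#' @param assembled,planted edge data frames.
#' @return list(precision, recall, n_assembled, n_planted).
#' @export
edge_set_precision <- function(assembled, planted) {
  a <- unique(edge_key(assembled)); p <- unique(edge_key(planted))
  list(precision = if (length(a)) length(intersect(a, p)) / length(a) else NA_real_,
       recall = if (length(p)) length(intersect(a, p)) / length(p) else NA_real_,
       n_assembled = length(a), n_planted = length(p))
}
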
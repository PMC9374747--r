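# Shared fixtures and independent oracles, built in code at test time.

# small replicate-level time course from a molecule x genotype list of
# per-time replicate matrices (times x replicates)
make_tc <- function(per_molecule, layer = "metabolite",
                    times = c(0, 20, 60, 120, 240)) {
  ids <- names(per_molecule)
  n_rep <- ncol(per_molecule[[1]][["WT"]])
  vals <- array(NA_real_, c(length(ids), 2, length(times), n_rep),
                dimnames = list(ids, c("WT", "OB"), as.character(times), NULL))
  for (i in seq_along(ids)) for (g in c("WT", "OB"))
    vals[i, g, , ] <- per_molecule[[i]][[g]]
  omics_timecourse(vals, layer)
}

# constant-trace replicate matrix: one row per time, same mean, no noise
flat_reps <- function(level, n_times = 5, n_rep = 5) {
  matrix(level, n_times, n_rep)
}

# trace_reps: per-time means with zero replicate noise
trace_reps <- function(means, n_rep = 5) {
  matrix(rep(means, n_rep), length(means), n_rep)
}

# independent hypergeometric tail-sum oracle: P[X >= a]
hyper_tail_oracle <- function(a, K, n, N) {
  amax <- min(n, K)
  if (a > amax) return(0)
  sum(stats::dhyper(a:amax, K, N - K, n))
}

# independent two-tailed t-test p via numerical integration of the density
welch_p_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tt), Inf,
                       rel.tol = 1e-12)$value
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# brute-force Ward agglomeration via the centroid form of the Ward
# distance: d(A,B) = sqrt(2|A||B|/(|A|+|B|)) * ||centroid_A - centroid_B||
brute_ward <- function(mat) {
  cl <- lapply(seq_len(nrow(mat)), function(i) i)
  cent <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  sizes <- rep(1, nrow(mat))
  heights <- numeric(0)
  merged_sets <- list()
  while (length(cl) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d <- sqrt(2 * sizes[i] * sizes[j] / (sizes[i] + sizes[j])) *
        sqrt(sum((cent[[i]] - cent[[j]])^2))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    newc <- (cent[[i]] * sizes[i] + cent[[j]] * sizes[j]) / (sizes[i] + sizes[j])
    newm <- sort(c(cl[[i]], cl[[j]]))
    heights <- c(heights, bd)
    merged_sets[[length(merged_sets) + 1]] <- newm
    keep <- setdiff(seq_along(cl), c(i, j))
    cl <- c(cl[keep], list(newm))
    cent <- c(cent[keep], list(newc))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  list(heights = heights, merged_sets = merged_sets)
}

# leaf-index sets per merge of a cluster_tree, as sorted integer vectors
tree_merge_sets <- function(tree) {
  nl <- tree_node_leaves(tree)
  lapply(nl$leaves, function(lv) sort(match(lv, tree$leaves)))
}

# minimal 3-reaction knowledge base used across network tests
tiny_kb <- function() {
  knowledge_base(
    enzyme_reactions = data.frame(
      gene_id = c("e1", "e2", "e2"),
      reaction_id = c("R1", "R2", "R3")),
    reaction_metabolites = data.frame(
      reaction_id = c("R1", "R1", "R3"),
      metabolite_id = c("mA", "mB", "mC"),
      role = c("substrate", "product", "product")),
    allosteric = data.frame(metabolite_id = "mA", reaction_id = "R2",
                            mode = "inhibitor"),
    motif_targets = data.frame(tf_id = "tf1", gene_id = c("e1", "e2")),
    background_genes = c("e1", "e2", "tf1", "g9"),
    kinase_targets = data.frame(signal_id = "s1",
                                target_id = c("tf1", "e1"),
                                target_type = c("tf", "enzyme")),
    tf_mode = data.frame(tf_id = "tf1", mode = "activator"),
    reaction_pathways = data.frame(reaction_id = c("R1", "R2", "R3"),
                                   pathway_id = c("pw1", "pw1", "pw2")),
    pathway_class = data.frame(pathway_id = c("pw1", "pw2"),
                               class = c("carbohydrate", "lipid")))
}

# class-map row constructor for hand-built assembly scenarios
cm_row <- function(id, class, dwt = "none", dob = "none",
                   swt = "undefined", sob = "undefined",
                   twt = NA_real_, tob = NA_real_) {
  data.frame(molecule_id = id, class = class,
             direction_WT = dwt, direction_OB = dob,
             t_half_WT = twt, t_half_OB = tob,
             speed_WT = swt, speed_OB = sob,
             responsive_WT = dwt != "none", responsive_OB = dob != "none",
             stringsAsFactors = FALSE)
}
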
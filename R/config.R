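#' Pipeline configuration
#'
#' Collects every tunable threshold of the trans-omic pipeline in one
#' validated list. Defaults are the study's operating point: a molecule is
#' glucose-responsive when |log2 fold change| >= 0.585 (a 1.5-fold change,
#' since 2^0.585 = 1.5) and Storey q <= 0.1 at any post-administration time
#' point; responses with a half-time T1/2 below 20 min are "rapid" and above
#' 60 min "slow"; motif enrichment is evaluated on dendrogram nodes holding
#' at least 100 genes at q <= 0.1; pathway associations are called at
#' q <= 0.01; condensation keeps the top 10% of pathways by regulated-reaction
#' coverage, metabolite-to-pathway edges regulating >= 5 reactions, and
#' transcription factors regulating >= 5 reactions; regulation summaries list
#' regulators of more than 15 reactions.
#'
#' @param fc_threshold_log2 minimum absolute log2 fold change for a
#'   responsive call.
#' @param q_threshold maximum q-value for a responsive call (and for the
#'   gene-selection filter before clustering).
#' @param rapid_max_min T1/2 strictly below this (minutes) is a rapid
#'   response.
#' @param slow_min_min T1/2 strictly above this (minutes) is a slow response;
#'   values in [rapid_max_min, slow_min_min] are intermediate.
#' @param min_detected_fraction minimum fraction of non-missing replicates
#'   required at every genotype x post-administration time point.
#' @param min_cluster_size_for_enrichment dendrogram nodes with fewer genes
#'   are not tested for motif enrichment.
#' @param enrichment_q q-value cutoff for significant motif enrichment.
#' @param pathway_assoc_q q-value cutoff for regulator-pathway association.
#' @param top_fraction_pathways fraction of pathways kept by coverage ranking
#'   during condensation.
#' @param min_reactions_per_condensed_edge metabolite-to-pathway edges
#'   regulating fewer reactions are dropped.
#' @param min_reactions_per_tf_node transcription factors regulating fewer
#'   metabolic reactions (or enzymes, see \code{tf_condense_criterion}) are
#'   dropped from the condensed network.
#' @param display_min_reactions_top_regulators regulation summaries list only
#'   regulators of strictly more than this many reactions.
#' @param n_metabolite_clusters number of metabolite clusters cut from the
#'   dendrogram (display/grouping only; chosen by inspection in the study).
#' @param random_seed integer seed threaded through every stochastic step.
#' @param pool_qvalues_across_times if TRUE, Storey q-values are computed on
#'   the pooled p-vector across time points instead of per time point.
#' @param storey_fixed_lambda if non-NULL, pi0 is estimated at this single
#'   lambda instead of the smoother over the lambda grid.
#' @param enrichment_comparator "odds_ratio" (default) or "p_value": the
#'   metric used to decide whether a child cluster is "more enriched".
#' @param tf_condense_criterion "reactions" (default) or "enzymes": whether
#'   the >= 5 inclusion rule for condensed transcription factors counts
#'   regulated reactions or regulated enzymes.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(fc_threshold_log2 = 0.585,
                            q_threshold = 0.1,
                            rapid_max_min = 20,
                            slow_min_min = 60,
                            min_detected_fraction = 0.5,
                            min_cluster_size_for_enrichment = 100,
                            enrichment_q = 0.1,
                            pathway_assoc_q = 0.01,
                            top_fraction_pathways = 0.10,
                            min_reactions_per_condensed_edge = 5,
                            min_reactions_per_tf_node = 5,
                            display_min_reactions_top_regulators = 15,
                            n_metabolite_clusters = 8,
                            random_seed = 1L,
                            pool_qvalues_across_times = FALSE,
                            storey_fixed_lambda = NULL,
                            enrichment_comparator = c("odds_ratio", "p_value"),
                            tf_condense_criterion = c("reactions", "enzymes")) {
  enrichment_comparator <- match.arg(enrichment_comparator)
  tf_condense_criterion <- match.arg(tf_condense_criterion)
  cfg <- list(
    fc_threshold_log2 = fc_threshold_log2,
    q_threshold = q_threshold,
    rapid_max_min = rapid_max_min,
    slow_min_min = slow_min_min,
    min_detected_fraction = min_detected_fraction,
    min_cluster_size_for_enrichment = min_cluster_size_for_enrichment,
    enrichment_q = enrichment_q,
    pathway_assoc_q = pathway_assoc_q,
    top_fraction_pathways = top_fraction_pathways,
    min_reactions_per_condensed_edge = min_reactions_per_condensed_edge,
    min_reactions_per_tf_node = min_reactions_per_tf_node,
    display_min_reactions_top_regulators = display_min_reactions_top_regulators,
    n_metabolite_clusters = n_metabolite_clusters,
    random_seed = as.integer(random_seed),
    pool_qvalues_across_times = isTRUE(pool_qvalues_across_times),
    storey_fixed_lambda = storey_fixed_lambda,
    enrichment_comparator = enrichment_comparator,
    tf_condense_criterion = tf_condense_criterion
  )
  for (nm in c("q_threshold", "enrichment_q", "pathway_assoc_q")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("config field '%s' must lie strictly between 0 and 1", nm))
  }
  if (cfg$top_fraction_pathways <= 0 || cfg$top_fraction_pathways > 1)
    stop("top_fraction_pathways must lie in (0, 1]")
  if (cfg$rapid_max_min >= cfg$slow_min_min)
    stop("rapid_max_min must be smaller than slow_min_min")
  if (cfg$min_detected_fraction < 0 || cfg$min_detected_fraction > 1)
    stop("min_detected_fraction must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file with a flat mapping of config fields.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
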
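#' Regulatory knowledge base
#'
#' Holds the database-derived maps that wire the trans-omic network:
#' enzyme-gene to reaction (EC-number) assignments, reaction substrates and
#' products, allosteric effectors with mode, transcription-factor binding
#' motif targets with their background gene universe, kinase targets,
#' transcription-factor activator/repressor classes, reaction-to-pathway
#' membership, and pathway classes. These tables play the role that KEGG,
#' BRENDA and TRANSFAC content plays in the study; they are user-supplied or
#' synthetic.
#'
#' @param enzyme_reactions data.frame(gene_id, reaction_id).
#' @param reaction_metabolites data.frame(reaction_id, metabolite_id,
#'   role) with role in {"substrate","product"}.
#' @param allosteric data.frame(metabolite_id, reaction_id, mode) with mode
#'   in {"activator","inhibitor"}.
#' @param motif_targets data.frame(tf_id, gene_id).
#' @param background_genes character vector; motif targets must be a subset.
#' @param kinase_targets data.frame(signal_id, target_id, target_type) with
#'   target_type in {"tf","enzyme"}.
#' @param tf_mode data.frame(tf_id, mode) with mode in
#'   {"activator","repressor","unknown"}.
#' @param reaction_pathways data.frame(reaction_id, pathway_id).
#' @param pathway_class data.frame(pathway_id, class) with class in
#'   {"carbohydrate","lipid","amino_acid","other"}.
#' @return an object of class \code{knowledge_base}. Duplicate rows are
#'   removed; referential integrity is enforced.
#' @export
knowledge_base <- function(enzyme_reactions, reaction_metabolites, allosteric,
                           motif_targets, background_genes, kinase_targets,
                           tf_mode, reaction_pathways, pathway_class) {
  need <- function(df, cols, nm) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!all(cols %in% names(df)))
      stop("knowledge-base table '", nm, "' must have columns: ",
           paste(cols, collapse = ", "))
    unique(df[cols])
  }
  kb <- list(
    enzyme_reactions = need(enzyme_reactions, c("gene_id", "reaction_id"), "enzyme_reactions"),
    reaction_metabolites = need(reaction_metabolites,
                                c("reaction_id", "metabolite_id", "role"), "reaction_metabolites"),
    allosteric = need(allosteric, c("metabolite_id", "reaction_id", "mode"), "allosteric"),
    motif_targets = need(motif_targets, c("tf_id", "gene_id"), "motif_targets"),
    background_genes = unique(as.character(background_genes)),
    kinase_targets = need(kinase_targets, c("signal_id", "target_id", "target_type"), "kinase_targets"),
    tf_mode = need(tf_mode, c("tf_id", "mode"), "tf_mode"),
    reaction_pathways = need(reaction_pathways, c("reaction_id", "pathway_id"), "reaction_pathways"),
    pathway_class = need(pathway_class, c("pathway_id", "class"), "pathway_class")
  )
  known <- unique(kb$enzyme_reactions$reaction_id)
  for (tab in c("allosteric", "reaction_metabolites", "reaction_pathways")) {
    orphans <- setdiff(unique(kb[[tab]]$reaction_id), known)
    if (length(orphans))
      stop("integrity error: table '", tab, "' references unknown reaction ids: ",
           paste(orphans, collapse = ", "))
  }
  stray <- setdiff(unique(kb$motif_targets$gene_id), kb$background_genes)
  if (length(stray))
    stop("integrity error: motif targets outside background_genes: ",
         paste(utils::head(stray, 5), collapse = ", "))
  if (!all(kb$allosteric$mode %in% c("activator", "inhibitor")))
    stop("allosteric mode must be 'activator' or 'inhibitor'")
  if (!all(kb$reaction_metabolites$role %in% c("substrate", "product")))
    stop("reaction_metabolites role must be 'substrate' or 'product'")
  if (!all(kb$kinase_targets$target_type %in% c("tf", "enzyme")))
    stop("kinase_targets target_type must be 'tf' or 'enzyme'")
  if (!all(kb$tf_mode$mode %in% c("activator", "repressor", "unknown")))
    stop("tf_mode mode must be 'activator', 'repressor' or 'unknown'")
  if (!all(kb$pathway_class$class %in% c("carbohydrate", "lipid", "amino_acid", "other")))
    stop("pathway_class class must be carbohydrate/lipid/amino_acid/other")
  structure(kb, class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_base> %d enzyme genes, %d reactions, ",
                     "%d pathways, %d TFs, %d signaling molecules\n"),
              length(unique(x$enzyme_reactions$gene_id)),
              length(kb_reaction_ids(x)),
              length(unique(x$reaction_pathways$pathway_id)),
              length(kb_roles(x)$tf_ids),
              length(kb_roles(x)$signal_ids)))
  invisible(x)
}

#' All reaction identifiers of a knowledge base
#' @param kb a \code{knowledge_base}.
#' @return character vector of reaction ids (the association-test universe).
#' @export
kb_reaction_ids <- function(kb) unique(kb$enzyme_reactions$reaction_id)

#' Molecule roles declared by a knowledge base
#'
#' Transcription factors are the ids appearing in the motif or TF-mode
#' tables; metabolic-enzyme genes the ids of the enzyme-reaction map;
#' signaling molecules the kinase sources. The three role sets must be
#' disjoint for layer assignment.
#' @param kb a \code{knowledge_base}.
#' @return list(tf_ids, enzyme_ids, signal_ids).
#' @export
kb_roles <- function(kb) {
  list(tf_ids = unique(c(kb$motif_targets$tf_id, kb$tf_mode$tf_id)),
       enzyme_ids = unique(kb$enzyme_reactions$gene_id),
       signal_ids = unique(kb$kinase_targets$signal_id))
}

kb_files <- c(enzyme_reactions = "enzyme_reactions.tsv",
              reaction_metabolites = "reaction_metabolites.tsv",
              allosteric = "allosteric.tsv",
              motif_targets = "motif_targets.tsv",
              kinase_targets = "kinase_targets.tsv",
              tf_mode = "tf_mode.tsv",
              reaction_pathways = "reaction_pathways.tsv",
              pathway_class = "pathway_class.tsv")

#' Read a knowledge base from a directory of TSV tables
#'
#' Expects the files \code{enzyme_reactions.tsv},
#' \code{reaction_metabolites.tsv}, \code{allosteric.tsv},
#' \code{motif_targets.tsv}, \code{kinase_targets.tsv}, \code{tf_mode.tsv},
#' \code{reaction_pathways.tsv}, \code{pathway_class.tsv} (headers as in
#' \code{\link{knowledge_base}}) and \code{background_genes.txt} (one gene id
#' per line). Rows are deduplicated and referential integrity is checked.
#' @param dir directory containing the tables.
#' @return a validated \code{knowledge_base}.
#' @export
read_knowledgebase <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing knowledge-base table: ", f)
    utils::read.delim(p, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  tabs <- lapply(kb_files, rd)
  bg_path <- file.path(dir, "background_genes.txt")
  if (!file.exists(bg_path)) stop("missing knowledge-base table: background_genes.txt")
  bg <- readLines(bg_path)
  bg <- bg[nzchar(bg)]
  knowledge_base(tabs$enzyme_reactions, tabs$reaction_metabolites,
                 tabs$allosteric, tabs$motif_targets, bg, tabs$kinase_targets,
                 tabs$tf_mode, tabs$reaction_pathways, tabs$pathway_class)
}

#' Write a knowledge base as a directory of TSV tables
#' @param kb a \code{knowledge_base}.
#' @param dir output directory (created if needed).
#' @export
write_knowledgebase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(kb_files)) {
    utils::write.table(kb[[nm]], file.path(dir, kb_files[[nm]]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(kb$background_genes, file.path(dir, "background_genes.txt"))
  invisible(dir)
}
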
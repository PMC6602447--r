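# IC-weighted phenotype matching: the core score.

#' Match-class weights for the phenotype score
#'
#' Defaults are the engine's trained weights: 5 for a direct term match, 2
#' for an ancestor match (the patient term is more general than a term
#' annotated to the gene), 0.05 for a descendant match (more specific).
#' `known_pathogenic` is an additive per-gene bonus for carrying a variant
#' listed in the known-pathogenic set; it defaults to 0 so that rankings are
#' driven purely by phenotype, matching how the engine is benchmarked.
#'
#' @param direct,ancestor,descendant,known_pathogenic Non-negative weights.
#' @return A `weight_config` list.
#' @export
weight_config <- function(direct = 5, ancestor = 2, descendant = 0.05,
                          known_pathogenic = 0) {
  w <- list(direct = direct, ancestor = ancestor, descendant = descendant,
            known_pathogenic = known_pathogenic)
  if (any(unlist(w) < 0)) stop("weights must be non-negative")
  structure(w, class = "weight_config")
}

#' Classify how a patient term relates to a gene's annotations
#'
#' `direct` if the patient term is itself annotated to the gene; `ancestor`
#' if it is an ancestor of (more general than) at least one annotated term;
#' `descendant` if it is a descendant of (more specific than) one; else
#' `none`. When several hold via different gene terms, precedence is
#' direct > ancestor > descendant.
#'
#' @param graph An `ontology_graph`.
#' @param gene_terms Character vector of the gene's asserted term ids (no
#'   closure).
#' @param t_patient A patient term id.
#' @return One of `"direct"`, `"ancestor"`, `"descendant"`, `"none"`.
#' @export
match_class <- function(graph, gene_terms, t_patient) {
  check_term(graph, t_patient)
  if (t_patient %in% gene_terms) return("direct")
  if (any(gene_terms %in% graph$descendants[[t_patient]])) return("ancestor")
  if (any(gene_terms %in% graph$ancestors[[t_patient]])) return("descendant")
  "none"
}

#' Score one gene against the patient's phenotype terms
#'
#' Each patient term contributes once, with its own information content
#' scaled by the weight of its best match class:
#' \deqn{S_{HPO}(g) = \sum_{t \in patient} w(class(t, g)) \cdot IC(t)}
#' with `w(none) = 0`. A patient term with no IC entry (never annotated to
#' any gene under the chosen propagation rule) contributes 0. The gene's
#' total adds `known_pathogenic` from the weights when
#' `has_known_pathogenic_variant` is `TRUE`.
#'
#' @param graph An `ontology_graph`.
#' @param ic An `ic_table` from [compute_ic()].
#' @param gene_terms The gene's asserted term ids.
#' @param patient_terms Non-empty character vector of patient term ids.
#' @param weights A [weight_config()].
#' @param has_known_pathogenic_variant Does the gene carry a kept variant in
#'   the known-pathogenic set?
#' @return A `score_breakdown`: list with `gene_terms`, `terms` (data.frame
#'   term / match_class / ic / contribution), `hpo_score`,
#'   `pathogenic_bonus`, `total`.
#' @export
score_gene <- function(graph, ic, gene_terms, patient_terms, weights = weight_config(),
                       has_known_pathogenic_variant = FALSE) {
  stopifnot(length(patient_terms) > 0L)
  cls <- vapply(patient_terms, function(t) match_class(graph, gene_terms, t),
                "", USE.NAMES = FALSE)
  ic_t <- unclass(ic)[patient_terms]
  ic_t[is.na(ic_t)] <- 0
  w <- c(direct = weights$direct, ancestor = weights$ancestor,
         descendant = weights$descendant, none = 0)
  contrib <- unname(w[cls]) * as.numeric(ic_t)
  bonus <- if (isTRUE(has_known_pathogenic_variant)) weights$known_pathogenic else 0
  structure(
    list(terms = data.frame(term = patient_terms, match_class = cls,
                            ic = as.numeric(ic_t), contribution = contrib,
                            stringsAsFactors = FALSE),
         hpo_score = sum(contrib),
         pathogenic_bonus = bonus,
         total = sum(contrib) + bonus),
    class = "score_breakdown"
  )
}

#' Score every candidate gene carrying a kept variant
#'
#' The candidate set is the genes owning at least one kept variant record.
#' All candidates are scored, including genes that match nothing (score 0):
#' they rank at the bottom rather than being dropped.
#'
#' @param graph An `ontology_graph`.
#' @param ic An `ic_table`.
#' @param ann An `annotation_set`; genes absent from it have no annotated
#'   terms and can only score 0 (plus any pathogenic bonus).
#' @param records Kept variant records (after filters and inheritance).
#' @param patient_terms Patient term ids.
#' @param weights A [weight_config()].
#' @return Named list gene -> `score_breakdown`.
#' @export
score_all_genes <- function(graph, ic, ann, records, patient_terms,
                            weights = weight_config()) {
  genes <- sort(unique(records$gene[!is.na(records$gene)]))
  if (length(genes) == 0L) return(stats::setNames(list(), character(0)))
  kp_genes <- unique(records$gene[records$known_pathogenic & !is.na(records$gene)])
  out <- lapply(genes, function(g) {
    gt <- ann$gene_to_terms[[g]]
    if (is.null(gt)) gt <- character(0)
    score_gene(graph, ic, gt, patient_terms, weights,
               has_known_pathogenic_variant = g %in% kp_genes)
  })
  stats::setNames(out, genes)
}

# Per-gene summed IC by match class: the weight-independent part of the
# score. One row per candidate gene, columns direct/ancestor/descendant;
# scores for any weight vector follow as M %*% w. Shared by the grid sweep.
match_ic_matrix <- function(graph, ic, ann, genes, patient_terms) {
  ic_v <- unclass(ic)[patient_terms]
  ic_v[is.na(ic_v)] <- 0
  ic_v <- as.numeric(ic_v)
  M <- matrix(0, nrow = length(genes), ncol = 3,
              dimnames = list(genes, c("direct", "ancestor", "descendant")))
  anc_t <- graph$ancestors[patient_terms]
  desc_t <- graph$descendants[patient_terms]
  for (gi in seq_along(genes)) {
    gt <- ann$gene_to_terms[[genes[gi]]]
    if (is.null(gt) || length(gt) == 0L) next
    for (ti in seq_along(patient_terms)) {
      t <- patient_terms[ti]
      cls <- if (t %in% gt) "direct"
      else if (any(gt %in% desc_t[[ti]])) "ancestor"
      else if (any(gt %in% anc_t[[ti]])) "descendant"
      else NA_character_
      if (!is.na(cls)) M[gi, cls] <- M[gi, cls] + ic_v[ti]
    }
  }
  M
}
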
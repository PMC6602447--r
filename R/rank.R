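# Tie-aware ranking and report output.

#' Rank scored genes with competition ranking
#'
#' Genes are ordered by descending total score; `rank(g) = 1 + |{g': S(g') >
#' S(g)}|`, so genes with the exact same score share the same rank (the
#' "1, 1, 3" convention). Within a tie, rows are sorted lexicographically by
#' gene symbol for deterministic output.
#'
#' @param scores Either a named list of `score_breakdown` objects (from
#'   [score_all_genes()]) or a named numeric vector of totals.
#' @return A data.frame with columns `rank`, `gene`, `score`, and -- when
#'   breakdowns were supplied -- `hpo_score`, `pathogenic_bonus`.
#' @export
rank_genes <- function(scores) {
  if (is.list(scores)) {
    total <- vapply(scores, function(b) b$total, 0)
    hpo <- vapply(scores, function(b) b$hpo_score, 0)
    bonus <- vapply(scores, function(b) b$pathogenic_bonus, 0)
    df <- data.frame(gene = names(scores), score = total, hpo_score = hpo,
                     pathogenic_bonus = bonus, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = names(scores), score = as.numeric(scores),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    return(cbind(data.frame(rank = integer(0)), df))
  }
  df <- df[order(-df$score, df$gene), , drop = FALSE]
  df$rank <- vapply(df$score, function(s) 1L + sum(df$score > s), 0L)
  rownames(df) <- NULL
  df[, c("rank", setdiff(names(df), "rank"))]
}

#' Write the ranked gene report
#'
#' `tsv` writes the summary table: rank, gene, score, best (most severe)
#' variant class, number of variants, highlight flags. `json` writes the
#' full detail: per-gene score breakdown plus its variant rows. Both outputs
#' are byte-deterministic for fixed input.
#'
#' @param ranked Data.frame from [rank_genes()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param scores Named list of `score_breakdown`s (required for `json`).
#' @param records Kept variant records; used for per-gene variant columns.
#' @param highlights Optional list of `gene_set`s with role `highlight`;
#'   each contributes a logical flag column to the TSV.
#' @param url_template Optional template like
#'   `"https://example.org/gene/{gene}"` expanded into a plain-string link
#'   column (no network access).
#' @return `path`, invisibly.
#' @export
write_report <- function(ranked, path, format = c("tsv", "json"),
                         scores = NULL, records = NULL, highlights = NULL,
                         url_template = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- ranked
    if (!is.null(records) && nrow(ranked) > 0L) {
      out$best_class <- vapply(out$gene, function(g) {
        cls <- records$effect_class[!is.na(records$gene) & records$gene == g]
        if (length(cls) == 0L) NA_character_
        else severity_classes[min(severity_rank(cls))]
      }, "")
      out$n_variants <- vapply(out$gene, function(g) {
        sum(!is.na(records$gene) & records$gene == g)
      }, 0L)
    }
    for (hs in highlights) {
      out[[paste0("in_", gsub("[^A-Za-z0-9]", "_", hs$name))]] <-
        out$gene %in% hs$genes
    }
    if (!is.null(url_template)) {
      out$link <- vapply(out$gene, function(g) {
        gsub("{gene}", g, url_template, fixed = TRUE)
      }, "")
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    detail <- lapply(seq_len(nrow(ranked)), function(i) {
      g <- ranked$gene[i]
      item <- list(rank = ranked$rank[i], gene = g, score = ranked$score[i])
      if (!is.null(scores) && g %in% names(scores)) {
        b <- scores[[g]]
        item$hpo_score <- b$hpo_score
        item$pathogenic_bonus <- b$pathogenic_bonus
        item$terms <- b$terms
      }
      if (!is.null(records)) {
        item$variants <- records[!is.na(records$gene) & records$gene == g, ,
                                 drop = FALSE]
      }
      item
    })
    jsonlite::write_json(detail, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Run the full prioritization pipeline
#'
#' Convenience wrapper: attach frequency / known-pathogenic annotations,
#' apply the filter chain, apply mode-of-inheritance logic, score candidate
#' genes against the patient terms, and rank.
#'
#' @param records Variant records from [read_vcf()].
#' @param graph An `ontology_graph`.
#' @param ann An `annotation_set`.
#' @param ic An `ic_table` (computed from `graph` + `ann` when `NULL`).
#' @param patient_terms Patient HPO term ids; obsolete ids are resolved
#'   through the ontology's `replaced_by` map, unknown ids are an error.
#' @param cfg A [filter_config()]; its `inheritance` field selects the mode.
#' @param weights A [weight_config()].
#' @param freqs,known Optional frequency table / known-pathogenic set.
#' @return List with `ranked` (data.frame), `scores` (breakdown list),
#'   `kept` (variant records), `filter_report`.
#' @export
prioritize <- function(records, graph, ann, ic = NULL, patient_terms,
                       cfg = filter_config(), weights = weight_config(),
                       freqs = NULL, known = NULL) {
  if (is.null(ic)) ic <- compute_ic(graph, ann)
  resolved <- vapply(patient_terms, function(t) {
    r <- resolve_term(graph, t)
    if (is.na(r)) stop("unknown patient term id: ", t)
    if (!identical(r, t)) message("patient term ", t, " resolved to ", r)
    r
  }, "", USE.NAMES = FALSE)
  flt <- apply_filters(records, cfg, freqs = freqs, known = known)
  kept <- apply_inheritance(flt$kept, cfg$inheritance)
  scores <- score_all_genes(graph, ic, ann, kept, resolved, weights)
  list(ranked = rank_genes(scores), scores = scores, kept = kept,
       filter_report = flt$report)
}
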
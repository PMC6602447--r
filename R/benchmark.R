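# Spike-in benchmarking: rank recovery of a known causative gene from a
# background exome, capped at rank 100, plus the weight-grid sweep.

#' Rank cap for benchmark bookkeeping
#'
#' Cases whose causative gene ranks beyond this are reported as not found.
#' @export
RANK_CAP <- 100L

#' Spike a benchmark case's causative variants into a background exome
#'
#' Inserts the case's variant records (with their stated genotypes) into the
#' background record set. A spike landing on an occupied site (same chrom,
#' pos) replaces the background record, with a message. Output is sorted by
#' coordinate.
#'
#' @param background Variant record data.frame (as from [read_vcf()]).
#' @param case A `benchmark_case` (see [load_cases()]).
#' @param coverage Read depth assigned to the spiked records.
#' @return The combined variant record data.frame.
#' @export
spike_in <- function(background, case, coverage = 50L) {
  v <- case$variants
  norm <- normalize_allele(v$pos, v$ref, v$alt)
  spikes <- data.frame(
    chrom = normalize_chrom(v$chrom), pos = norm$pos, ref = norm$ref,
    alt = norm$alt, gene = case$gene,
    effect_class = classify_effect(v$effect), genotype = v$genotype,
    coverage = as.integer(coverage), af_db = NA_real_,
    known_pathogenic = FALSE, stringsAsFactors = FALSE)
  occupied <- paste(background$chrom, background$pos) %in%
    paste(spikes$chrom, spikes$pos)
  if (any(occupied)) {
    message("spike-in replaced ", sum(occupied), " occupied site(s) for ",
            case$case_id)
  }
  out <- rbind(background[!occupied, names(spikes), drop = FALSE], spikes)
  out <- out[order(match(out$chrom, fx_contig_order), out$pos, out$ref,
                   out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared per-case preparation: spike, annotate, filter, inheritance.
# Returns the kept records and the candidate gene list.
prepare_case <- function(case, background, cfg, freqs = NULL, known = NULL) {
  cfg$inheritance <- "any"  # the case's own mode is applied below
  recs <- spike_in(background, case)
  flt <- apply_filters(recs, cfg, freqs = freqs, known = known)
  mode <- case$inheritance
  if (is.null(mode) || is.na(mode) || !nzchar(mode)) mode <- "any"
  kept <- apply_inheritance(flt$kept, mode)
  kept
}

#' Evaluate one spike-in case through the full pipeline
#'
#' Spikes the causative variant(s) into the background, applies the filter
#' chain and the case's mode of inheritance, scores all candidate genes
#' against the case's phenotype terms (with the known-pathogenic bonus
#' disabled, so ranking is purely phenotype-driven), ranks with competition
#' ranking, and records the causative gene's rank. A rank beyond
#' [RANK_CAP], or a causative gene absent from the output, is `not_found`.
#' A pipeline failure is reported as status `errored`, never as `not_found`.
#'
#' @param case A `benchmark_case`.
#' @param background Background variant records.
#' @param graph,ann,ic Ontology, annotation set and IC table.
#' @param weights A [weight_config()]; its `known_pathogenic` weight is
#'   forced to 0 for benchmarking.
#' @param cfg A [filter_config()] holding the record-level filters; the
#'   case's own `inheritance` field overrides `cfg$inheritance`.
#' @param freqs,known Optional frequency table / known-pathogenic set.
#' @return A `benchmark_result`: list with `case_id`, `rank` (integer or
#'   `NA`), `status` (`"found"`, `"not_found"`, `"errored"`), `n_candidates`.
#' @export
evaluate_case <- function(case, background, graph, ann, ic,
                          weights = weight_config(), cfg = filter_config(),
                          freqs = NULL, known = NULL) {
  weights$known_pathogenic <- 0
  res <- tryCatch({
    kept <- prepare_case(case, background, cfg, freqs, known)
    scores <- score_all_genes(graph, ic, ann, kept, case$terms, weights)
    ranked <- rank_genes(scores)
    i <- match(case$gene, ranked$gene)
    if (is.na(i) || ranked$rank[i] > RANK_CAP) {
      list(rank = NA_integer_, status = "not_found",
           n_candidates = nrow(ranked))
    } else {
      list(rank = ranked$rank[i], status = "found",
           n_candidates = nrow(ranked))
    }
  }, error = function(e) {
    list(rank = NA_integer_, status = "errored", n_candidates = NA_integer_)
  })
  structure(c(list(case_id = case$case_id), res), class = "benchmark_result")
}

#' Run all benchmark cases and collect results
#'
#' @param cases List of `benchmark_case`s.
#' @inheritParams evaluate_case
#' @return Data.frame: case_id, gene, inheritance, rank, status.
#' @export
run_benchmark <- function(cases, background, graph, ann, ic,
                          weights = weight_config(), cfg = filter_config(),
                          freqs = NULL, known = NULL) {
  rows <- lapply(cases, function(cs) {
    r <- evaluate_case(cs, background, graph, ann, ic, weights, cfg,
                       freqs, known)
    data.frame(case_id = cs$case_id, gene = cs$gene,
               inheritance = cs$inheritance, rank = r$rank,
               status = r$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative top-k accuracy over benchmark results
#'
#' `acc(k)` is the fraction of cases whose causative gene ranked within the
#' top `k`. Errored and not-found cases stay in the denominator and never
#' enter the numerator.
#'
#' @param results Data.frame from [run_benchmark()] (columns `rank`,
#'   `status`).
#' @param ks Integer vector of rank cutoffs within `1..RANK_CAP`.
#' @return Named numeric vector `acc` over `ks`.
#' @export
cumulative_accuracy <- function(results, ks = c(1L, 10L, 20L, 100L)) {
  if (nrow(results) == 0L) stop("empty benchmark result set")
  stopifnot(all(ks >= 1L), all(ks <= RANK_CAP))
  found <- results$status == "found"
  vapply(stats::setNames(as.integer(ks), ks), function(k) {
    sum(found & !is.na(results$rank) & results$rank <= k) / nrow(results)
  }, 0)
}

#' Weight grid for the sweep
#'
#' The default grid crosses 7 direct, 7 ancestor and 5 descendant weights,
#' 245 combinations in total.
#'
#' @param direct,ancestor,descendant Candidate weight values.
#' @return A `grid_spec` data.frame, one row per combination.
#' @export
grid_spec <- function(direct = c(0.5, 1, 2, 3, 5, 7, 10),
                      ancestor = c(0.05, 0.1, 0.5, 1, 2, 3, 5),
                      descendant = c(0.05, 0.1, 0.5, 1, 2)) {
  g <- expand.grid(direct = direct, ancestor = ancestor,
                   descendant = descendant, KEEP.OUT.ATTRS = FALSE)
  structure(g, class = c("grid_spec", "data.frame"))
}

#' Sweep the benchmark over a grid of match weights
#'
#' For every weight combination, every case is re-ranked and the rank
#' distribution summarized. The weight-independent part of each case -- the
#' filter chain, the inheritance logic, and each candidate gene's summed IC
#' per match class -- is computed once; each combination is then a linear
#' combination of the per-gene IC sums, which is exactly what
#' [score_gene()] computes term by term.
#'
#' No winning combination is declared: the sweep reports, the user chooses.
#'
#' @param cases List of `benchmark_case`s.
#' @param background,graph,ann,ic As in [evaluate_case()].
#' @param grid A [grid_spec()].
#' @param cfg,freqs,known As in [evaluate_case()].
#' @return Data.frame with one row per combination: the three weights,
#'   `acc1`, `acc10`, `acc20`, `acc100`, `median_rank` (over found cases),
#'   `unsolved` (fraction not found within the cap, errored included),
#'   sorted by `acc10` descending then `unsolved` ascending.
#' @export
weight_grid_search <- function(cases, background, graph, ann, ic,
                               grid = grid_spec(), cfg = filter_config(),
                               freqs = NULL, known = NULL) {
  stopifnot(nrow(grid) > 0L)
  prepped <- lapply(cases, function(cs) {
    tryCatch({
      kept <- prepare_case(cs, background, cfg, freqs, known)
      genes <- sort(unique(kept$gene[!is.na(kept$gene)]))
      list(M = match_ic_matrix(graph, ic, ann, genes, cs$terms),
           gene = cs$gene, errored = FALSE)
    }, error = function(e) list(M = NULL, gene = cs$gene, errored = TRUE))
  })

  n_cases <- length(cases)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- as.numeric(grid[i, c("direct", "ancestor", "descendant")])
    ranks <- vapply(prepped, function(p) {
      if (p$errored || is.null(p$M) || !(p$gene %in% rownames(p$M))) {
        return(NA_integer_)
      }
      s <- as.numeric(p$M %*% w)
      rank <- 1L + sum(s > s[match(p$gene, rownames(p$M))])
      if (rank > RANK_CAP) NA_integer_ else rank
    }, 0L)
    found <- !is.na(ranks)
    data.frame(direct = w[1L], ancestor = w[2L], descendant = w[3L],
               acc1 = sum(found & ranks <= 1L) / n_cases,
               acc10 = sum(found & ranks <= 10L) / n_cases,
               acc20 = sum(found & ranks <= 20L) / n_cases,
               acc100 = sum(found) / n_cases,
               median_rank = if (any(found)) stats::median(ranks[found])
                             else NA_real_,
               unsolved = sum(!found) / n_cases)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$acc10, out$unsolved), , drop = FALSE]
  rownames(out) <- NULL
  out
}
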
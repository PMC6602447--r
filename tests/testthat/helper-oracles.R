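# Shared test fixtures and independent brute-force oracles. The oracles do
# everything by explicit path enumeration / pair enumeration and never call
# the package's traversal or scoring code paths.

# Write a toy OBO from a named parent list, e.g. list(root = character(0),
# A = "root", B = c("A")), and parse it.
toy_graph <- function(parents, extra_lines = character(0)) {
  path <- tempfile(fileext = ".obo")
  out <- c("format-version: 1.2", "")
  for (id in names(parents)) {
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: name of ", id),
             paste0("is_a: ", parents[[id]]), "")
  }
  writeLines(c(out, extra_lines), path)
  parse_obo(path)
}

# Build an annotation_set by writing and loading a TSV.
toy_ann <- function(gene_to_terms, graph) {
  path <- tempfile(fileext = ".tsv")
  rows <- unlist(lapply(names(gene_to_terms), function(g) {
    paste(g, gene_to_terms[[g]], sep = "\t")
  }))
  writeLines(rows, path)
  load_gene_annotations(path, graph)
}

# Random layered DAG as a named parent list (node "N1" is always a root).
random_parent_list <- function(n_nodes) {
  ids <- paste0("N", seq_len(n_nodes))
  parents <- stats::setNames(vector("list", n_nodes), ids)
  parents[[1L]] <- character(0)
  for (i in seq_len(n_nodes)[-1L]) {
    k <- sample(0:min(3L, i - 1L), 1L)
    parents[[i]] <- if (k == 0L) character(0) else
      ids[sample.int(i - 1L, k)]
  }
  parents
}

# Oracle: all ancestors of `t` by exhaustive enumeration of upward paths.
oracle_ancestors <- function(parents, t) {
  walk <- function(node) {
    ps <- parents[[node]]
    unique(c(ps, unlist(lapply(ps, walk))))
  }
  sort(unique(walk(t)))
}

# Oracle: descendants = all nodes whose ancestor enumeration contains t.
oracle_descendants <- function(parents, t) {
  sort(names(parents)[vapply(names(parents), function(v) {
    t %in% oracle_ancestors(parents, v)
  }, TRUE)])
}

# Oracle IC: count genes through the closure with oracle_ancestors.
oracle_ic <- function(parents, gene_to_terms, propagate = TRUE) {
  n_total <- length(gene_to_terms)
  counts <- integer(0)
  for (g in names(gene_to_terms)) {
    terms <- gene_to_terms[[g]]
    if (propagate) {
      terms <- unique(c(terms, unlist(lapply(terms, function(t) {
        oracle_ancestors(parents, t)
      }))))
    }
    for (t in terms) counts[t] <- if (t %in% names(counts)) counts[[t]] + 1L else 1L
  }
  -log(counts / n_total)
}

# Oracle score: enumerate all (patient term, gene term) pairs, classify each
# by explicit path search, keep the best class per patient term, sum
# weighted patient-term IC.
oracle_score <- function(parents, ic, gene_terms, patient_terms, w) {
  prec <- c(direct = 3L, ancestor = 2L, descendant = 1L, none = 0L)
  total <- 0
  for (t in patient_terms) {
    best <- "none"
    for (gt in gene_terms) {
      cls <- if (t == gt) "direct"
      else if (t %in% oracle_ancestors(parents, gt)) "ancestor"
      else if (gt %in% oracle_ancestors(parents, t)) "descendant"
      else "none"
      if (prec[cls] > prec[best]) best <- cls
    }
    ic_t <- if (t %in% names(ic)) ic[[t]] else 0
    wt <- switch(best, direct = w$direct, ancestor = w$ancestor,
                 descendant = w$descendant, none = 0)
    total <- total + wt * ic_t
  }
  total
}

# Oracle competition rank: 1 + number of strictly greater scores.
oracle_rank <- function(scores, g) 1L + sum(scores > scores[[g]])

# A small in-memory variant record table for filter tests.
toy_records <- function(...) {
  rows <- list(...)
  defaults <- list(chrom = "1", pos = 100L, ref = "A", alt = "T",
                   gene = "GENE1", effect_class = "missense",
                   genotype = "het", coverage = 30L, af_db = NA_real_,
                   known_pathogenic = FALSE)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(defaults, rows[[i]])
    r$pos <- r$pos + 10L * (i - 1L)  # distinct sites unless overridden
    if (!is.null(rows[[i]]$pos)) r$pos <- rows[[i]]$pos
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

# Shared small fixture set, generated once per test run.
fx_env <- new.env(parent = emptyenv())
shared_fixtures <- function(seed = 42L, n_cases = 50L) {
  key <- paste0("s", seed, "c", n_cases)
  if (!is.null(fx_env[[key]])) return(fx_env[[key]])
  spec <- fixture_spec(seed = seed, n_cases = n_cases)
  dir <- file.path(tempdir(), paste0("phenoprior-fx-", key))
  paths <- make_fixtures(spec, dir)
  graph <- parse_obo(paths$ontology)
  ann <- load_gene_annotations(paths$annotations, graph)
  fx <- list(spec = spec, paths = paths, graph = graph, ann = ann,
             ic = compute_ic(graph, ann),
             background = read_vcf(paths$vcf),
             freqs = load_frequencies(paths$frequencies),
             cases = load_cases(paths$cases),
             cfg = filter_config(max_af = 0.01, min_coverage = 10))
  fx_env[[key]] <- fx
  fx
}
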
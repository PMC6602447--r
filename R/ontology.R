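# Ontology parsing, DAG traversal and information content.

#' Parse an OBO ontology file into a DAG
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file and builds a directed
#' acyclic graph over `is_a` edges. Only the keys `id`, `name`, `is_a`,
#' `is_obsolete` and `replaced_by` are consumed; all other stanza lines and
#' non-`[Term]` stanzas are ignored. Obsolete terms are resolved through
#' `replaced_by` when present (all references to them are remapped), and
#' dropped with a warning otherwise.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `ids` (character vector of term ids), `name` (named character),
#'   `parents` (named list of character vectors, `is_a` edges),
#'   `children` (inverse of `parents`), `roots` (ids with no parents),
#'   `ancestors` and `descendants` (named lists holding the precomputed
#'   transitive closures, excluding the term itself), and `replaced`
#'   (named character map from obsolete ids to their replacements).
#' @details A cycle among `is_a` edges or a parent reference to a term id
#'   absent from the file is a hard error.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: HP:0000001", "name: root", "",
#'   "[Term]", "id: HP:0000002", "name: child", "is_a: HP:0000001 ! root"),
#'   obo)
#' g <- parse_obo(obo)
#' g$roots
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  # split into stanzas
  stanza_start <- grep("^\\[", lines)
  if (length(stanza_start) == 0L) stop("no stanzas found in OBO file: ", path)
  bounds <- c(stanza_start, length(lines) + 1L)

  ids <- character(0)
  nm <- character(0)
  parents <- list()
  obsolete <- character(0)
  replaced <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (i in seq_along(stanza_start)) {
    head_line <- lines[stanza_start[i]]
    if (!identical(trimws(head_line), "[Term]")) next
    body <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else "", "")
    id <- trimws(strip_comment(vals[keys == "id"][1L]))
    if (is.na(id) || !nzchar(id)) next
    is_a <- trimws(strip_comment(vals[keys == "is_a"]))
    is_obs <- any(keys == "is_obsolete" &
                    grepl("^true", trimws(vals), ignore.case = TRUE))
    rep_by <- trimws(strip_comment(vals[keys == "replaced_by"]))

    if (is_obs) {
      obsolete <- c(obsolete, id)
      if (length(rep_by) > 0L && nzchar(rep_by[1L])) {
        replaced[id] <- rep_by[1L]
      }
      next
    }
    ids <- c(ids, id)
    nm[id] <- trimws(strip_comment(vals[keys == "name"][1L]))
    parents[[id]] <- unique(is_a[nzchar(is_a)])
  }

  if (length(ids) == 0L) stop("OBO file contains no usable [Term] stanzas: ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate term id in OBO file: ", ids[duplicated(ids)][1L])
  }

  dropped <- setdiff(obsolete, names(replaced))
  if (length(dropped) > 0L) {
    warning("dropped ", length(dropped),
            " obsolete term(s) without replaced_by: ",
            paste(utils::head(dropped, 3L), collapse = ", "))
  }

  # resolve references through replaced_by chains (obsolete -> live id)
  resolve <- function(id) {
    seen <- character(0)
    while (id %in% names(replaced)) {
      if (id %in% seen) stop("replaced_by cycle at term ", id)
      seen <- c(seen, id)
      id <- replaced[[id]]
    }
    id
  }
  parents <- lapply(parents, function(p) {
    unique(vapply(p, resolve, "", USE.NAMES = FALSE))
  })
  names(parents) <- ids

  # drop parent edges into dropped-obsolete terms, error on unknown ids
  parents <- lapply(parents, function(p) setdiff(p, dropped))
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing) > 0L) {
    stop("is_a reference to unknown term id: ", missing[1L])
  }

  g <- build_ontology_graph(ids, nm, parents)
  g$replaced <- replaced
  g
}

# Assemble the graph object from id/name/parent data; topological sort doubles
# as the acyclicity check and drives the closure computation.
build_ontology_graph <- function(ids, nm, parents) {
  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  # Kahn's algorithm from the roots; leftover nodes are on a cycle.
  indeg <- lengths(parents[ids])
  names(indeg) <- ids
  queue <- ids[indeg == 0L]
  topo <- character(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    cyc <- setdiff(ids, topo)
    stop("cycle detected among is_a edges; involved term: ", cyc[1L])
  }

  anc <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (v in topo) {
    up <- parents[[v]]
    anc[[v]] <- unique(c(up, unlist(anc[up], use.names = FALSE),
                         character(0)))
  }
  desc <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (v in rev(topo)) {
    dn <- children[[v]]
    desc[[v]] <- unique(c(dn, unlist(desc[dn], use.names = FALSE),
                          character(0)))
  }

  structure(
    list(ids = ids,
         name = nm[ids],
         parents = parents[ids],
         children = children[ids],
         roots = ids[lengths(parents[ids]) == 0L],
         ancestors = anc,
         descendants = desc,
         replaced = character(0)),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$ids), "terms,",
      length(x$roots), "root(s),",
      sum(lengths(x$parents)), "is_a edges\n")
  invisible(x)
}

# Map a (possibly obsolete) term id to its live id, or NA if unknown.
resolve_term <- function(graph, id) {
  seen <- character(0)
  while (id %in% names(graph$replaced)) {
    if (id %in% seen) break
    seen <- c(seen, id)
    id <- graph$replaced[[id]]
  }
  if (id %in% graph$ids) id else NA_character_
}

check_term <- function(graph, t) {
  if (!t %in% graph$ids) stop("unknown term id: ", t)
  invisible(t)
}

#' Ancestors of an ontology term
#'
#' All terms reachable from `t` by following `is_a` edges upward, excluding
#' `t` itself.
#'
#' @param graph An `ontology_graph` from [parse_obo()].
#' @param t A term id present in the graph.
#' @return Character vector of term ids (possibly empty).
#' @seealso [descendants()]
#' @export
ancestors <- function(graph, t) {
  check_term(graph, t)
  graph$ancestors[[t]]
}

#' Descendants of an ontology term
#'
#' All terms from which `t` is reachable by `is_a` edges, excluding `t`.
#'
#' @inheritParams ancestors
#' @return Character vector of term ids (possibly empty).
#' @export
descendants <- function(graph, t) {
  check_term(graph, t)
  graph$descendants[[t]]
}

#' Per-term information content from a gene annotation set
#'
#' The information content of a term is
#' \deqn{IC(t) = -\ln( n_{genes}(t) / N_{total} )}
#' where `n_genes(t)` is the number of genes annotated with `t` and
#' `N_total` the number of genes annotated with at least one term. With
#' `propagate = TRUE` (the true-path rule, the default) a gene annotated to a
#' term also counts for all of that term's ancestors, which makes IC
#' monotone non-increasing from leaves to roots. Terms no gene counts for are
#' absent from the returned table. Natural logarithm; the base rescales all
#' scores uniformly and cannot change a rank.
#'
#' @param graph An `ontology_graph`.
#' @param ann An `annotation_set` from [load_gene_annotations()].
#' @param propagate Count genes through the ancestor closure (default `TRUE`).
#' @return Named numeric vector (class `ic_table`): term id -> IC in nats.
#' @export
compute_ic <- function(graph, ann, propagate = TRUE) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(ann, "annotation_set"))
  n_total <- ann$total_annotated_genes
  if (n_total < 1L) stop("no annotated genes")
  counts <- integer(0)
  for (g in names(ann$gene_to_terms)) {
    terms <- ann$gene_to_terms[[g]]
    if (propagate) {
      terms <- unique(c(terms, unlist(graph$ancestors[terms], use.names = FALSE)))
    }
    for (t in terms) {
      counts[t] <- if (t %in% names(counts)) counts[[t]] + 1L else 1L
    }
  }
  ic <- -log(counts / n_total)
  ic <- ic[order(names(ic))]
  structure(ic, class = "ic_table", n_total = n_total)
}

#' Export an IC table as a two-column TSV
#'
#' @param ic An `ic_table` from [compute_ic()].
#' @param path Output path; columns `term_id`, `ic`.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(ic, path) {
  df <- data.frame(term_id = names(ic), ic = as.numeric(ic),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
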
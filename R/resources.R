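# Loaders for the data tables the filters and score consume.

#' Load gene-to-phenotype annotations
#'
#' Reads a TSV of `gene symbol <tab> HPO term id` rows (header optional,
#' auto-detected: a first line whose second column is not a resolvable term
#' id is taken as a header). Duplicate rows collapse; term ids are resolved
#' through
#' the ontology's `replaced_by` map; rows whose term is unknown after
#' resolution are dropped and counted in the load report.
#'
#' @param path TSV file path.
#' @param graph An `ontology_graph`; used to resolve and validate term ids.
#' @return An `annotation_set`: list with `gene_to_terms` (named list of
#'   character vectors, as asserted, no closure), `term_to_genes`
#'   (inverse), `total_annotated_genes`, and `report` (rows read / kept /
#'   dropped).
#' @export
load_gene_annotations <- function(path, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no annotated genes")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop("annotation row with fewer than 2 columns at line ", bad[1L])
  }
  gene <- toupper(trimws(vapply(fields, `[[`, "", 1L)))
  term <- trimws(vapply(fields, `[[`, "", 2L))
  # header row: the first line's second column is not a resolvable term id
  if (is.na(resolve_term(graph, term[1L]))) {
    gene <- gene[-1L]
    term <- term[-1L]
  }
  n_read <- length(gene)
  if (n_read == 0L) stop("no annotated genes")

  resolved <- vapply(term, function(t) resolve_term(graph, t), "",
                     USE.NAMES = FALSE)
  keep <- !is.na(resolved)
  n_dropped <- sum(!keep)
  gene <- gene[keep]
  term <- resolved[keep]
  if (length(gene) == 0L) stop("no annotated genes")

  key <- paste(gene, term, sep = "\r")
  dup <- duplicated(key)
  gene <- gene[!dup]
  term <- term[!dup]

  gene_to_terms <- lapply(split(term, gene), function(x) sort(unique(x)))
  term_to_genes <- lapply(split(gene, term), function(x) sort(unique(x)))
  structure(
    list(gene_to_terms = gene_to_terms,
         term_to_genes = term_to_genes,
         total_annotated_genes = length(gene_to_terms),
         report = c(rows_read = n_read,
                    rows_kept = n_read - n_dropped - sum(dup),
                    rows_dropped_unknown_term = n_dropped,
                    rows_dropped_duplicate = sum(dup))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", x$total_annotated_genes, "genes,",
      length(x$term_to_genes), "terms with direct annotations\n")
  invisible(x)
}

#' Load a known-pathogenic variant list
#'
#' Reads a TSV with columns chrom, pos, ref, alt (header auto-detected by a
#' non-numeric pos field). Entries are stored under normalized keys
#' ([normalize_chrom()] + [normalize_allele()]), so membership tests are
#' representation-invariant.
#'
#' @param path TSV path.
#' @return A `known_pathogenic_set`: list with `keys` (character vector of
#'   normalized `chrom:pos:ref:alt` keys).
#' @export
load_known_pathogenic <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "ref", "alt"),
                          colClasses = "character")
  if (nrow(df) > 0L && is_coord_header(df[1L, ])) {
    df <- df[-1L, , drop = FALSE]
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    stop("malformed coordinate in known-pathogenic table at line ",
         which(is.na(pos))[1L])
  }
  structure(
    list(keys = unique(variant_key(df$chrom, pos, df$ref, df$alt))),
    class = "known_pathogenic_set"
  )
}

#' Test variants for known-pathogenic membership
#'
#' @param known A `known_pathogenic_set` (or `NULL`, in which case all
#'   results are `FALSE`).
#' @param chrom,pos,ref,alt Vectors describing variants.
#' @return Logical vector.
#' @export
is_known_pathogenic <- function(known, chrom, pos, ref, alt) {
  if (is.null(known)) return(rep(FALSE, length(pos)))
  variant_key(chrom, pos, ref, alt) %in% known$keys
}

#' Load a population allele-frequency table
#'
#' TSV with columns chrom, pos, ref, alt, AF (header auto-detected). Keys
#' are normalized like the known-pathogenic set; an AF outside \[0, 1\] is a
#' hard error.
#'
#' @param path TSV path.
#' @return A `frequency_table`: named numeric vector AF keyed by normalized
#'   variant key.
#' @export
load_frequencies <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 5L) stop("frequency table needs 5 columns: chrom pos ref alt af")
  names(df)[1:5] <- c("chrom", "pos", "ref", "alt", "af")
  if (nrow(df) > 0L && is_coord_header(df[1L, ])) {
    df <- df[-1L, , drop = FALSE]
  }
  af <- as.numeric(df$af)
  if (anyNA(af) || any(af < 0) || any(af > 1)) {
    stop("allele frequency outside [0,1] at line ",
         which(is.na(af) | af < 0 | af > 1)[1L])
  }
  keys <- variant_key(df$chrom, as.integer(df$pos), df$ref, df$alt)
  structure(stats::setNames(af, keys), class = "frequency_table")
}

# A first row is a header only when it carries recognizable column names,
# never merely because a field fails to parse (that is a hard error).
is_coord_header <- function(row) {
  tolower(row$pos) %in% c("pos", "position", "start") ||
    tolower(row$chrom) %in% c("chrom", "chr", "chromosome", "#chrom")
}

# AF lookup for variant records; NA where the site is absent from the table.
lookup_af <- function(freqs, chrom, pos, ref, alt) {
  if (is.null(freqs)) return(rep(NA_real_, length(pos)))
  unname(unclass(freqs)[variant_key(chrom, pos, ref, alt)])
}

#' Load a gene set (candidate panel or highlight list)
#'
#' Accepts a plain list of symbols (one per line) or a TSV whose first
#' column is the symbol. Symbols are upper-cased. An empty set is a hard
#' error for the `panel_restrict` role (filtering to nothing is never
#' intended) and a warning otherwise.
#'
#' @param path File path.
#' @param role `"panel_restrict"` (the set restricts the analysis) or
#'   `"highlight"` (the set only flags genes in the report).
#' @param name Label for the set; defaults to the file name.
#' @return A `gene_set`: list with `name`, `genes`, `role`.
#' @export
load_gene_set <- function(path, role = c("highlight", "panel_restrict"),
                          name = basename(path)) {
  role <- match.arg(role)
  lines <- readLines(path)
  genes <- toupper(trimws(vapply(strsplit(lines, "\t", fixed = TRUE),
                                 function(x) if (length(x)) x[[1L]] else "",
                                 "")))
  genes <- sort(unique(genes[nzchar(genes)]))
  if (length(genes) == 0L) {
    if (role == "panel_restrict") stop("empty gene set for panel_restrict role: ", path)
    warning("empty gene set: ", path)
  }
  structure(list(name = name, genes = genes, role = role), class = "gene_set")
}

#' Load genomic regions from BED
#'
#' BED3 (chrom, start, end), 0-based half-open; a BED line `1 999 2000`
#' covers 1-based VCF positions 1000..2000. Intervals may overlap.
#'
#' @param path BED file path.
#' @return A `region_set`: data.frame with columns `chrom` (normalized),
#'   `start`, `end`.
#' @export
load_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = normalize_chrom(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end) | out$start >= out$end)) {
    stop("malformed BED interval (need start < end): ", path)
  }
  structure(out, class = c("region_set", "data.frame"))
}

#' Write a region set back to BED3
#'
#' @param regions A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions)[, c("chrom", "start", "end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TRUE for each (chrom, pos) covered by >=1 interval; pos is 1-based.
in_regions <- function(regions, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  out <- logical(length(pos))
  for (i in seq_len(nrow(regions))) {
    out <- out | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  out
}
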
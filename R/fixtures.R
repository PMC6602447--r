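# Deterministic generators for every input the pipeline consumes: a rooted
# phenotype DAG (OBO), gene-term annotations, a synthetic background exome
# VCF with an AF sidecar, candidate panels / regions, and spike-in case
# manifests. Same seed, same bytes.

#' Specification for the synthetic fixture set
#'
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @param n_terms Number of ontology terms (including the root).
#' @param dag_depth Maximum depth of the term DAG.
#' @param n_genes Number of genes; each gets a deterministic locus (contig +
#'   position window), with a few reserved on X and MT so X-linked and
#'   mitochondrial cases exist.
#' @param terms_per_gene Annotated terms per gene (at least 2, so every case
#'   has the two-term minimum a genotype-phenotype training entry needs).
#' @param n_background_variants Records in the background exome VCF.
#' @param n_cases Number of spike-in benchmark cases.
#' @param phenotype_noise Probability that a patient term is replaced by one
#'   of its parents, emulating clinicians describing the same patient at
#'   different levels of generality.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 200L, dag_depth = 6L,
                         n_genes = 150L, terms_per_gene = 4L,
                         n_background_variants = 1500L, n_cases = 50L,
                         phenotype_noise = 0.2) {
  stopifnot(n_terms >= dag_depth, terms_per_gene >= 2L,
            phenotype_noise >= 0, phenotype_noise <= 1,
            n_terms >= 2L, n_genes >= 1L)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 dag_depth = as.integer(dag_depth),
                 n_genes = as.integer(n_genes),
                 terms_per_gene = as.integer(terms_per_gene),
                 n_background_variants = as.integer(n_background_variants),
                 n_cases = as.integer(n_cases),
                 phenotype_noise = phenotype_noise),
            class = "fixture_spec")
}

fx_term_id <- function(i) sprintf("HP:%07d", i)
fx_gene_id <- function(i) sprintf("GENE%04d", i)

# Layered random DAG: term 1 is the root (depth 0); every other term draws
# 1-2 parents among strictly shallower terms.
fx_dag <- function(spec) {
  n <- spec$n_terms
  depth <- integer(n)
  depth[1L] <- 0L
  if (n > 1L) {
    depth[2:n] <- sample(seq_len(spec$dag_depth - 1L), n - 1L, replace = TRUE)
    depth[2:n] <- sort(depth[2:n])  # ids increase with depth
  }
  parents <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    pool <- which(depth < depth[i])
    k <- min(length(pool), sample(1:2, 1L))
    parents[[i]] <- sort(pool[sample.int(length(pool), k)])
  }
  list(depth = depth, parents = parents)
}

#' Generate a synthetic phenotype ontology as OBO
#'
#' A rooted DAG of `n_terms` terms (plus one obsolete term carrying a
#' `replaced_by` pointer, so the resolution path is exercised), written in
#' the OBO 1.2 dialect [parse_obo()] reads.
#'
#' @param spec A [fixture_spec()].
#' @param path Output OBO path.
#' @return `path`, invisibly.
#' @export
make_ontology <- function(spec, path) {
  with_seed(spec$seed, {
    dag <- fx_dag(spec)
    out <- c("format-version: 1.2",
             "ontology: synthetic-phenotype-fixture", "")
    for (i in seq_len(spec$n_terms)) {
      out <- c(out, "[Term]", paste0("id: ", fx_term_id(i)),
               paste0("name: synthetic term ", i))
      for (p in dag$parents[[i]]) {
        out <- c(out, paste0("is_a: ", fx_term_id(p),
                             " ! synthetic term ", p))
      }
      out <- c(out, "")
    }
    # one obsolete term resolving to the root
    out <- c(out, "[Term]", paste0("id: ", fx_term_id(spec$n_terms + 1L)),
             "name: obsolete synthetic term", "is_obsolete: true",
             paste0("replaced_by: ", fx_term_id(1L)), "")
    writeLines(out, path)
  })
  invisible(path)
}

#' Generate synthetic gene-phenotype annotations as TSV
#'
#' Every gene receives `terms_per_gene` distinct non-root terms. The draw is
#' coupled to the ontology generated from the same spec.
#'
#' @inheritParams make_ontology
#' @param path Output TSV path (gene, term).
#' @return `path`, invisibly.
#' @export
make_annotations <- function(spec, path) {
  ann <- fx_annotation_table(spec)
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("gene", "hpo_id"))
  invisible(path)
}

fx_annotation_table <- function(spec) {
  with_seed(spec$seed + 1L, {
    rows <- lapply(seq_len(spec$n_genes), function(g) {
      terms <- sample(2:spec$n_terms, spec$terms_per_gene)
      data.frame(gene = fx_gene_id(g), term = fx_term_id(sort(terms)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Deterministic gene loci: contigs cycle over autosomes with a few genes
# pinned to X and MT; each gene owns a 100 kb window.
fx_gene_loci <- function(spec) {
  n <- spec$n_genes
  contig <- rep(as.character(1:22), length.out = n)
  n_x <- max(2L, n %/% 25L)
  n_mt <- max(2L, n %/% 30L)
  contig[seq_len(n_x)] <- "X"
  contig[seq(n_x + 1L, n_x + n_mt)] <- "MT"
  data.frame(gene = fx_gene_id(seq_len(n)), chrom = contig,
             start = 100000L + (seq_len(n) - 1L) * 100000L,
             stringsAsFactors = FALSE)
}

fx_contig_order <- c(as.character(1:22), "X", "Y", "MT")

#' Generate a synthetic background exome VCF plus AF sidecar
#'
#' `n_background_variants` records spread over the gene loci, with GT/DP
#' FORMAT fields, SnpEff-style `ANN` INFO annotations drawn from the
#' severity-class vocabulary, sorted coordinates, and normalized alleles.
#' About a third of the records appear in the allele-frequency sidecar with
#' a common-polymorphism AF, and a handful with low DP, so the AF and
#' coverage filters have work to do.
#'
#' @inheritParams make_ontology
#' @param vcf_path Output VCF path.
#' @param af_path Output allele-frequency TSV path (chrom, pos, ref, alt, af).
#' @return Invisible list with both paths.
#' @export
make_background_vcf <- function(spec, vcf_path, af_path) {
  with_seed(spec$seed + 2L, {
    loci <- fx_gene_loci(spec)
    n <- spec$n_background_variants
    gi <- sort(sample(seq_len(nrow(loci)), n, replace = TRUE))
    pos <- loci$start[gi] + sample.int(99999L, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    # a few indels
    idx_ins <- sample.int(n, max(1L, n %/% 50L))
    alt[idx_ins] <- paste0(ref[idx_ins], "A")
    effects <- c("missense_variant", "synonymous_variant", "intron_variant",
                 "stop_gained", "frameshift_variant", "splice_donor_variant",
                 "inframe_deletion", "3_prime_UTR_variant")
    eff <- sample(effects, n, replace = TRUE,
                  prob = c(0.35, 0.2, 0.2, 0.05, 0.05, 0.05, 0.05, 0.05))
    gt <- sample(c("0/1", "1/1"), n, replace = TRUE, prob = c(0.7, 0.3))
    hap <- loci$chrom[gi] %in% c("X", "MT")
    gt[hap] <- ifelse(gt[hap] == "1/1", "1", sample(c("0/1", "1"), sum(hap),
                                                    replace = TRUE))
    dp <- 10L + stats::rpois(n, 35L)
    dp[sample.int(n, max(1L, n %/% 40L))] <- sample(1:9, max(1L, n %/% 40L),
                                                    replace = TRUE)

    df <- data.frame(chrom = loci$chrom[gi], pos = pos, ref = ref, alt = alt,
                     gene = loci$gene[gi], effect = eff, gt = gt, dp = dp,
                     stringsAsFactors = FALSE)
    # drop duplicate sites, sort by contig order then position
    df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
    df <- df[order(match(df$chrom, fx_contig_order), df$pos), , drop = FALSE]

    write_vcf(df, vcf_path)

    n_af <- nrow(df) %/% 3L
    af_idx <- sort(sample.int(nrow(df), n_af))
    af <- data.frame(chrom = df$chrom[af_idx], pos = df$pos[af_idx],
                     ref = df$ref[af_idx], alt = df$alt[af_idx],
                     af = round(stats::runif(n_af, 0.02, 0.6), 4),
                     stringsAsFactors = FALSE)
    utils::write.table(af, af_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
  invisible(list(vcf = vcf_path, af = af_path))
}

#' Write variant rows as a minimal single-sample VCF 4.2 file
#'
#' @param df Data.frame with columns chrom, pos, ref, alt, gene, effect, gt,
#'   dp. Gene and effect land in a SnpEff-style `ANN` INFO field.
#' @param path Output path.
#' @param sample_name Sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(df, path, sample_name = "SYNTH01") {
  contigs <- unique(df$chrom)
  contigs <- contigs[order(match(contigs, fx_contig_order))]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phenoprior-fixtures",
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, "100", "PASS",
                paste0("ANN=", df$alt, "|", df$effect, "|MODIFIER|", df$gene),
                "GT:DP", paste0(df$gt, ":", df$dp), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate the spike-in benchmark case manifest
#'
#' Each case picks a causative gene, takes the gene's annotated terms as the
#' patient phenotype, replaces each term by one of its parents with
#' probability `phenotype_noise`, and emits one or two causative variants
#' inside the gene's locus. Cases cycle through inheritance modes: dominant
#' (one het), recessive-homozygous, recessive compound-het (two distinct het
#' variants), mitochondrial (MT gene, hemizygous-style call) and X-linked,
#' matching the genotype the mode expects.
#'
#' @inheritParams make_ontology
#' @param path Output manifest TSV (one row per causative variant; columns
#'   case_id, gene, inheritance, chrom, pos, ref, alt, genotype, terms with
#'   `;`-separated term ids).
#' @return `path`, invisibly.
#' @export
make_cases <- function(spec, path) {
  manifest <- fx_case_table(spec)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fx_case_table <- function(spec) {
  with_seed(spec$seed + 3L, {
    dag <- fx_dag_reseeded(spec)
    ann <- fx_annotation_table(spec)
    loci <- fx_gene_loci(spec)
    gene_terms <- split(ann$term, ann$gene)

    mt_genes <- loci$gene[loci$chrom == "MT"]
    x_genes <- loci$gene[loci$chrom == "X"]
    auto_genes <- loci$gene[!loci$chrom %in% c("X", "MT")]

    modes <- rep(c("dominant", "recessive", "recessive_comphet",
                   "mitochondrial", "x_linked"),
                 length.out = spec$n_cases)
    rows <- vector("list", spec$n_cases)
    for (i in seq_len(spec$n_cases)) {
      mode <- modes[i]
      gene <- switch(mode,
                     mitochondrial = sample(mt_genes, 1L),
                     x_linked = sample(x_genes, 1L),
                     sample(auto_genes, 1L))
      locus <- loci[loci$gene == gene, ]
      terms <- gene_terms[[gene]]
      noised <- vapply(terms, function(t) {
        if (stats::runif(1) < spec$phenotype_noise) {
          ti <- as.integer(sub("HP:", "", t))
          p <- dag$parents[[ti]]
          if (length(p) > 0L) return(fx_term_id(sample_one(p)))
        }
        t
      }, "", USE.NAMES = FALSE)
      noised <- unique(noised)
      # two terms can noise onto the same parent; keep >= 2 patient terms
      if (length(noised) < 2L) {
        noised <- unique(c(noised, terms))[seq_len(2L)]
      }

      n_var <- if (mode == "recessive_comphet") 2L else 1L
      gt <- switch(mode,
                   dominant = "het",
                   recessive = "hom_alt",
                   recessive_comphet = "het",
                   mitochondrial = "hemi",
                   x_linked = "hemi")
      vpos <- locus$start + sample.int(99999L, n_var)
      ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
      inh_mode <- sub("recessive_comphet", "recessive", mode)
      rows[[i]] <- data.frame(
        case_id = sprintf("case%03d", i), gene = gene,
        inheritance = inh_mode, chrom = locus$chrom, pos = vpos,
        ref = ref, alt = alt, genotype = gt,
        effect = sample(c("missense_variant", "stop_gained",
                          "frameshift_variant"), n_var, replace = TRUE),
        terms = paste(noised, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# the DAG as drawn inside make_ontology (same sub-seed)
fx_dag_reseeded <- function(spec) with_seed(spec$seed, fx_dag(spec))

#' Load a benchmark case manifest
#'
#' @param path Manifest TSV written by [make_cases()] (or hand-authored in
#'   the same layout).
#' @return List of `benchmark_case` objects: `case_id`, `gene`,
#'   `inheritance`, `terms`, and `variants` (data.frame chrom / pos / ref /
#'   alt / genotype / effect).
#' @export
load_cases <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  lapply(split(df, df$case_id), function(d) {
    structure(list(case_id = d$case_id[1L], gene = d$gene[1L],
                   inheritance = d$inheritance[1L],
                   terms = strsplit(d$terms[1L], ";", fixed = TRUE)[[1L]],
                   variants = d[, c("chrom", "pos", "ref", "alt",
                                    "genotype", "effect")]),
              class = "benchmark_case")
  })
}

#' Generate the complete fixture set into a directory
#'
#' Writes `ontology.obo`, `annotations.tsv`, `background.vcf`,
#' `frequencies.tsv`, `cases.tsv`, a `regions.bed` covering all gene loci
#' and a `panel.txt` with a third of the genes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths.
#' @export
make_fixtures <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    vcf = file.path(dir, "background.vcf"),
    frequencies = file.path(dir, "frequencies.tsv"),
    cases = file.path(dir, "cases.tsv"),
    regions = file.path(dir, "regions.bed"),
    panel = file.path(dir, "panel.txt")
  )
  make_ontology(spec, paths$ontology)
  make_annotations(spec, paths$annotations)
  make_background_vcf(spec, paths$vcf, paths$frequencies)
  make_cases(spec, paths$cases)

  loci <- fx_gene_loci(spec)
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L,
                    end = loci$start + 100000L)
  bed <- bed[order(match(bed$chrom, fx_contig_order), bed$start), ]
  utils::write.table(bed, paths$regions, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(loci$gene[seq_len(max(1L, nrow(loci) %/% 3L))], paths$panel)
  paths
}
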
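# Single-sample VCF reading, effect classes and the filter chain.

#' Severity classes for predicted variant effects
#'
#' Ordered from most to least severe. Variants are grouped by class for
#' filtering and display; the class never enters the phenotype score.
#'
#' @format Character vector of class names, most severe first.
#' @export
severity_classes <- c("frameshift", "stop_gain", "splice_site", "missense",
                      "inframe_indel", "synonymous", "noncoding_intragenic",
                      "unknown")

# Sequence-Ontology-style effect token -> severity class.
.effect_map <- c(
  frameshift_variant = "frameshift",
  stop_gained = "stop_gain",
  stop_lost = "stop_gain",
  start_lost = "stop_gain",
  splice_acceptor_variant = "splice_site",
  splice_donor_variant = "splice_site",
  splice_region_variant = "splice_site",
  missense_variant = "missense",
  inframe_insertion = "inframe_indel",
  inframe_deletion = "inframe_indel",
  disruptive_inframe_insertion = "inframe_indel",
  disruptive_inframe_deletion = "inframe_indel",
  synonymous_variant = "synonymous",
  stop_retained_variant = "synonymous",
  intron_variant = "noncoding_intragenic",
  `5_prime_UTR_variant` = "noncoding_intragenic",
  `3_prime_UTR_variant` = "noncoding_intragenic",
  non_coding_transcript_exon_variant = "noncoding_intragenic",
  non_coding_transcript_variant = "noncoding_intragenic"
)

#' Map effect annotation tokens to a severity class
#'
#' Total function over Sequence-Ontology-style effect names. A token may
#' combine several effects joined by `&` (as in SnpEff `ANN` fields); the
#' most severe class wins. Unrecognized tokens map to `"unknown"`.
#'
#' @param tokens Character vector of effect tokens.
#' @return Character vector of severity classes (see [severity_classes]).
#' @examples
#' classify_effect(c("stop_gained", "splice_acceptor_variant",
#'                   "intron_variant&missense_variant", "weird_thing"))
#' @export
classify_effect <- function(tokens) {
  vapply(as.character(tokens), function(tok) {
    if (is.na(tok) || !nzchar(tok)) return("unknown")
    parts <- strsplit(tok, "&", fixed = TRUE)[[1L]]
    cls <- .effect_map[parts]
    cls[is.na(cls)] <- "unknown"
    cls[which.min(match(cls, severity_classes))]
  }, "", USE.NAMES = FALSE)
}

# severity comparison helper: rank 1 = most severe
severity_rank <- function(cls) match(cls, severity_classes)

#' Read a single-sample VCF into variant records
#'
#' Parses a VCF 4.x file with exactly one sample. Multi-allelic sites are
#' split into one record per alt allele the sample actually carries; alleles
#' are reduced to their minimal representation. Genotype comes from `GT`
#' (`het`, `hom_alt`, `hemi` for haploid calls on X/Y/MT, `missing` when
#' unparseable), coverage from the `DP` FORMAT field (INFO `DP` as
#' fallback). Gene and effect come from an `ANN` or `CSQ` INFO field when
#' present, else from `effect_table`.
#'
#' @param path VCF path.
#' @param effect_table Optional sidecar TSV with columns chrom, pos, ref,
#'   alt, gene, effect, used when the VCF carries no ANN/CSQ annotation.
#' @return A data.frame of variant records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `effect_class`, `genotype`, `coverage`, `af_db`
#'   (`NA` until [attach_frequencies()]), `known_pathogenic` (`FALSE` until
#'   [attach_known_pathogenic()]).
#' @export
read_vcf <- function(path, effect_table = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_samples <- if (ncol(v@gt) >= 2L) ncol(v@gt) - 1L else 0L
  if (n_samples != 1L) {
    stop("expected exactly one sample in VCF, found ", n_samples)
  }

  gt_raw <- as.character(vcfR::extract.gt(v, element = "GT"))
  dp_raw <- suppressWarnings(
    as.integer(as.character(vcfR::extract.gt(v, element = "DP"))))
  info <- v@fix[, "INFO"]
  if (all(is.na(dp_raw))) {
    m <- regmatches(info, regexec("(?:^|;)DP=([0-9]+)", info))
    dp_info <- suppressWarnings(
      as.integer(vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")))
    dp_raw <- dp_info
  }

  eff_lookup <- NULL
  if (!is.null(effect_table)) {
    # colClasses: a bare T/F allele must stay a string, not become logical
    et <- utils::read.table(effect_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character")
    eff_lookup <- et
    eff_lookup$key <- variant_key(et$chrom, et$pos, et$ref, et$alt)
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- normalize_chrom(fix[i, "CHROM"])
    pos <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])

    gt <- gt_raw[i]
    alleles <- if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
      integer(0)
    } else {
      suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1L]]))
    }
    parse_ok <- length(alleles) > 0L && !anyNA(alleles)

    ann <- parse_ann_field(info[i])

    out <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      if (parse_ok) {
        n_alt <- sum(alleles == j)
        if (n_alt == 0L) next  # sample does not carry this alt
        ploidy <- length(alleles)
        genotype <- if (ploidy == 1L) {
          if (chrom %in% c("X", "Y", "MT")) "hemi" else "hom_alt"
        } else if (n_alt == ploidy) "hom_alt" else "het"
      } else {
        genotype <- "missing"
      }

      gene <- NA_character_; eff <- NA_character_
      if (!is.null(ann)) {
        hit <- ann[ann$alt == alts[j] | is.na(ann$alt), , drop = FALSE]
        if (nrow(hit) == 0L) hit <- ann
        eff <- hit$effect[1L]
        gene <- hit$gene[1L]
      } else if (!is.null(eff_lookup)) {
        k <- variant_key(chrom, pos, ref, alts[j])
        hit <- match(k, eff_lookup$key)
        if (!is.na(hit)) {
          eff <- eff_lookup$effect[hit]
          gene <- eff_lookup$gene[hit]
        }
      }
      norm <- normalize_allele(pos, ref, alts[j])
      out[[j]] <- data.frame(
        chrom = chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
        gene = if (is.na(gene) || !nzchar(gene)) NA_character_ else toupper(gene),
        effect_class = classify_effect(if (is.na(eff)) "" else eff),
        genotype = genotype,
        coverage = dp_raw[i],
        stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rec)) {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), effect_class = character(0),
                      genotype = character(0), coverage = integer(0),
                      stringsAsFactors = FALSE)
  }
  rec$af_db <- NA_real_
  rec$known_pathogenic <- FALSE
  rec <- rec[order(rec$chrom, rec$pos, rec$ref, rec$alt), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# Parse a SnpEff ANN= or VEP CSQ= INFO field into alt/effect/gene rows.
parse_ann_field <- function(info) {
  if (is.na(info)) return(NULL)
  m <- regmatches(info, regexec("(?:^|;)(ANN|CSQ)=([^;]+)", info))[[1L]]
  if (length(m) != 3L) return(NULL)
  entries <- strsplit(m[3L], ",", fixed = TRUE)[[1L]]
  parts <- strsplit(entries, "|", fixed = TRUE)
  if (m[2L] == "ANN") {
    # ANN: Allele|Annotation|Impact|Gene_Name|...
    data.frame(
      alt = toupper(vapply(parts, function(x) x[1L], "")),
      effect = vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", ""),
      gene = vapply(parts, function(x) if (length(x) >= 4L) x[4L] else "", ""),
      stringsAsFactors = FALSE)
  } else {
    # CSQ (VEP default): Allele|Consequence|IMPACT|SYMBOL|...
    data.frame(
      alt = toupper(vapply(parts, function(x) x[1L], "")),
      effect = vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", ""),
      gene = vapply(parts, function(x) if (length(x) >= 4L) x[4L] else "", ""),
      stringsAsFactors = FALSE)
  }
}

#' Attach population allele frequencies to variant records
#'
#' @param records Variant record data.frame from [read_vcf()].
#' @param freqs A `frequency_table` from [load_frequencies()], or `NULL`.
#' @return `records` with the `af_db` column filled (NA where absent).
#' @export
attach_frequencies <- function(records, freqs) {
  records$af_db <- lookup_af(freqs, records$chrom, records$pos,
                             records$ref, records$alt)
  records
}

#' Flag variant records found in a known-pathogenic set
#'
#' @param records Variant record data.frame.
#' @param known A `known_pathogenic_set` or `NULL`.
#' @return `records` with the `known_pathogenic` column filled.
#' @export
attach_known_pathogenic <- function(records, known) {
  records$known_pathogenic <- is_known_pathogenic(
    known, records$chrom, records$pos, records$ref, records$alt)
  records
}

#' Filter configuration for the variant filter chain
#'
#' @param max_af Drop records with database allele frequency strictly above
#'   this value (known-pathogenic records are exempt). `NULL` disables; there
#'   is deliberately no default threshold.
#' @param min_coverage Keep records with read depth `>= min_coverage`;
#'   records with unknown depth are dropped when this is set.
#' @param regions A `region_set` restricting the genomic search space.
#' @param panel A `gene_set` with role `panel_restrict`.
#' @param require_homozygous Keep only `hom_alt` and `hemi` calls.
#' @param min_severity Least severe class to keep (see [severity_classes]).
#' @param inheritance Suspected mode of inheritance applied by
#'   [apply_inheritance()]: `"any"`, `"dominant"`, `"recessive"`,
#'   `"x_linked"` or `"mitochondrial"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_af = NULL, min_coverage = NULL, regions = NULL,
                          panel = NULL, require_homozygous = FALSE,
                          min_severity = NULL,
                          inheritance = c("any", "dominant", "recessive",
                                          "x_linked", "mitochondrial")) {
  inheritance <- match.arg(inheritance)
  if (!is.null(max_af)) stopifnot(max_af >= 0, max_af <= 1)
  if (!is.null(min_severity)) stopifnot(min_severity %in% severity_classes)
  if (!is.null(panel)) stopifnot(inherits(panel, "gene_set"),
                                 panel$role == "panel_restrict")
  structure(list(max_af = max_af, min_coverage = min_coverage,
                 regions = regions, panel = panel,
                 require_homozygous = require_homozygous,
                 min_severity = min_severity, inheritance = inheritance),
            class = "filter_config")
}

#' Apply the record-level filter chain
#'
#' Filters run in a fixed order -- region, panel, coverage, allele
#' frequency, zygosity, severity -- and each record is dropped by the first
#' filter it fails, so the per-filter drop counts plus the kept count always
#' sum to the input size. Known-pathogenic records are exempt from the AF
#' filter: a known disease mutation must not be discarded as a polymorphism.
#'
#' @param records Variant record data.frame.
#' @param cfg A [filter_config()].
#' @param freqs Optional `frequency_table`; attached before filtering.
#' @param known Optional `known_pathogenic_set`; attached before filtering.
#' @return List with `kept` (records data.frame) and `report` (named integer
#'   vector of drop counts per filter plus `kept`).
#' @export
apply_filters <- function(records, cfg, freqs = NULL, known = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!is.null(freqs)) records <- attach_frequencies(records, freqs)
  if (!is.null(known)) records <- attach_known_pathogenic(records, known)

  report <- c(region = 0L, panel = 0L, coverage = 0L, af = 0L,
              zygosity = 0L, severity = 0L, kept = 0L)
  drop_stage <- function(keep, stage) {
    report[stage] <<- report[stage] + sum(!keep)
    records <<- records[keep, , drop = FALSE]
  }

  if (!is.null(cfg$regions)) {
    drop_stage(in_regions(cfg$regions, records$chrom, records$pos), "region")
  }
  if (!is.null(cfg$panel)) {
    drop_stage(!is.na(records$gene) & records$gene %in% cfg$panel$genes,
               "panel")
  }
  if (!is.null(cfg$min_coverage)) {
    drop_stage(!is.na(records$coverage) &
                 records$coverage >= cfg$min_coverage, "coverage")
  }
  if (!is.null(cfg$max_af)) {
    drop_stage(records$known_pathogenic |
                 is.na(records$af_db) | records$af_db <= cfg$max_af, "af")
  }
  if (isTRUE(cfg$require_homozygous)) {
    drop_stage(records$genotype %in% c("hom_alt", "hemi"), "zygosity")
  }
  if (!is.null(cfg$min_severity)) {
    drop_stage(severity_rank(records$effect_class) <=
                 severity_rank(cfg$min_severity), "severity")
  }
  report["kept"] <- nrow(records)
  rownames(records) <- NULL
  list(kept = records, report = report)
}

#' Apply mode-of-inheritance logic
#'
#' Runs after all record-level filters (the compound-heterozygote rule
#' depends on which heterozygous records of a gene survived filtering).
#'
#' * `dominant`: any record with a non-missing genotype passes.
#' * `recessive`: `hom_alt` passes; a `het` record passes only if its gene
#'   holds at least two distinct heterozygous records (a compound-het
#'   surrogate -- no phasing, no trio check).
#' * `x_linked`: only X-chromosome records; `hemi` and `hom_alt` pass, `het`
#'   only when `allow_het_x = TRUE` (carrier mothers / de novo dominant X).
#' * `mitochondrial`: only MT records.
#' * `any`: no-op.
#'
#' @param records Variant record data.frame (post-filtering).
#' @param mode One of `"any"`, `"dominant"`, `"recessive"`, `"x_linked"`,
#'   `"mitochondrial"`.
#' @param allow_het_x Keep heterozygous X records in `x_linked` mode.
#' @return The kept records.
#' @export
apply_inheritance <- function(records, mode = c("any", "dominant", "recessive",
                                                "x_linked", "mitochondrial"),
                              allow_het_x = TRUE) {
  mode <- match.arg(mode)
  if (mode == "any" || nrow(records) == 0L) return(records)
  keep <- switch(
    mode,
    dominant = records$genotype != "missing",
    recessive = {
      het <- records$genotype == "het"
      key <- paste(records$pos, records$ref, records$alt)
      n_het <- vapply(seq_len(nrow(records)), function(i) {
        if (!het[i] || is.na(records$gene[i])) return(0L)
        same <- het & !is.na(records$gene) & records$gene == records$gene[i]
        length(unique(key[same]))
      }, 0L)
      records$genotype == "hom_alt" | (het & n_het >= 2L)
    },
    x_linked = records$chrom == "X" &
      (records$genotype %in% c("hemi", "hom_alt") |
         (allow_het_x & records$genotype == "het")),
    mitochondrial = records$chrom == "MT"
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variant records as TSV
#'
#' @param records Variant record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
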
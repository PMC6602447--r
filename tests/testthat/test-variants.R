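# VCF reading, effect classification, the filter chain and inheritance.

write_test_vcf <- function(lines, samples = "S1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>", "##contig=<ID=X>", "##contig=<ID=MT>",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), path)
  path
}

test_that("GT/DP parsing, hemizygous convention and multi-allelic split", {
  vcf <- write_test_vcf(c(
    "1\t100\t.\tA\tT\t50\tPASS\tANN=T|missense_variant|MOD|G1\tGT:DP\t0/1:35",
    "1\t200\t.\tC\tG\t50\tPASS\tANN=G|stop_gained|MOD|G2\tGT:DP\t1/1:20",
    "1\t300\t.\tA\tT,G\t50\tPASS\tANN=T|missense_variant|MOD|G3,G|synonymous_variant|MOD|G3\tGT:DP\t1/2:40",
    "X\t400\t.\tG\tA\t50\tPASS\tANN=A|missense_variant|MOD|G4\tGT:DP\t1:30",
    "1\t500\t.\tT\tC\t50\tPASS\tANN=C|intron_variant|MOD|G5\tGT:DP\t.:10"))
  rec <- read_vcf(vcf)
  expect_equal(nrow(rec), 6L)  # 4 plain sites + the multi-allelic site split

  r100 <- rec[rec$pos == 100, ]
  expect_equal(r100$genotype, "het")
  expect_equal(r100$coverage, 35L)
  expect_equal(r100$gene, "G1")
  expect_equal(r100$effect_class, "missense")

  expect_equal(rec[rec$pos == 200, ]$genotype, "hom_alt")
  split_recs <- rec[rec$pos == 300, ]
  expect_equal(nrow(split_recs), 2L)
  expect_setequal(split_recs$alt, c("T", "G"))
  expect_equal(split_recs$genotype, c("het", "het"))
  expect_equal(rec[rec$chrom == "X", ]$genotype, "hemi")
  expect_equal(rec[rec$pos == 500, ]$genotype, "missing")
})

test_that("a haploid call on an autosome is hom_alt, not hemi", {
  vcf <- write_test_vcf(
    "1\t100\t.\tA\tT\t50\tPASS\tANN=T|missense_variant|MOD|G1\tGT:DP\t1:30")
  expect_equal(read_vcf(vcf)$genotype, "hom_alt")
})

test_that("multi-sample and zero-sample VCFs are rejected", {
  two <- write_test_vcf(
    "1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/1:35\t0/1:20",
    samples = c("S1", "S2"))
  expect_error(read_vcf(two), "one sample")
})

test_that("effect tokens map to severity classes, worst class wins", {
  expect_equal(classify_effect("stop_gained"), "stop_gain")
  expect_equal(classify_effect("splice_acceptor_variant"), "splice_site")
  expect_equal(classify_effect("frameshift_variant"), "frameshift")
  expect_equal(classify_effect("no_such_effect"), "unknown")
  # multiple tokens: the most severe wins
  expect_equal(classify_effect("intron_variant&stop_gained"), "stop_gain")
  expect_equal(classify_effect(c("synonymous_variant",
                                 "missense_variant&splice_donor_variant")),
               c("synonymous", "splice_site"))
})

test_that("a sidecar effect table supplies gene/effect when ANN is absent", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               "1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1"), path)
  et <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tgene\teffect",
               "1\t100\tA\tT\tMYGENE\tframeshift_variant"), et)
  rec <- read_vcf(path, effect_table = et)
  expect_equal(rec$gene, "MYGENE")
  expect_equal(rec$effect_class, "frameshift")
})

test_that("filter chain drops in order and accounts for every record", {
  recs <- toy_records(
    list(af_db = 0.20),                                   # af drop
    list(af_db = 0.20, known_pathogenic = TRUE),          # exempt: kept
    list(coverage = 9L),                                  # coverage drop
    list(genotype = "hom_alt"),
    list(effect_class = "synonymous"))
  cfg <- filter_config(max_af = 0.01, min_coverage = 10,
                       min_severity = "missense")
  out <- apply_filters(recs, cfg)
  expect_equal(unname(out$report["af"]), 1L)
  expect_equal(unname(out$report["coverage"]), 1L)
  expect_equal(unname(out$report["severity"]), 1L)
  expect_equal(unname(out$report["kept"]), 2L)
  expect_true(any(out$kept$known_pathogenic))  # AF exemption rule held
  # accounting: kept + sum of drops = input
  expect_equal(sum(out$report), nrow(recs) + 0L)

  # boundary: DP exactly at min_coverage is kept
  b <- apply_filters(toy_records(list(coverage = 10L)),
                     filter_config(min_coverage = 10))
  expect_equal(unname(b$report["kept"]), 1L)
})

test_that("region and panel filters restrict by locus and symbol", {
  bed <- tempfile(); writeLines("1\t999\t2000", bed)
  regions <- load_regions(bed)
  recs <- toy_records(list(pos = 1000L), list(pos = 2500L),
                      list(pos = 1500L, gene = "OTHER"))
  cfg <- filter_config(regions = regions)
  expect_equal(unname(apply_filters(recs, cfg)$report["region"]), 1L)

  panel <- tempfile(); writeLines("GENE1", panel)
  cfg2 <- filter_config(panel = load_gene_set(panel, "panel_restrict"))
  out2 <- apply_filters(recs, cfg2)
  expect_equal(unname(out2$report["panel"]), 1L)
  expect_true(all(out2$kept$gene == "GENE1"))
})

test_that("zygosity filter keeps hom_alt and hemi only", {
  recs <- toy_records(list(genotype = "het"), list(genotype = "hom_alt"),
                      list(genotype = "hemi", chrom = "X"))
  out <- apply_filters(recs, filter_config(require_homozygous = TRUE))
  expect_setequal(out$kept$genotype, c("hom_alt", "hemi"))
})

test_that("filter accounting holds on random record sets", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    recs <- data.frame(
      chrom = sample(c("1", "2", "X", "MT"), n, replace = TRUE),
      pos = sample.int(5000L, n), ref = "A", alt = "T",
      gene = sample(c("G1", "G2", NA), n, replace = TRUE),
      effect_class = sample(severity_classes, n, replace = TRUE),
      genotype = sample(c("het", "hom_alt", "missing"), n, replace = TRUE),
      coverage = sample(c(NA, 5:50), n, replace = TRUE),
      af_db = ifelse(runif(n) < 0.4, runif(n), NA),
      known_pathogenic = runif(n) < 0.1, stringsAsFactors = FALSE)
    cfg <- filter_config(max_af = 0.05, min_coverage = 10,
                         require_homozygous = sample(c(TRUE, FALSE), 1),
                         min_severity = sample(severity_classes, 1))
    out <- apply_filters(recs, cfg)
    expect_equal(sum(out$report), n)
    # monotone: adding a filter never increases the kept set
    out_fewer <- apply_filters(recs, filter_config(max_af = 0.05))
    expect_lte(nrow(out$kept), nrow(out_fewer$kept))
  }
})

test_that("inheritance logic follows the mode table", {
  recs <- data.frame(
    chrom = c("1", "1", "1", "2", "X", "X", "MT", "3"),
    pos = c(1, 2, 3, 4, 5, 6, 7, 8) * 100L,
    ref = "A", alt = "T",
    gene = c("CH", "CH", "SINGLE", "HOM", "XG", "XG", "MTG", "MISS"),
    effect_class = "missense",
    genotype = c("het", "het", "het", "hom_alt", "hemi", "het", "hemi",
                 "missing"),
    coverage = 30L, af_db = NA_real_, known_pathogenic = FALSE,
    stringsAsFactors = FALSE)

  dom <- apply_inheritance(recs, "dominant")
  expect_false("MISS" %in% dom$gene)
  expect_equal(nrow(dom), 7L)

  rec <- apply_inheritance(recs, "recessive")
  expect_setequal(unique(rec$gene), c("CH", "HOM"))  # comp-het + homozygous
  expect_equal(sum(rec$gene == "CH"), 2L)            # both hets kept
  expect_false("SINGLE" %in% rec$gene)               # single het fails

  xl <- apply_inheritance(recs, "x_linked")
  expect_setequal(unique(xl$chrom), "X")
  xl_strict <- apply_inheritance(recs, "x_linked", allow_het_x = FALSE)
  expect_equal(xl_strict$genotype, "hemi")

  mt <- apply_inheritance(recs, "mitochondrial")
  expect_equal(unique(mt$chrom), "MT")   # autosomal records dropped

  expect_identical(apply_inheritance(recs, "any"), recs)
})

test_that("compound-het needs two DISTINCT het sites, not a duplicated one", {
  recs <- data.frame(chrom = "1", pos = c(100L, 100L), ref = "A", alt = "T",
                     gene = "G", effect_class = "missense", genotype = "het",
                     coverage = 30L, af_db = NA_real_,
                     known_pathogenic = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(apply_inheritance(recs, "recessive")), 0L)
})

test_that("record-level filters commute, and comp-het runs after them", {
  set.seed(9)
  recs <- data.frame(
    chrom = "1", pos = seq_len(40) * 10L, ref = "A", alt = "T",
    gene = sample(paste0("G", 1:8), 40, replace = TRUE),
    effect_class = sample(severity_classes, 40, replace = TRUE),
    genotype = sample(c("het", "hom_alt"), 40, replace = TRUE),
    coverage = sample(5:50, 40, replace = TRUE),
    af_db = ifelse(runif(40) < 0.3, runif(40), NA),
    known_pathogenic = FALSE, stringsAsFactors = FALSE)
  cfg_a <- filter_config(max_af = 0.1)
  cfg_b <- filter_config(min_coverage = 15)
  ab <- apply_filters(apply_filters(recs, cfg_a)$kept, cfg_b)$kept
  ba <- apply_filters(apply_filters(recs, cfg_b)$kept, cfg_a)$kept
  expect_identical(ab, ba)

  # compound-het is NOT order independent: a gene with two hets where one
  # fails coverage must lose both under filter-then-inheritance
  ch <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "T",
                   gene = "G", effect_class = "missense", genotype = "het",
                   coverage = c(30L, 5L), af_db = NA_real_,
                   known_pathogenic = FALSE, stringsAsFactors = FALSE)
  cfg <- filter_config(min_coverage = 10)
  filtered_first <- apply_inheritance(apply_filters(ch, cfg)$kept, "recessive")
  expect_equal(nrow(filtered_first), 0L)
  inherit_first <- apply_filters(apply_inheritance(ch, "recessive"), cfg)$kept
  expect_equal(nrow(inherit_first), 1L)  # the wrong order over-keeps
})
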
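Package: phenoprior
Title: Phenotype-Driven Prioritization of Exome Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline engine for phenotype-driven prioritization of variants
    from single-sample exome VCF files. Candidate genes are scored against a
    patient's Human Phenotype Ontology (HPO) terms with an information-content
    based score that weights direct, ancestor and descendant term matches
    differently, after a configurable filter chain (genomic region, candidate
    panel, coverage, population allele frequency, zygosity, predicted-effect
    severity) and mode-of-inheritance logic including a compound-heterozygote
    surrogate. Includes tie-aware competition ranking, spike-in benchmarking
    with top-k cumulative accuracy capped at rank 100, a weight-grid sweep,
    and deterministic synthetic-fixture generators (ontology, gene
    annotations, background exome VCF, case manifests) so everything runs
    without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
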
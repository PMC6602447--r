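---
title: "Phenotype-driven variant prioritization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprior)
```

## The problem

A single exome yields tens of thousands of variants; filtering on allele
frequency, coverage and predicted effect still leaves hundreds of plausible
candidates. For suspected monogenic disease, the patient's phenotype —
expressed as Human Phenotype Ontology (HPO) terms — is the strongest
remaining discriminator: the causative gene is usually a gene whose known
phenotype spectrum resembles the patient's presentation. `phenoprior` turns
that intuition into a score and a ranked gene list, and ships the evaluation
machinery (spike-in benchmarking, a weight-grid sweep) used to justify the
score's default parameters.

## The score

### Information content

For a term $t$, with $n(t)$ the number of genes annotated with $t$ and $N$
the number of genes carrying at least one annotation,

$$IC(t) = -\ln\frac{n(t)}{N}.$$

Rare, specific terms carry high IC; a term annotated to every gene carries
none. Two choices are deliberately fixed here:

* **Propagation (true-path rule), default on.** A gene annotated to a term
  also counts for all the term's ancestors, so interior terms that no curator
  annotates directly still get a finite, well-ordered IC — which is what
  makes ancestor matches scoreable at all. This is standard IC practice for
  ontologies; with propagation, IC is monotone non-increasing from leaves to
  roots, and `compute_ic(..., propagate = FALSE)` remains available for the
  raw counting view.
* **Natural logarithm.** The log base rescales every score by the same
  constant; no rank — the only observable the engine reports — can change.
  Nats are the convention stated in the function documentation and tests.

$N$ is always computed from the annotation file actually loaded, never
assumed: annotation releases differ, and a hard-coded total would silently
skew every IC the day the file changes.

### Matching and weighting

Each patient term contributes once per gene, classified against the gene's
*asserted* annotations (not their closure):

| class | meaning | default weight |
|---|---|---|
| direct | patient term is annotated to the gene | 5 |
| ancestor | patient term is more general than an annotated term | 2 |
| descendant | patient term is more specific than an annotated term | 0.05 |
| none | no path between the terms | 0 |

with precedence direct > ancestor > descendant when several hold via
different gene terms. The gene score is

$$S(g) = \sum_{t \in \text{patient}} w(\text{class}(t,g)) \cdot IC(t),$$

optionally plus an additive bonus when the gene carries a variant from a
known-pathogenic list (weight 0 by default, so benchmark rankings are purely
phenotype-driven, matching how such engines are compared against tools that
have no equivalent bonus).

The asymmetry of the weights encodes a model of phenotyping error: a
clinician describing a patient one level too generally (ancestor) is common
and forgivable; a patient term more specific than anything known about the
gene (descendant) is weak evidence, worth keeping only as a tie-breaker.

Two aggregation choices were genuinely open and are fixed as follows:

* **Sum over patient terms** (not max or mean): accumulating evidence from
  several matched terms is what lets well-phenotyped patients beat sparse
  coincidental overlaps, and makes the score strictly increase when a new
  direct match is added — a property the tests assert.
* **The patient term's IC for all classes** (not the gene-side term's):
  anchoring on the user-entered term keeps a descendant match from exploding
  when the gene carries very specific annotations, and makes contributions
  comparable across genes. Both choices are configuration points at the
  scoring API level and documented there.

Severity classes (frameshift > stop-gain > splice > missense > in-frame
indel > synonymous > non-coding > unknown) group and filter variants but
never enter the score: the engine's variant-effect input is Boolean-ish
class membership, so scoring by class would only re-encode the filter.

### Ranking

Competition ranking: $\text{rank}(g) = 1 + |\{g': S(g') > S(g)\}|$; ties
share a rank, and the next rank skips ("1, 1, 3"). This is conservative for
top-$k$ accuracy (a tie at the top counts every tied gene as rank 1, but a
cluster of 100 ties pushes the next gene to rank 101) and matches how top-k
recovery is normally computed. Within a tie the printed order is
lexicographic, so reports are byte-stable and diffable.

## The filter chain and inheritance logic

Record-level filters run in a fixed order — region, panel, coverage, allele
frequency, zygosity, severity — each record falling to the first filter it
fails, so per-filter drop counts plus the kept count always equal the input
size. Boundaries: depth passes at `DP >= min_coverage` (records with unknown
depth are dropped when the filter is active, since their depth cannot be
verified); the AF filter drops strictly above `max_af`; there is no default
AF threshold — polymorphism stringency is a per-study decision the caller
must make explicitly. Known-pathogenic variants are exempt from the AF
filter: a known disease mutation is something to score, not to discard as a
polymorphism. Variant keys (VCF records, AF table, known-pathogenic list)
are all reduced to minimal representation with normalized contig names
(`chr` prefixes stripped, `M`/`chrMT` to `MT`), so membership tests cannot
be defeated by representation differences.

Mode-of-inheritance logic runs *after* the record-level filters, because the
compound-heterozygote surrogate — a heterozygous record survives recessive
mode only if its gene retains at least two distinct heterozygous records —
must see the post-filter record set (a het whose partner failed coverage is
no longer compound). Without phasing or parental genotypes this over-calls
compound heterozygotes (two variants on the same haplotype are
indistinguishable); that conservative over-call is accepted and documented.
Hemizygous calls (haploid genotypes on X/Y/MT) satisfy the homozygosity
filter, since a single-copy alternate allele is functionally homozygous.

## The synthetic study

The fixture generators exist so that every test and the packaged benchmark
run from a seed with no network. Defaults, chosen once as a desk-scale
analogue of the real setting:

| parameter | default | what it emulates |
|---|---|---|
| `n_terms` | 200 | a phenotype ontology (rooted DAG, depth 6, 1–2 parents/term) |
| `n_genes` | 150 | the annotated gene universe; a few genes pinned to X and MT |
| `terms_per_gene` | 4 | sparse curated annotations |
| `n_background_variants` | 1500 | a filtered background exome with GT/DP and effect annotations |
| `n_cases` | 50 | spike-in cases cycling dominant / recessive / compound-het / mitochondrial / X-linked |
| `phenotype_noise` | 0.2 | a patient term replaced by one of its parents |

The noise model is parent-replacement only: the discrepancy between two
clinicians phenotyping the same patient is overwhelmingly one of generality
and timing, not of wrong organ systems, so injecting random unrelated terms
would test robustness against an error mode the score is not designed for.
About a third of background variants get a common-polymorphism allele
frequency and a handful get low read depth, so the AF and coverage filters
do real work in every benchmark run.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: genes in real annotation sets share terms heavily
(disease families), which compresses score differences; real exomes have
linkage structure and recurrent artifacts; real HPO has 17k+ terms with much
deeper, multi-parent paths. On the synthetic set the default weights solve
every case at rank 1; that is a construction property (independent random
annotations make cross-gene phenotype overlap rare), and the acceptance
threshold (≥90% of cases in the top 10) is deliberately phrased as a
generator-contract check, not a performance claim.

## Benchmarking machinery

`spike_in()` inserts a case's causative variant(s) into the background
(replacing an occupied site, with a message), `evaluate_case()` runs the
full pipeline — filters, the case's inheritance mode, scoring with the
known-pathogenic bonus forced off, competition ranking — and records the
causative gene's rank. Ranks beyond 100, and causative genes absent from
the output, are *not found*; a pipeline error is reported as *errored*,
never conflated with not-found. Cumulative accuracy keeps errored and
not-found cases in the denominator.

`weight_grid_search()` sweeps a 7 × 7 × 5 grid (245 combinations) of
direct/ancestor/descendant weights. The filter chain and each candidate
gene's summed IC per match class are weight-independent, so they are
computed once per case; each combination is then a 3-vector product against
the per-case matrix — algebraically identical to the term-by-term scoring
path, and a test asserts the two routes agree. The sweep reports acc(1),
acc(10), acc(20), acc(100), median rank and unsolved fraction per row,
sorted by acc(10) then unsolved fraction, and deliberately declares no
winner: weight choice trades first-rank sharpness against solve rate, and
that judgement is left to the analyst. The scale-equivariance of the score
(multiplying all three weights by a constant changes no rank) means the grid
effectively explores weight *ratios*; duplicate-statistics rows for scaled
combinations are expected and tested.

## Numerical and degenerate-input choices

* Obsolete ontology terms resolve through `replaced_by` (chains followed,
  cycles detected); obsolete terms without a replacement are dropped with a
  warning, and patient terms that resolve are accepted with a message.
* A cycle among `is_a` edges, or a parent reference to an unknown term, is a
  hard error at parse time — every later guarantee assumes a DAG.
* A patient term with no IC entry (count zero under the chosen propagation
  rule) contributes exactly 0 rather than erroring: an uninformative term
  should not sink an analysis.
* Empty candidate sets, empty ranked lists and empty filter results are
  valid and produce empty (header-only) outputs.
* Multi-allelic sites split per alt allele; split records the sample carries
  zero copies of are dropped (they have no genotype for this sample).
* Loaders treat a first line as a header only when it carries recognizable
  column names; a malformed coordinate is always a hard error with a line
  number, never silently skipped.
* All randomness in the generators flows from the single `seed` field
  through fixed per-file offsets, so one seed yields byte-identical files,
  reports included.

## Problem sizes used in the shipped checks

The test suite exercises: traversal against exhaustive path enumeration on
100 random DAGs of up to 25 nodes; scoring against a brute-force
pair-enumeration oracle on 200 random ontology/annotation/patient triples;
rank laws on random score maps with heavy ties; and the full 50-case
benchmark plus the 245-combination sweep on the default fixture set. These
sizes keep a complete run comfortably in the minutes range on one CPU while
still covering every code path; they are the package's own choice of test
scale.

## Known limitations

* No trio/family logic, no phasing: compound-heterozygote detection
  over-calls cis pairs by design.
* Variant effects are taken from `ANN`/`CSQ` annotations or a sidecar table;
  the package does not predict effects itself.
* One contribution per patient term (best match class); genes with many
  redundant annotations gain nothing from redundancy — intended, but it
  means annotation *depth* is invisible to the score.
* Gene-set inputs (panels, pathway or expression-derived lists) act only as
  filters or highlight flags; their weighting is not statistically
  optimizable with the data the engine consumes, so none is attempted.
* GRCh37-style single-sample VCFs only; structural variants are out of
  scope.
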
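# Spike-in construction, rank bookkeeping, cumulative accuracy, grid sweep.

make_case <- function(case_id = "c1", gene = "G1", chrom = "1",
                      pos = 100L, ref = "A", alt = "T", genotype = "het",
                      effect = "missense_variant", terms, inheritance = "any",
                      n_var = 1L) {
  structure(list(
    case_id = case_id, gene = gene, inheritance = inheritance, terms = terms,
    variants = data.frame(chrom = chrom, pos = pos + (seq_len(n_var) - 1L) * 7L,
                          ref = ref, alt = alt, genotype = genotype,
                          effect = effect, stringsAsFactors = FALSE)),
    class = "benchmark_case")
}

test_that("spike_in inserts, replaces occupied sites, and keeps sort order", {
  bg <- toy_records(list(pos = 100L), list(pos = 200L), list(pos = 300L))
  cs <- make_case(gene = "SPIKED", pos = 250L, terms = "X")
  out <- spike_in(bg, cs)
  expect_equal(nrow(out), 4L)
  expect_true(any(out$gene == "SPIKED" & out$pos == 250L))
  expect_false(is.unsorted(out$pos))
  expect_equal(out$genotype[out$gene == "SPIKED"], "het")

  # occupied site gets replaced, with a message
  cs2 <- make_case(gene = "SPIKED", pos = 200L, terms = "X")
  expect_message(out2 <- spike_in(bg, cs2), "replaced")
  expect_equal(nrow(out2), 3L)
  expect_equal(out2$gene[out2$pos == 200L], "SPIKED")

  # compound-het case inserts both variants
  cs3 <- make_case(gene = "SPIKED", pos = 400L, terms = "X", n_var = 2L)
  expect_equal(sum(spike_in(bg, cs3)$gene == "SPIKED"), 2L)
})

test_that("a uniquely matching causative gene ranks first; ties share rank 1", {
  g <- toy_graph(list(root = character(0), A = "root", B = "root",
                      C = "root"))
  ann <- toy_ann(list(CAUSE = c("A", "B"), OTHER = "C", TWIN = c("A", "B")), g)
  ic <- compute_ic(g, ann)
  bg <- toy_records(list(gene = "OTHER", pos = 500L))
  cs <- make_case(gene = "CAUSE", pos = 100L, terms = c("A", "B"))
  r <- evaluate_case(cs, bg, g, ann, ic)
  expect_equal(r$status, "found")
  expect_equal(r$rank, 1L)

  # add a variant in TWIN (identical annotations): both genes tie at rank 1
  bg2 <- rbind(bg, toy_records(list(gene = "TWIN", pos = 700L)))
  r2 <- evaluate_case(cs, bg2, g, ann, ic)
  expect_equal(r2$rank, 1L)
})

test_that("the cap rule reports not_found beyond rank 100", {
  # 150 background genes all share the patient term; the causative gene has
  # no phenotype overlap, so > 100 genes outscore it
  ids <- c("root", "A", "B")
  g <- toy_graph(stats::setNames(list(character(0), "root", "root"), ids))
  genes <- stats::setNames(rep(list("A"), 150), sprintf("BG%03d", 1:150))
  genes$CAUSE <- "B"
  ann <- toy_ann(genes, g)
  ic <- compute_ic(g, ann)
  bg <- do.call(rbind, lapply(seq_len(150), function(i) {
    data.frame(chrom = "1", pos = i * 10L, ref = "A", alt = "T",
               gene = sprintf("BG%03d", i), effect_class = "missense",
               genotype = "het", coverage = 30L, af_db = NA_real_,
               known_pathogenic = FALSE, stringsAsFactors = FALSE)
  }))
  cs <- make_case(gene = "CAUSE", pos = 5000L, terms = "A")
  r <- evaluate_case(cs, bg, g, ann, ic)
  expect_equal(r$status, "not_found")
  expect_true(is.na(r$rank))
  # sanity: the causative gene's raw competition rank is indeed beyond the cap
  expect_gt(r$n_candidates, phenoprior::RANK_CAP)
})

test_that("a causative gene absent from the kept output is not_found", {
  g <- toy_graph(list(root = character(0), A = "root"))
  ann <- toy_ann(list(CAUSE = "A", OTHER = "A"), g)
  ic <- compute_ic(g, ann)
  bg <- toy_records(list(gene = "OTHER", genotype = "hom_alt", pos = 900L))
  # recessive mode with a single het causative variant: it gets dropped
  cs <- make_case(gene = "CAUSE", pos = 100L, terms = "A",
                  inheritance = "recessive", genotype = "het")
  r <- evaluate_case(cs, bg, g, ann, ic)
  expect_equal(r$status, "not_found")
})

test_that("cumulative accuracy counts hands-on examples and is monotone", {
  res <- data.frame(rank = c(1L, 5L, NA, 2L),
                    status = c("found", "found", "not_found", "found"))
  acc <- cumulative_accuracy(res, c(1, 10, 100))
  expect_equal(unname(acc), c(0.25, 0.75, 0.75))

  all1 <- data.frame(rank = rep(1L, 5), status = "found")
  expect_true(all(cumulative_accuracy(all1, c(1, 50, 100)) == 1))

  # errored cases stay in the denominator
  err <- data.frame(rank = c(1L, NA), status = c("found", "errored"))
  expect_equal(unname(cumulative_accuracy(err, 100)), 0.5)

  expect_error(cumulative_accuracy(res[0, ]), "empty")

  set.seed(77)
  rnd <- data.frame(rank = sample(c(NA, 1:100), 30, replace = TRUE))
  rnd$status <- ifelse(is.na(rnd$rank), "not_found", "found")
  accs <- cumulative_accuracy(rnd, 1:100)
  expect_true(all(diff(accs) >= 0))
})

test_that("the default grid enumerates exactly 245 combinations", {
  grid <- grid_spec()
  expect_equal(nrow(grid), 245L)
  expect_equal(nrow(unique(grid)), 245L)
  expect_equal(nrow(grid_spec(direct = 1, ancestor = 1, descendant = 1)), 1L)
})

test_that("grid sweep matches evaluate_case aggregation for a single combination", {
  fx <- shared_fixtures()
  cases <- fx$cases[1:10]
  res <- run_benchmark(cases, fx$background, fx$graph, fx$ann, fx$ic,
                       weights = weight_config(3, 1, 0.1),
                       cfg = fx$cfg, freqs = fx$freqs)
  acc <- cumulative_accuracy(res, c(1, 10, 20, 100))
  sweep <- weight_grid_search(cases, fx$background, fx$graph, fx$ann, fx$ic,
                              grid = grid_spec(3, 1, 0.1),
                              cfg = fx$cfg, freqs = fx$freqs)
  expect_equal(nrow(sweep), 1L)
  expect_equal(sweep$acc1, unname(acc["1"]))
  expect_equal(sweep$acc10, unname(acc["10"]))
  expect_equal(sweep$acc20, unname(acc["20"]))
  expect_equal(sweep$acc100, unname(acc["100"]))
  expect_equal(sweep$unsolved, mean(res$status != "found"))
})

test_that("scaling all three weights duplicates the sweep row statistics", {
  fx <- shared_fixtures()
  cases <- fx$cases[1:10]
  grid <- grid_spec(direct = c(2, 6), ancestor = c(1, 3),
                    descendant = c(0.5, 1.5))  # second = 3 x first
  sweep <- weight_grid_search(cases, fx$background, fx$graph, fx$ann, fx$ic,
                              grid = grid, cfg = fx$cfg, freqs = fx$freqs)
  a <- sweep[sweep$direct == 2 & sweep$ancestor == 1 & sweep$descendant == 0.5, ]
  b <- sweep[sweep$direct == 6 & sweep$ancestor == 3 & sweep$descendant == 1.5, ]
  expect_equal(a[, c("acc1", "acc10", "acc20", "acc100", "median_rank",
                     "unsolved")],
               b[, c("acc1", "acc10", "acc20", "acc100", "median_rank",
                     "unsolved")],
               ignore_attr = TRUE)
})

test_that("with equal weights the rank depends only on total matched IC", {
  set.seed(88)
  parents <- random_parent_list(20)
  g <- toy_graph(parents)
  genes <- stats::setNames(lapply(1:8, function(i) sample(names(parents), 3)),
                           paste0("G", 1:8))
  ann <- toy_ann(genes, g)
  ic <- compute_ic(g, ann)
  patient <- sample(names(parents), 4)
  w <- weight_config(1, 1, 1)
  # simplified oracle: total IC over patient terms matched in ANY class
  matched_ic <- vapply(names(genes), function(gn) {
    sum(vapply(patient, function(t) {
      cls <- match_class(g, genes[[gn]], t)
      if (cls == "none") 0 else {
        v <- unclass(ic)[t]; if (is.na(v)) 0 else as.numeric(v)
      }
    }, 0))
  }, 0)
  scores <- vapply(names(genes), function(gn) {
    score_gene(g, ic, genes[[gn]], patient, w)$total
  }, 0)
  expect_equal(rank_genes(scores)$rank[match(names(genes),
                                             rank_genes(scores)$gene)],
               unname(vapply(names(genes), function(gn) {
                 oracle_rank(matched_ic, gn)
               }, 0L)))
})
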
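# Toy world: a 4-gene disease module (clique) plus a 20-gene background
# ring, bridged once. The exome carries a spiked novel missense in the
# module's 4th gene and a stronger-scoring decoy variant in a background
# gene far from the module.
toy_world <- function() {
  mods <- utils::combn(sprintf("M%02d", 1:4), 2)
  ring <- sprintf("B%02d B%02d 0.8", 1:20, c(2:20, 1))
  net <- do.call(toy_net, c(
    as.list(sprintf("%s %s 0.9", mods[1, ], mods[2, ])),
    as.list(ring), list("B01 M01 0.75")))
  variants <- mk_variants(
    mk_variant(pos = 10, gene = "M04"),                        # spike: 1 * 0.6
    mk_variant(pos = 20, gene = "B10", mutation_taster = 0.99), # decoy: 0.99
    mk_variant(pos = 30, gene = "B11", mutation_taster = 0.50),
    mk_variant(pos = 40, gene = "B12", maf = 0.005, polyphen = 0.8),
    mk_variant(pos = 50, gene = "B04", effect = "SYNONYMOUS"),
    mk_variant(pos = 60, gene = "B05", maf = 0.08, polyphen = 0.9))
  list(net = net, variants = variants, seeds = sprintf("M%02d", 1:3))
}

test_that("ordinal ranking is descending with alphabetical tie-break", {
  cand <- tibble::tibble(gene = c("G_B", "G_A", "G_C"),
                         exome_walker_score = c(0.5, 0.5, 0.9))
  r <- rank_candidates(cand, "EXOMEWALKER")
  expect_equal(r$gene, c("G_C", "G_A", "G_B"))
  expect_equal(r$rank, 1:3)

  tied <- tibble::tibble(gene = c("Z", "M", "A"), exome_walker_score = 1)
  expect_equal(rank_candidates(tied)$gene, c("A", "M", "Z"))

  one <- tibble::tibble(gene = "X", gene_variant_score = 0.2)
  expect_equal(rank_candidates(one, "VARIANT")$rank, 1L)
})

test_that("ranking matches a stable-sort oracle on randomized tied inputs", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    cand <- tibble::tibble(
      gene = sample(sprintf("G%03d", sample.int(999, n))),
      exome_walker_score = sample(stats::runif(max(2, n %/% 3)), n,
                                  replace = TRUE))
    r <- rank_candidates(cand, "EXOMEWALKER")
    oracle <- cand[order(-cand$exome_walker_score, cand$gene), ]
    expect_equal(r$gene, oracle$gene)
    expect_equal(r$rank, seq_len(n))  # unique consecutive ranks
    # key consistency
    s <- r$exome_walker_score
    for (k in seq_len(n - 1)) {
      expect_true(s[k] > s[k + 1] ||
                    (s[k] == s[k + 1] && r$gene[k] < r$gene[k + 1]))
    }
  }
})

test_that("walk evidence lifts a module gene past a stronger decoy variant", {
  tw <- toy_world()
  model <- default_combiner_model()
  res <- prioritize(tw$variants, network = tw$net, seeds = tw$seeds,
                    model = model)
  expect_equal(res$candidates$gene[res$candidates$rank == 1], "M04")
  expect_equal(res$n_postfilter_genes, 4L)

  by_var <- prioritize(tw$variants, network = tw$net, seeds = tw$seeds,
                       model = model, rank_by = "VARIANT")
  m04_rank <- by_var$candidates$rank[by_var$candidates$gene == "M04"]
  expect_gt(m04_rank, 1L)
  expect_equal(by_var$candidates$gene[by_var$candidates$rank == 1], "B10")
})

test_that("pipeline scores agree with a brute-force recomputation", {
  tw <- toy_world()
  model <- default_combiner_model()
  res <- prioritize(tw$variants, network = tw$net, seeds = tw$seeds,
                    model = model)
  p_oracle <- brute_rwr(tw$net, tw$seeds, r = 0.7)
  pct <- rank(signif(p_oracle, 12), ties.method = "average") / length(p_oracle)
  cand <- res$candidates
  for (k in seq_len(nrow(cand))) {
    g <- cand$gene[k]
    expect_equal(cand$walk_score[k], unname(p_oracle[g]), tolerance = 1e-8)
    expected <- stats::plogis(model$intercept +
                                model$w_variant * cand$gene_variant_score[k] +
                                model$w_walk * pct[g])
    expect_equal(cand$exome_walker_score[k], unname(expected), tolerance = 1e-8)
  }
  # seed interaction evidence: M04 is adjacent to all three seeds
  expect_equal(cand$direct_seed_neighbors[cand$gene == "M04"], 3L)
})

test_that("an exome with no surviving candidates yields a structured empty result", {
  tw <- toy_world()
  empty <- tw$variants[0, ]
  res <- prioritize(empty, network = tw$net, seeds = tw$seeds,
                    model = default_combiner_model())
  expect_s3_class(res, "ranked_result")
  expect_equal(res$n_postfilter_genes, 0L)
  expect_equal(nrow(res$candidates), 0L)

  off_only <- mk_variant(effect = "INTRONIC")
  res2 <- prioritize(off_only, network = tw$net, seeds = tw$seeds,
                     model = default_combiner_model())
  expect_equal(res2$n_postfilter_genes, 0L)
})

test_that("identical inputs produce byte-identical result files", {
  tw <- toy_world()
  model <- default_combiner_model()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_result(prioritize(tw$variants, tw$net, tw$seeds, model = model), f1)
  write_ranked_result(prioritize(tw$variants, tw$net, tw$seeds, model = model), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".json")), readLines(paste0(f2, ".json")))
})

test_that("the pipeline runs end-to-end from files on disk", {
  tw <- toy_world()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  side <- withr::local_tempfile(fileext = ".tsv")
  write_variants(tw$variants, vcf, side)
  seedfile <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# disease-gene family", tw$seeds), seedfile)
  res <- prioritize(vcf, network = tw$net, seeds = seedfile,
                    annotations = side, model = default_combiner_model())
  expect_equal(res$candidates$gene[1], "M04")
})
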
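scored <- function(...) score_variant(mk_variants(...))

test_that("grouping by gene drops unassigned variants with a count", {
  v <- mk_variants(mk_variant(pos = 1, gene = "G1"),
                   mk_variant(pos = 2, gene = "G1"),
                   mk_variant(pos = 3, gene = "G2"),
                   mk_variant(pos = 4, gene = NA_character_))
  expect_message(by_gene <- group_by_gene(v), "1 variant")
  expect_setequal(names(by_gene), c("G1", "G2"))
  expect_equal(nrow(by_gene$G1), 2L)
  expect_length(group_by_gene(v[0, ]), 0L)
  expect_length(suppressMessages(group_by_gene(v[1:2, ])), 1L)
})

test_that("inheritance models gate qualifying variants correctly", {
  one_het <- scored(mk_variant(pos = 1, genotype = "HET"))
  expect_equal(nrow(apply_inheritance(one_het, "AR")), 0L)
  expect_equal(nrow(apply_inheritance(one_het, "AD")), 1L)
  expect_equal(nrow(apply_inheritance(one_het, "NONE")), 1L)

  two_het <- scored(mk_variant(pos = 1), mk_variant(pos = 2))
  expect_equal(nrow(apply_inheritance(two_het, "AR")), 2L)  # compound het

  hom <- scored(mk_variant(pos = 1, genotype = "HOM_ALT"))
  expect_equal(nrow(apply_inheritance(hom, "AR")), 1L)
  expect_equal(nrow(apply_inheritance(hom, "AD")), 1L)
})

test_that("tightening the model never adds candidate genes", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    v <- score_variant(mk_variant(
      pos = seq_len(n),
      genotype = sample(c("HET", "HOM_ALT"), n, replace = TRUE),
      gene = sample(sprintf("G%d", 1:6), n, replace = TRUE),
      effect = "MISSENSE"))
    cand <- function(model) assemble_genes(v, model)$gene
    expect_true(all(cand("AD") %in% cand("NONE")))
    expect_true(all(cand("AR") %in% cand("NONE")))
  }
})

test_that("gene variant score follows best-variant and compound-het rules", {
  v <- scored(mk_variant(pos = 1, mutation_taster = 0.9),
              mk_variant(pos = 2, mutation_taster = 0.4))
  expect_equal(gene_variant_score(v, "NONE"), 0.9)

  ch <- scored(mk_variant(pos = 1, mutation_taster = 0.9),
               mk_variant(pos = 2, mutation_taster = 0.7),
               mk_variant(pos = 3, mutation_taster = 0.2))
  expect_equal(gene_variant_score(apply_inheritance(ch, "AR"), "AR"),
               (0.9 + 0.7) / 2)

  both <- scored(mk_variant(pos = 1, genotype = "HOM_ALT", mutation_taster = 0.95),
                 mk_variant(pos = 2, mutation_taster = 0.9),
                 mk_variant(pos = 3, mutation_taster = 0.7))
  expect_equal(gene_variant_score(apply_inheritance(both, "AR"), "AR"), 0.95)

  weak_hom <- scored(mk_variant(pos = 1, genotype = "HOM_ALT", mutation_taster = 0.5),
                     mk_variant(pos = 2, mutation_taster = 0.9),
                     mk_variant(pos = 3, mutation_taster = 0.7))
  expect_equal(gene_variant_score(apply_inheritance(weak_hom, "AR"), "AR"), 0.8)

  expect_error(gene_variant_score(v[0, ], "NONE"), "no qualifying")
})

test_that("bulk gene assembly matches the per-gene reference route", {
  set.seed(123)
  for (i in 1:8) {
    n <- sample(10:60, 1)
    v <- score_variant(mk_variant(
      pos = seq_len(n),
      genotype = sample(c("HET", "HOM_ALT"), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
      gene = sample(c(sprintf("G%02d", 1:10), NA_character_), n, replace = TRUE),
      effect = "MISSENSE",
      mutation_taster = stats::runif(n)))
    for (model in c("NONE", "AD", "AR")) {
      bulk <- suppressMessages(assemble_genes(v, model))
      ref <- lapply(suppressMessages(group_by_gene(v)), function(gv) {
        q <- apply_inheritance(gv, model)
        if (nrow(q) == 0L) NULL else
          data.frame(n = nrow(q), s = gene_variant_score(q, model))
      })
      ref <- ref[!vapply(ref, is.null, logical(1))]
      expect_setequal(bulk$gene, names(ref))
      ord <- match(bulk$gene, names(ref))
      expect_equal(unname(bulk$gene_variant_score),
                   unname(vapply(ref[ord], `[[`, numeric(1), "s")))
      expect_equal(bulk$n_variants,
                   unname(vapply(ref[ord], function(d) as.integer(d$n),
                                 integer(1))))
    }
  }
})

test_that("gene score stays within the range of its qualifying variant scores", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    v <- score_variant(mk_variant(
      pos = seq_len(n),
      genotype = sample(c("HET", "HOM_ALT"), n, replace = TRUE),
      mutation_taster = stats::runif(n)))
    for (model in c("NONE", "AD", "AR")) {
      q <- apply_inheritance(v, model)
      if (nrow(q) == 0L) next
      s <- gene_variant_score(q, model)
      expect_gte(s, min(q$variant_score) - 1e-12)
      expect_lte(s, max(q$variant_score) + 1e-12)
    }
  }
})
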
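test_that("spike-in inserts one variant with the inheritance-appropriate genotype", {
  cfg <- fixture_config(n_genes = 40, n_modules = 4, module_size = 4,
                        n_background_variants = 100, rng_seed = 6)
  gen <- generate_network(cfg)
  bg <- generate_exome(cfg, gen$network)
  rec_ad <- list(gene = gen$families[[1]][1], family = names(gen$families)[1],
                 chrom = "1", pos = 9500001L, ref = "A", alt = "T",
                 effect = "MISSENSE", moi = "AD")
  sp <- spike_in(bg, rec_ad)
  expect_equal(nrow(sp), nrow(bg) + 1L)
  row <- sp[sp$pos == 9500001L, ]
  expect_equal(row$genotype, "HET")
  expect_false(is.unsorted(order(sp$chrom, sp$pos)))

  rec_ar <- rec_ad; rec_ar$moi <- "AR"
  expect_equal(spike_in(bg, rec_ar)[sp$pos == 9500001L, ]$genotype[1], "HOM_ALT")

  # spiked novel missense survives filtering
  flt <- filter_variants(sp)
  expect_true(9500001L %in% flt$kept$pos)

  clash <- rec_ad; clash$chrom <- bg$chrom[1]; clash$pos <- bg$pos[1]
  expect_error(spike_in(bg, clash), "already present")
})

test_that("a sole surviving spiked gene is recovered as the top hit", {
  cfg <- fixture_config(n_genes = 30, n_modules = 3, module_size = 4,
                        n_background_variants = 40, offtarget_prob = 1,
                        rng_seed = 8)
  gen <- generate_network(cfg)
  bg <- generate_exome(cfg, gen$network)   # all off-target: filtered away
  rec <- data.frame(gene = gen$families[[1]][1], family = names(gen$families)[1],
                    chrom = "1", pos = 9500001L, ref = "A", alt = "T",
                    effect = "MISSENSE", moi = "AD", stringsAsFactors = FALSE)
  res <- run_benchmark(rec, gen$families, list(bg), gen$network,
                       model = default_combiner_model())
  expect_equal(res$n_runs, 1L)
  expect_equal(res$top1, 1)
  expect_equal(res$runs$rank, 1L)
  expect_equal(res$runs$n_postfilter, 1L)
})

test_that("benchmark aggregates are exact fractions with top-k monotonicity", {
  cfg <- fixture_config(n_genes = 80, n_modules = 6, module_size = 4,
                        n_background_variants = 200, rng_seed = 9)
  gen <- generate_network(cfg)
  backgrounds <- lapply(11:12, function(s) generate_exome(cfg, gen$network,
                                                          seed = s))
  records <- make_spikein_catalogue(gen$families, seed = 10)
  res <- run_benchmark(records, gen$families, backgrounds, gen$network,
                       model = default_combiner_model())
  expect_equal(res$n_runs, nrow(records) * 2L)
  for (cut in c(1, 10, 50)) {
    frac <- sum(!is.na(res$runs$rank) & res$runs$rank <= cut) / res$n_runs
    expect_identical(res[[paste0("top", cut)]], frac)
  }
  expect_lte(res$top1, res$top10)
  expect_lte(res$top10, res$top50)

  res2 <- run_benchmark(records, gen$families, backgrounds, gen$network,
                        model = default_combiner_model())
  expect_identical(res$runs, res2$runs)  # deterministic
})

test_that("leave-one-out seeding never lets the spiked gene seed its own run", {
  cfg <- fixture_config(n_genes = 40, n_modules = 2, module_size = 4,
                        n_background_variants = 60, rng_seed = 13)
  gen <- generate_network(cfg)
  bg <- generate_exome(cfg, gen$network)
  rec <- make_spikein_catalogue(gen$families, seed = 14)[1, ]
  seeds_used <- setdiff(gen$families[[rec$family]], rec$gene)
  expect_false(rec$gene %in% seeds_used)
  expect_gte(length(seeds_used), 3L)
  # and the run still ranks the gene (it is a candidate, not a seed)
  res <- run_benchmark(rec, gen$families, list(bg), gen$network,
                       model = default_combiner_model())
  expect_false(is.na(res$runs$rank))
})

test_that("families and spike-in catalogues round-trip through their file dialects", {
  fams <- list(FAM1 = c("G1", "G2", "G3"), FAM2 = c("G4", "G5"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_families(fams, f)
  expect_identical(read_families(f), fams)

  cat_df <- make_spikein_catalogue(fams, seed = 2)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_spikein_catalogue(cat_df, g)
  back <- read_spikein_catalogue(g)
  expect_identical(back$gene, cat_df$gene)
  expect_identical(as.integer(back$pos), cat_df$pos)
  expect_identical(back$moi, cat_df$moi)
})

test_that("benchmark results serialize to per-run TSV plus JSON summary", {
  cfg <- fixture_config(n_genes = 30, n_modules = 2, module_size = 4,
                        n_background_variants = 50, rng_seed = 21)
  gen <- generate_network(cfg)
  res <- run_benchmark(make_spikein_catalogue(gen$families, seed = 3)[1, ],
                       gen$families, list(generate_exome(cfg, gen$network)),
                       gen$network, model = default_combiner_model())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_result(res, f)
  expect_true(file.exists(f))
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$n_runs, res$n_runs)
  expect_equal(js$top1, res$top1)
})
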
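# Deterministic synthetic-data generators: planted-module PPA networks
# (each planted module is a disease-gene family), background exomes with
# realistic MAF/pathogenicity mixtures, and labeled variant sets for
# training the fusion model. Every generator is a pure function of its
# config + seed, so the whole pipeline is testable with no downloads.

#' Fixture generator configuration
#'
#' @param n_genes total genes in the synthetic network (default 300).
#' @param n_modules number of planted dense modules, each a disease-gene
#'   family (default 20).
#' @param module_size genes per module (default 5; families of >= 4 keep
#'   leave-one-out seed sets non-trivial).
#' @param intra_module_edge_prob probability of each within-module
#'   association beyond the guaranteed spanning cycle (default 0.8).
#' @param background_edge_prob probability of each background association
#'   between any gene pair (default 0.01).
#' @param n_background_variants variants per synthetic exome (default 1000).
#' @param maf_absent_prob,maf_common_prob fractions of variants with no
#'   population frequency and with a common (> 1%) frequency; the
#'   remainder are rare (uniform on \[0, 0.01\]). Defaults 0.4 / 0.2.
#' @param offtarget_prob fraction of off-target variants (synonymous,
#'   intronic, intergenic, UTR, non-coding), default 0.3.
#' @param prediction_missing_prob per-tool probability that a missense
#'   prediction is unavailable (default 0.3).
#' @param offnetwork_gene_frac fraction of coding variants assigned to
#'   genes absent from the network (default 0.05).
#' @param rng_seed default RNG seed for the generators.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 300L, n_modules = 20L, module_size = 5L,
                           intra_module_edge_prob = 0.8,
                           background_edge_prob = 0.01,
                           n_background_variants = 1000L,
                           maf_absent_prob = 0.4, maf_common_prob = 0.2,
                           offtarget_prob = 0.3,
                           prediction_missing_prob = 0.3,
                           offnetwork_gene_frac = 0.05,
                           rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              intra_module_edge_prob = intra_module_edge_prob,
              background_edge_prob = background_edge_prob,
              n_background_variants = as.integer(n_background_variants),
              maf_absent_prob = maf_absent_prob,
              maf_common_prob = maf_common_prob,
              offtarget_prob = offtarget_prob,
              prediction_missing_prob = prediction_missing_prob,
              offnetwork_gene_frac = offnetwork_gene_frac,
              rng_seed = as.integer(rng_seed))
  probs <- c(cfg$intra_module_edge_prob, cfg$background_edge_prob,
             cfg$maf_absent_prob, cfg$maf_common_prob, cfg$offtarget_prob,
             cfg$prediction_missing_prob, cfg$offnetwork_gene_frac)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$maf_absent_prob + cfg$maf_common_prob <= 1,
            cfg$n_genes >= 1L, cfg$module_size >= 2L,
            cfg$n_background_variants >= 0L)
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    stop("infeasible config: planted modules need more genes than n_genes",
         call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate a planted-module PPA network with its disease-gene families
#'
#' Builds a random network in which each planted module is a dense gene
#' cluster standing in for a disease-gene family (the core assumption the
#' walk exploits: family genes associate in specific subnetworks). Every
#' module carries a guaranteed spanning cycle (confidence >= 0.75) plus
#' random intra-module edges; background edges are sampled uniformly over
#' all pairs with confidences straddling the 0.7 threshold so that
#' confidence filtering is exercised. Components left disconnected after
#' filtering are joined by deterministic bridge edges.
#'
#' @param cfg a [fixture_config()].
#' @param seed RNG seed (default `cfg$rng_seed`).
#' @return list with `network` (a `ppa_network`) and `families` (named
#'   list of gene-ID vectors, one per planted module).
#' @export
generate_network <- function(cfg = fixture_config(), seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    module_of <- split(genes[seq_len(cfg$n_modules * cfg$module_size)],
                       rep(seq_len(cfg$n_modules), each = cfg$module_size))
    names(module_of) <- sprintf("FAM%02d", seq_len(cfg$n_modules))

    ea <- character(0); eb <- character(0); conf <- numeric(0)
    for (mod in module_of) {
      k <- length(mod)
      # spanning cycle keeps every family member attached at high confidence
      ca <- mod; cb <- mod[c(2:k, 1L)]
      ea <- c(ea, ca); eb <- c(eb, cb)
      conf <- c(conf, stats::runif(k, 0.75, 0.99))
      extra <- utils::combn(mod, 2L)
      not_cycle <- !(paste(pmin(extra[1L, ], extra[2L, ]),
                           pmax(extra[1L, ], extra[2L, ])) %in%
                       paste(pmin(ca, cb), pmax(ca, cb)))
      pick <- not_cycle & stats::runif(ncol(extra)) < cfg$intra_module_edge_prob
      ea <- c(ea, extra[1L, pick]); eb <- c(eb, extra[2L, pick])
      conf <- c(conf, stats::runif(sum(pick), 0.75, 0.99))
    }
    pairs <- utils::combn(genes, 2L)
    pick <- stats::runif(ncol(pairs)) < cfg$background_edge_prob
    ea <- c(ea, pairs[1L, pick]); eb <- c(eb, pairs[2L, pick])
    conf <- c(conf, stats::runif(sum(pick), 0.5, 0.95))

    net <- ppa_network(data.frame(gene_a = ea, gene_b = eb, confidence = conf,
                                  stringsAsFactors = FALSE),
                       min_confidence = 0.7)
    # deterministically bridge any disconnected components
    repeat {
      g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                         vertices = net$genes)
      comp <- igraph::components(g)
      if (comp$no == 1L) break
      anchors <- vapply(seq_len(comp$no), function(cc)
        sort(net$genes[comp$membership == cc])[1L], character(1))
      bridges <- data.frame(gene_a = anchors[1L], gene_b = anchors[-1L],
                            confidence = 0.8, stringsAsFactors = FALSE)
      net <- ppa_network(rbind(net$edges, bridges), min_confidence = 0.7)
    }
    families <- lapply(module_of, function(mod) intersect(mod, net$genes))
    list(network = net, families = families)
  })
}

#' Generate a synthetic background exome
#'
#' Draws background variants over the network's genes: effect classes at
#' the configured on-/off-target proportions, MAFs from a
#' common/rare/absent mixture, the three pathogenicity predictions for
#' missense variants correlated through a latent deleteriousness (with
#' per-tool dropout), genotypes mostly heterozygous. Optionally writes
#' the exome as a plain-text VCF v4.2 plus annotation sidecar.
#'
#' @param cfg a [fixture_config()].
#' @param network the `ppa_network` the exome's genes are drawn from.
#' @param seed RNG seed (default `cfg$rng_seed`).
#' @param vcf_path,sidecar_path optional output paths (see
#'   [write_variants()]).
#' @return annotated variant tibble, coordinate-sorted.
#' @export
generate_exome <- function(cfg = fixture_config(), network, seed = cfg$rng_seed,
                           vcf_path = NULL, sidecar_path = NULL) {
  stopifnot(inherits(cfg, "fixture_config"), inherits(network, "ppa_network"))
  n <- cfg$n_background_variants
  with_seed(seed, {
    off <- stats::runif(n) < cfg$offtarget_prob
    effect <- character(n)
    effect[off] <- sample(ew_offtarget_classes, sum(off), replace = TRUE)
    effect[!off] <- sample(c("MISSENSE", "NONSENSE", "FRAMESHIFT",
                             "SPLICE_SITE", "INFRAME_INDEL"),
                           sum(!off), replace = TRUE,
                           prob = c(0.85, 0.05, 0.04, 0.03, 0.03))
    gene <- rep(NA_character_, n)
    coding <- effect != "INTERGENIC"
    offnet <- coding & stats::runif(n) < cfg$offnetwork_gene_frac
    gene[coding & !offnet] <- sample(network$genes, sum(coding & !offnet),
                                     replace = TRUE)
    gene[offnet] <- sprintf("OFFNET%02d", sample.int(20L, sum(offnet),
                                                     replace = TRUE))
    maf_class <- sample(c("ABSENT", "COMMON", "RARE"), n, replace = TRUE,
                        prob = c(cfg$maf_absent_prob, cfg$maf_common_prob,
                                 1 - cfg$maf_absent_prob - cfg$maf_common_prob))
    maf <- rep(NA_real_, n)
    maf[maf_class == "COMMON"] <- stats::runif(sum(maf_class == "COMMON"),
                                               0.011, 0.2)
    maf[maf_class == "RARE"] <- stats::runif(sum(maf_class == "RARE"), 0, 0.01)

    clamp01 <- function(x) pmin(1, pmax(0, x))
    sift <- polyphen <- mt <- rep(NA_real_, n)
    mis <- effect == "MISSENSE"
    nm <- sum(mis)
    if (nm > 0L) {
      d <- stats::rbeta(nm, 2, 2)  # latent deleteriousness
      sift[mis] <- clamp01(1 - d + stats::rnorm(nm, 0, 0.15))
      polyphen[mis] <- clamp01(d + stats::rnorm(nm, 0, 0.15))
      mt[mis] <- clamp01(d + stats::rnorm(nm, 0, 0.15))
      for (col in c("sift", "polyphen", "mt")) {
        drop <- mis & stats::runif(n) < cfg$prediction_missing_prob
        if (col == "sift") sift[drop] <- NA_real_
        if (col == "polyphen") polyphen[drop] <- NA_real_
        if (col == "mt") mt[drop] <- NA_real_
      }
    }
    genotype <- sample(c("HET", "HOM_ALT", "HOM_REF", "MISSING"), n,
                       replace = TRUE, prob = c(0.80, 0.12, 0.05, 0.03))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    pos <- sample.int(9000000L, n)  # globally unique => unique per chromosome
    chrom <- as.character(sample.int(22L, n, replace = TRUE))

    v <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                        genotype = genotype, gene = gene, effect = effect,
                        maf = maf, sift = sift, polyphen = polyphen,
                        mutation_taster = mt)
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), ]
    if (!is.null(vcf_path)) write_variants(v, vcf_path, sidecar_path)
    v
  })
}

#' Analytic post-filter retention expectation for a generated exome
#'
#' The probability that a generated background variant survives
#' [filter_variants()]: on-target effect, known MAF not above 1% (common
#' draws always exceed it; rare and absent draws always pass), and an
#' alternate-carrying genotype.
#'
#' @param cfg a [fixture_config()].
#' @return expected kept fraction in \[0,1\].
#' @export
expected_retention <- function(cfg) {
  p_genotype <- 0.80 + 0.12  # HET + HOM_ALT generator weights
  (1 - cfg$offtarget_prob) * (1 - cfg$maf_common_prob) * p_genotype
}

#' Generate labeled examples for training the score-fusion model
#'
#' Surrogate for a catalogue of known disease variants versus benign
#' ones: disease examples draw stochastically higher variant scores and
#' walk percentiles than benign examples, with class separation
#' controlled by `effect_size` (0 = class-blind features, AUC 0.5; large
#' values approach separability). Features are independent given the
#' label. Walk scores are on the percentile scale in \[0,1\].
#'
#' @param n_pos,n_neg number of disease / benign examples.
#' @param effect_size separation parameter >= 0 (default 1).
#' @param seed RNG seed.
#' @return tibble with `variant_score`, `walk_score`, `label`.
#' @export
generate_labeled_variants <- function(n_pos, n_neg, effect_size = 1, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, effect_size >= 0)
  with_seed(seed, {
    a <- 1 + 2 * effect_size
    tibble::tibble(
      variant_score = c(stats::rbeta(n_pos, a, 1), stats::rbeta(n_neg, 1, a)),
      walk_score = c(stats::rbeta(n_pos, a, 1), stats::rbeta(n_neg, 1, a)),
      label = rep(c("DISEASE", "BENIGN"), c(n_pos, n_neg)))
  })
}

#' Build a spike-in catalogue over planted families
#'
#' Picks one target gene per family (uniformly at random under the seed)
#' and a fresh locus outside the background coordinate range, alternating
#' dominant and recessive inheritance across records. Spiked variants
#' emulate catalogued disease mutations: novel (no population frequency)
#' missense changes with a strongly deleterious MutationTaster prediction
#' (uniform on \[0.9, 1\]).
#'
#' @param families named list of gene-ID vectors.
#' @param seed RNG seed.
#' @return data.frame of spike-in records (`gene family chrom pos ref alt
#'   effect moi`).
#' @export
make_spikein_catalogue <- function(families, seed = 1L) {
  stopifnot(length(families) >= 1L)
  small <- names(families)[lengths(families) < 2L]
  if (length(small) > 0L) {
    stop("families too small for leave-one-out seeding: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    gene <- vapply(families, function(f) sample(f, 1L), character(1))
    n <- length(families)
    data.frame(gene = unname(gene), family = names(families),
               chrom = "1", pos = 9500000L + seq_len(n),
               ref = "A", alt = "T", effect = "MISSENSE",
               moi = rep_len(c("AD", "AR"), n),
               mutation_taster = stats::runif(n, 0.9, 1),
               stringsAsFactors = FALSE)
  })
}

#' Write / read a families file (`family<TAB>gene1,gene2,...`)
#'
#' @param families named list of gene-ID vectors.
#' @param path file path.
#' @export
write_families <- function(families, path) {
  writeLines(sprintf("%s\t%s", names(families),
                     vapply(families, paste, character(1), collapse = ",")),
             path)
  invisible(path)
}

#' @rdname write_families
#' @param catalogue data.frame of spike-in records.
#' @export
write_spikein_catalogue <- function(catalogue, path) {
  utils::write.table(catalogue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
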
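# Shared test builders and independent oracles.

# Build a tiny network from strings like "A B 0.9".
toy_net <- function(..., min_confidence = 0.7) {
  rows <- strsplit(c(...), "[ \t]+")
  ppa_network(data.frame(
    gene_a = vapply(rows, `[`, character(1), 1L),
    gene_b = vapply(rows, `[`, character(1), 2L),
    confidence = as.numeric(vapply(rows, `[`, character(1), 3L)),
    stringsAsFactors = FALSE), min_confidence = min_confidence)
}

mk_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                       genotype = "HET", gene = "G1", effect = "MISSENSE",
                       maf = NA_real_, sift = NA_real_, polyphen = NA_real_,
                       mutation_taster = NA_real_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 genotype = genotype, gene = gene, effect = effect,
                 maf = maf, sift = sift, polyphen = polyphen,
                 mutation_taster = mutation_taster)
}

mk_variants <- function(...) do.call(rbind, list(...))

# Random connected network: G(n, p) plus a spanning path so no node is
# isolated and the graph is connected; all confidences above threshold.
rand_connected_net <- function(n, p = 0.1) {
  genes <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(genes, 2L)
  pick <- stats::runif(ncol(pairs)) < p
  ea <- c(pairs[1L, pick], genes[-n])
  eb <- c(pairs[2L, pick], genes[-1L])
  ppa_network(data.frame(gene_a = ea, gene_b = eb,
                         confidence = stats::runif(length(ea), 0.7, 1),
                         stringsAsFactors = FALSE))
}

# Independent RWR oracle: plain base-R power iteration built from the
# network's edge table, bypassing the package's matrix machinery.
brute_rwr <- function(net, seed_genes, r = 0.7, iters = 500L) {
  genes <- net$genes
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[k]; b <- net$edges$gene_b[k]
    A[a, b] <- 1; A[b, a] <- 1
  }
  W <- sweep(A, 2L, colSums(A), "/")
  p0 <- setNames(numeric(n), genes)
  p0[seed_genes] <- 1 / length(seed_genes)
  p <- p0
  for (t in seq_len(iters)) p <- (1 - r) * (W %*% p)[, 1L] + r * p0
  p
}

# Deterministic seed-column sum check helper used in several places.
linf <- function(a, b) max(abs(a - b))
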
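# Grouping scored variants into gene-level candidates under a
# mode-of-inheritance (MOI) model.

ew_inheritance_models <- c("NONE", "AD", "AR")

#' Group variants by gene
#'
#' Variants lacking a gene assignment (e.g. intergenic calls that slipped
#' through) are dropped with a message reporting the count; per-gene
#' variant order is preserved.
#'
#' @param variants scored variant tibble.
#' @return named list of per-gene tibbles.
#' @export
group_by_gene <- function(variants) {
  has_gene <- !is.na(variants$gene) & nzchar(variants$gene)
  n_drop <- sum(!has_gene)
  if (n_drop > 0L) {
    message(sprintf("dropping %d variant(s) without a gene assignment", n_drop))
  }
  v <- variants[has_gene, , drop = FALSE]
  if (nrow(v) == 0L) return(stats::setNames(list(), character()))
  split(v, factor(v$gene, levels = unique(v$gene)))
}

#' Qualifying variants of a gene under a mode-of-inheritance model
#'
#' `NONE` passes every variant through. `AD` (autosomal dominant)
#' requires at least one alternate allele: HET or HOM_ALT variants
#' qualify (a homozygous dominant allele is still causal). `AR`
#' (autosomal recessive) requires two hit alleles: a gene qualifies with
#' at least one HOM_ALT variant, or with >= 2 distinct HET variants
#' assumed in trans (compound heterozygote; phase is unknowable from a
#' single sample). A gene whose qualifying list is empty is excluded from
#' candidacy.
#'
#' @param gene_variants tibble of one gene's variants (post-filtering).
#' @param model one of `"NONE"`, `"AD"`, `"AR"`.
#' @return tibble of qualifying variants (possibly 0 rows).
#' @export
apply_inheritance <- function(gene_variants, model = "NONE") {
  model <- match.arg(model, ew_inheritance_models)
  gt <- gene_variants$genotype
  switch(model,
    NONE = gene_variants,
    AD = gene_variants[gt %in% c("HET", "HOM_ALT"), , drop = FALSE],
    AR = {
      hom <- gt == "HOM_ALT"
      het <- gt == "HET"
      qual <- hom | (het & sum(het) >= 2L)
      if (!any(hom) && sum(het) < 2L) {
        gene_variants[0L, , drop = FALSE]
      } else {
        gene_variants[qual, , drop = FALSE]
      }
    })
}

#' Gene-level variant score
#'
#' By default the gene takes its best (maximum) variant score. Under the
#' recessive model a compound-heterozygote gene (no homozygous alternate
#' variant) is scored as the average of its two highest-scoring
#' heterozygous variants; when both mechanisms are available the gene
#' takes the larger of the homozygous maximum and the compound-het
#' average.
#'
#' @param qualifying tibble of qualifying variants (non-empty), with a
#'   `variant_score` column.
#' @param model the inheritance model the qualifying list was produced
#'   under.
#' @return a single score in \[0,1\].
#' @export
gene_variant_score <- function(qualifying, model = "NONE") {
  model <- match.arg(model, ew_inheritance_models)
  if (nrow(qualifying) == 0L) {
    stop("gene has no qualifying variants; exclude it before scoring", call. = FALSE)
  }
  s <- qualifying$variant_score
  if (model != "AR") return(max(s))
  hom <- qualifying$genotype == "HOM_ALT"
  het <- qualifying$genotype == "HET"
  mechanisms <- numeric(0)
  if (any(hom)) mechanisms <- c(mechanisms, max(s[hom]))
  if (sum(het) >= 2L) {
    top2 <- sort(s[het], decreasing = TRUE)[1:2]
    mechanisms <- c(mechanisms, mean(top2))
  }
  max(mechanisms)
}

#' Assemble gene candidates from scored variants
#'
#' Groups by gene, applies the inheritance model and computes each
#' surviving gene's variant score.
#'
#' @param variants scored variant tibble (output of [score_variant()] on
#'   filtered variants).
#' @param model inheritance model.
#' @return tibble with `gene`, `n_variants` (qualifying count),
#'   `gene_variant_score`; one row per candidate gene.
#' @export
assemble_genes <- function(variants, model = "NONE") {
  model <- match.arg(model, ew_inheritance_models)
  empty <- tibble::tibble(gene = character(), n_variants = integer(),
                          gene_variant_score = numeric())
  has_gene <- !is.na(variants$gene) & nzchar(variants$gene)
  n_drop <- sum(!has_gene)
  if (n_drop > 0L) {
    message(sprintf("dropping %d variant(s) without a gene assignment", n_drop))
  }
  v <- variants[has_gene, , drop = FALSE]
  if (model == "AD") {
    v <- v[v$genotype %in% c("HET", "HOM_ALT"), , drop = FALSE]
  }
  if (nrow(v) == 0L) return(empty)
  # aggregate on plain vectors (equivalent to the per-gene operations
  # apply_inheritance() + gene_variant_score(); cross-checked in tests)
  g <- factor(v$gene)
  s_by <- split(v$variant_score, g)
  gt_by <- split(v$genotype, g)
  if (model %in% c("NONE", "AD")) {
    out <- tibble::tibble(gene = levels(g),
                          n_variants = unname(lengths(s_by)),
                          gene_variant_score = unname(vapply(s_by, max, numeric(1))))
  } else {
    score_ar <- function(s, gt) {
      hom <- gt == "HOM_ALT"
      n_het <- sum(gt == "HET")
      if (!any(hom) && n_het < 2L) return(c(NA_real_, 0))
      mech <- numeric(0)
      if (any(hom)) mech <- c(mech, max(s[hom]))
      if (n_het >= 2L) mech <- c(mech, mean(sort(s[gt == "HET"],
                                                 decreasing = TRUE)[1:2]))
      c(max(mech), sum(hom) + if (n_het >= 2L) n_het else 0L)
    }
    res <- mapply(score_ar, s_by, gt_by)
    keep <- !is.na(res[1L, ])
    out <- tibble::tibble(gene = levels(g)[keep],
                          n_variants = as.integer(unname(res[2L, keep])),
                          gene_variant_score = unname(res[1L, keep]))
  }
  out$n_variants <- as.integer(out$n_variants)
  if (nrow(out) == 0L) empty else out
}
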
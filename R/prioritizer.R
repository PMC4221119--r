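# End-to-end ranking: filter -> score variants -> assemble genes ->
# random walk -> fuse -> ordinal rank.

ew_rank_keys <- c("EXOMEWALKER", "VARIANT", "WALK")

rank_key_column <- c(EXOMEWALKER = "exome_walker_score",
                     VARIANT = "gene_variant_score",
                     WALK = "walk_score")

#' Ordinal ranking of scored gene candidates
#'
#' Sorts descending by the chosen score and resolves ties
#' deterministically by ascending alphabetical gene identifier, then
#' assigns unique consecutive ranks 1..K (ordinal ranking: a reviewer
#' works down equally scored candidates in a fixed order).
#'
#' @param candidates tibble with one row per gene, carrying the score
#'   columns `exome_walker_score`, `gene_variant_score`, `walk_score` (or
#'   at least the one selected).
#' @param key ranking key: `"EXOMEWALKER"`, `"VARIANT"` or `"WALK"`.
#' @return the candidates tibble, reordered, with a `rank` column
#'   prepended.
#' @export
rank_candidates <- function(candidates, key = "EXOMEWALKER") {
  key <- match.arg(key, ew_rank_keys)
  col <- rank_key_column[[key]]
  stopifnot(col %in% names(candidates))
  ord <- order(-candidates[[col]], candidates$gene, method = "radix")
  out <- candidates[ord, , drop = FALSE]
  out <- tibble::as_tibble(out)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Prioritize candidate disease genes in an exome
#'
#' The full pipeline: read variants, filter on target region / rarity /
#' genotype, score each variant (frequency x pathogenicity), assemble
#' gene candidates under the inheritance model, compute the
#' random-walk-with-restart profile from the seed disease-gene family,
#' fuse gene variant score with walk score through the logistic model and
#' rank. Genes absent from the network keep walk score 0 and rank via
#' their variant evidence.
#'
#' @param vcf path to the sample VCF, or an already-annotated variant
#'   tibble (in which case `annotations` is ignored).
#' @param network a `ppa_network`.
#' @param seeds character vector of seed genes (the disease-gene family),
#'   or a path passed through [read_seed_list()] when it names a file.
#' @param annotations optional annotation sidecar TSV path (see
#'   [read_variants()]).
#' @param moi inheritance model: `"NONE"`, `"AD"`, `"AR"`.
#' @param model fusion model; `NULL` uses [default_combiner_model()].
#' @param params [rwr_params()].
#' @param max_maf rarity filter threshold (default 0.01).
#' @param walk_matrix optional precomputed [precompute_walk_matrix()]
#'   result for this network and `params` (reused across samples).
#' @param rank_by ranking key (default `"EXOMEWALKER"`).
#' @param include_paths attach first-/second-degree seed interaction
#'   counts to each candidate (default `TRUE`).
#' @return object of class `ranked_result`: `candidates` tibble (`rank,
#'   gene, exome_walker_score, gene_variant_score, walk_score,
#'   walk_percentile, n_variants, off_network` and, when requested,
#'   `direct_seed_neighbors, second_degree_paths`), `n_postfilter_genes`,
#'   `filter_reasons`, `metadata`.
#' @export
prioritize <- function(vcf, network, seeds, annotations = NULL, moi = "NONE",
                       model = NULL, params = rwr_params(), max_maf = 0.01,
                       walk_matrix = NULL, rank_by = "EXOMEWALKER",
                       include_paths = TRUE) {
  moi <- match.arg(moi, ew_inheritance_models)
  rank_by <- match.arg(rank_by, ew_rank_keys)
  stopifnot(inherits(network, "ppa_network"))
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds)) {
    seeds <- read_seed_list(seeds)
  }
  variants <- if (is.character(vcf)) read_variants(vcf, annotations) else vcf
  if (is.null(model)) model <- default_combiner_model()

  seed_set <- make_seed_set(network, seeds)
  if (is.null(walk_matrix)) {
    walk_matrix <- precompute_walk_matrix(build_transition_matrix(network), params)
  }

  flt <- filter_variants(variants, max_maf = max_maf)
  scored <- score_variant(flt$kept)
  genes <- assemble_genes(scored, model = moi)

  meta <- list(r = params$r, moi = moi, seeds = seed_set$members,
               seeds_missing = seed_set$missing, max_maf = max_maf,
               rank_by = rank_by, n_input_variants = nrow(variants),
               model_provenance = model$provenance,
               walk_transform = model$walk_transform)

  if (nrow(genes) == 0L) {
    empty <- tibble::tibble(rank = integer(), gene = character(),
                            exome_walker_score = numeric(),
                            gene_variant_score = numeric(),
                            walk_score = numeric(), walk_percentile = numeric(),
                            n_variants = integer(), off_network = logical())
    return(structure(list(candidates = empty, n_postfilter_genes = 0L,
                          filter_reasons = flt$reason_counts, metadata = meta),
                     class = "ranked_result"))
  }

  profile <- rwr_closed_form(walk_matrix, seed_set)
  ws <- walk_scores(profile, genes$gene)
  genes$walk_score <- ws$walk_score
  genes$walk_percentile <- ws$walk_percentile
  genes$off_network <- ws$off_network
  walk_feature <- if (identical(model$walk_transform, "PERCENTILE"))
    genes$walk_percentile else genes$walk_score
  genes$exome_walker_score <- combine(genes$gene_variant_score, walk_feature, model)

  if (include_paths) {
    pc <- seed_path_counts(network, genes$gene, seed_set$members)
    genes$direct_seed_neighbors <- pc$direct_seed_neighbors
    genes$second_degree_paths <- pc$second_degree_paths
  }
  ranked <- rank_candidates(genes, key = rank_by)
  first <- c("rank", "gene", "exome_walker_score", "gene_variant_score",
             "walk_score", "walk_percentile", "n_variants", "off_network")
  ranked <- ranked[, c(first, setdiff(names(ranked), first))]
  structure(list(candidates = ranked, n_postfilter_genes = nrow(ranked),
                 filter_reasons = flt$reason_counts, metadata = meta),
            class = "ranked_result")
}

#' @export
print.ranked_result <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked exome result: %d candidate genes (MOI %s, r = %g, ranked by %s)\n",
              x$n_postfilter_genes, x$metadata$moi, x$metadata$r,
              x$metadata$rank_by))
  print(utils::head(x$candidates, n))
  invisible(x)
}

#' Write a ranked result as TSV plus a JSON run-metadata sidecar
#'
#' Scores are formatted to 6 significant digits so identical runs produce
#' byte-identical files.
#'
#' @param result a `ranked_result`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @export
write_ranked_result <- function(result, path) {
  stopifnot(inherits(result, "ranked_result"))
  df <- as.data.frame(result$candidates)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- formatC(signif(df[[col]], 6L), format = "g", digits = 6L)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- result$metadata
  meta$n_postfilter_genes <- result$n_postfilter_genes
  meta$filter_reasons <- as.list(result$filter_reasons)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
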
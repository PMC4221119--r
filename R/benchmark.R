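# Spike-in benchmarking: insert a known pathogenic variant into a
# background exome, prioritize with the rest of the disease-gene family
# as seeds (leave-one-out), and measure top-k recovery of the true gene.

#' Insert a pathogenic spike-in variant into a background exome
#'
#' The spiked genotype follows the record's inheritance mode: one
#' heterozygous variant for dominant disease, one homozygous-alternate
#' variant for recessive disease. The background is otherwise untouched
#' and coordinate sort order is preserved.
#'
#' @param background annotated variant tibble.
#' @param record a spike-in record: list/one-row data.frame with `gene`,
#'   `family`, `chrom`, `pos`, `ref`, `alt`, `effect`, `moi`, and
#'   optionally `maf`, `sift`, `polyphen`, `mutation_taster` (default
#'   absent, i.e. a novel variant with no predictions).
#' @return the background tibble with the spiked variant inserted.
#' @export
spike_in <- function(background, record) {
  rec <- as.list(record)
  stopifnot(!is.null(rec$gene), !is.null(rec$chrom), !is.null(rec$pos),
            !is.null(rec$moi))
  collision <- background$chrom == rec$chrom & background$pos == rec$pos
  if (any(collision)) {
    stop(sprintf("spike-in locus %s:%s already present in the background",
                 rec$chrom, rec$pos), call. = FALSE)
  }
  grab <- function(field, default = NA_real_) {
    if (is.null(rec[[field]]) || is.na(rec[[field]])) default else as.numeric(rec[[field]])
  }
  row <- tibble::tibble(
    chrom = as.character(rec$chrom), pos = as.integer(rec$pos),
    ref = as.character(rec$ref), alt = as.character(rec$alt),
    genotype = if (identical(rec$moi, "AR")) "HOM_ALT" else "HET",
    gene = as.character(rec$gene), effect = as.character(rec$effect),
    maf = grab("maf"), sift = grab("sift"), polyphen = grab("polyphen"),
    mutation_taster = grab("mutation_taster"))
  out <- rbind(background, row)
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Read a disease-gene families file
#'
#' Dialect: `family_name<TAB>comma-separated gene IDs`, `#` comments
#' allowed (a phenotypic-series analogue).
#'
#' @param path file path.
#' @return named list of gene-ID character vectors.
#' @export
read_families <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]]),
                  vapply(parts, `[`, character(1), 1L))
}

#' Read a spike-in catalogue TSV
#'
#' Columns: `gene family chrom pos ref alt effect moi`.
#'
#' @param path file path.
#' @return data.frame of spike-in records.
#' @export
read_spikein_catalogue <- function(path) {
  utils::read.delim(path, comment.char = "#", colClasses = "character")
}

#' Run the spike-in recovery benchmark
#'
#' For every (spike-in record, background exome) pair: insert the
#' pathogenic variant, take the rest of the record's disease-gene family
#' as seeds (leave-one-out: the spiked gene never seeds its own run),
#' prioritize, and record the rank of the spiked gene under `rank_by`.
#' Aggregates the fraction of runs recovering the true gene at rank 1,
#' within the top 10 and within the top 50, and the mean number of
#' post-filter candidate genes. A spiked gene absent from the post-filter
#' candidates counts as not recovered at any cutoff.
#'
#' @param records data.frame of spike-in records (see
#'   [read_spikein_catalogue()]).
#' @param families named list: family name -> gene-ID vector; every
#'   record's family must be present and contain its gene plus at least
#'   one other gene.
#' @param backgrounds list of background exome variant tibbles.
#' @param network a `ppa_network`.
#' @param model fusion model (`NULL`: [default_combiner_model()]).
#' @param params [rwr_params()].
#' @param rank_by ranking key under evaluation.
#' @param moi `NULL` to use each record's own inheritance model, or a
#'   fixed model (`"NONE"` reproduces the no-inheritance setting).
#' @param max_maf rarity filter threshold.
#' @return object of class `benchmark_result`: `n_runs`, `top1`, `top10`,
#'   `top50` (exact fractions), `mean_postfilter_genes`, `runs` per-run
#'   tibble (`gene, family, background, rank, n_postfilter`).
#' @export
run_benchmark <- function(records, families, backgrounds, network,
                          model = NULL, params = rwr_params(),
                          rank_by = "EXOMEWALKER", moi = NULL,
                          max_maf = 0.01) {
  rank_by <- match.arg(rank_by, ew_rank_keys)
  if (is.null(model)) model <- default_combiner_model()
  records <- as.data.frame(records)
  missing_fam <- setdiff(unique(records$family), names(families))
  if (length(missing_fam) > 0L) {
    stop("spike-in records reference unknown families: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  walk_matrix <- precompute_walk_matrix(build_transition_matrix(network), params)

  runs <- vector("list", nrow(records) * length(backgrounds))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    fam_genes <- families[[rec$family]]
    seeds <- setdiff(fam_genes, rec$gene)
    if (length(seeds) == 0L) {
      stop(sprintf("family %s has no seed genes left after removing %s",
                   rec$family, rec$gene), call. = FALSE)
    }
    run_moi <- if (is.null(moi)) rec$moi else moi
    for (b in seq_along(backgrounds)) {
      spiked <- spike_in(backgrounds[[b]], rec)
      res <- suppressWarnings(suppressMessages(
        prioritize(spiked, network = network, seeds = seeds, moi = run_moi,
                   model = model, params = params, max_maf = max_maf,
                   walk_matrix = walk_matrix, rank_by = rank_by,
                   include_paths = FALSE)))
      hit <- match(rec$gene, res$candidates$gene)
      k <- k + 1L
      runs[[k]] <- tibble::tibble(
        gene = rec$gene, family = rec$family, background = b,
        rank = if (is.na(hit)) NA_integer_ else res$candidates$rank[hit],
        n_postfilter = res$n_postfilter_genes)
    }
  }
  runs <- do.call(rbind, runs[seq_len(k)])
  frac <- function(cut) sum(!is.na(runs$rank) & runs$rank <= cut) / nrow(runs)
  structure(list(n_runs = nrow(runs), top1 = frac(1L), top10 = frac(10L),
                 top50 = frac(50L),
                 mean_postfilter_genes = mean(runs$n_postfilter),
                 rank_by = rank_by, runs = runs),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(paste0("Spike-in benchmark (%d runs, ranked by %s)\n",
                     "  top-1 %.1f%%  top-10 %.1f%%  top-50 %.1f%%\n",
                     "  mean post-filter genes: %.1f\n"),
              x$n_runs, x$rank_by, 100 * x$top1, 100 * x$top10, 100 * x$top50,
              x$mean_postfilter_genes))
  invisible(x)
}

#' Write a benchmark result (per-run TSV + JSON summary)
#'
#' @param result a `benchmark_result`.
#' @param path output TSV path for the per-run table; the summary goes to
#'   `<path>.json`.
#' @export
write_benchmark_result <- function(result, path) {
  stopifnot(inherits(result, "benchmark_result"))
  utils::write.table(as.data.frame(result$runs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_runs = result$n_runs, top1 = result$top1, top10 = result$top10,
         top50 = result$top50,
         mean_postfilter_genes = result$mean_postfilter_genes,
         rank_by = result$rank_by),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
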
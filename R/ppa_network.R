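# Protein-protein association (PPA) network: parsing, confidence filtering,
# transition matrix, seed sets and seed-proximal interaction paths.

#' Construct a PPA network from an edge table
#'
#' Low-level constructor used by [load_edge_list()] and the fixture
#' generators. Applies the canonical cleanup rules: edges below the
#' confidence threshold are dropped, self-associations are dropped,
#' duplicate (undirected) pairs are collapsed keeping the maximum
#' confidence, and genes left without any retained edge are removed so
#' that every node of the final graph has degree >= 1 (a requirement for
#' column-normalization of the adjacency matrix).
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @param min_confidence minimum association confidence to retain, in
#'   \[0,1\]. High-confidence functional associations conventionally use
#'   0.7 (the default).
#' @return An object of class `ppa_network`: a list with `genes` (sorted
#'   character vector), `edges` (canonical edge table, `gene_a` <
#'   `gene_b`), `index` (named integer, gene -> matrix position),
#'   `adjacency` (sparse symmetric 0/1 Matrix), `confidence` (sparse
#'   symmetric Matrix of edge confidences) and `min_confidence`.
#' @export
ppa_network <- function(edges, min_confidence = 0.7) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (!is.numeric(min_confidence) || length(min_confidence) != 1L ||
      min_confidence < 0 || min_confidence > 1) {
    stop("`min_confidence` must be a single value in [0, 1]", call. = FALSE)
  }
  conf <- as.numeric(edges$confidence)
  if (anyNA(conf)) stop("non-numeric confidence value in edge table", call. = FALSE)
  if (any(conf < 0 | conf > 1)) {
    stop("edge confidence outside [0, 1]", call. = FALSE)
  }
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)

  keep <- conf >= min_confidence & a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  # canonical undirected orientation, then collapse duplicates keeping max
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    conf <- tapply(conf, key, max)
    pair <- strsplit(names(conf), "\r", fixed = TRUE)
    lo <- vapply(pair, `[`, character(1), 1L)
    hi <- vapply(pair, `[`, character(1), 2L)
    conf <- unname(conf)
  }
  if (length(lo) == 0L) {
    stop("network is empty after confidence filtering", call. = FALSE)
  }
  genes <- sort(unique(c(lo, hi)))  # lexicographic, reproducible layout
  idx <- stats::setNames(seq_along(genes), genes)
  ord <- order(lo, hi)
  edges <- data.frame(gene_a = lo[ord], gene_b = hi[ord],
                      confidence = conf[ord], stringsAsFactors = FALSE)

  n <- length(genes)
  i <- idx[edges$gene_a]; j <- idx[edges$gene_b]
  adjacency <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                    dims = c(n, n), dimnames = list(genes, genes))
  confidence <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                                     x = rep(edges$confidence, 2L),
                                     dims = c(n, n), dimnames = list(genes, genes))
  structure(list(genes = genes, edges = edges, index = idx,
                 adjacency = adjacency, confidence = confidence,
                 min_confidence = min_confidence),
            class = "ppa_network")
}

#' @export
print.ppa_network <- function(x, ...) {
  cat(sprintf("PPA network: %d genes, %d associations (confidence >= %g)\n",
              length(x$genes), nrow(x$edges), x$min_confidence))
  invisible(x)
}

#' Load a PPA network from an edge-list TSV
#'
#' Reads a STRING-style tab-separated edge list (`gene_a`, `gene_b`,
#' `confidence` in \[0,1\]; lines starting with `#` are ignored) and
#' applies confidence filtering. Extra columns beyond the first three are
#' ignored. Gene identifiers are treated as opaque strings (canonically,
#' Entrez Gene IDs); an optional two-column symbol-to-identifier mapping
#' can be applied first.
#'
#' @param path path to the edge-list TSV.
#' @param min_confidence confidence threshold, default 0.7.
#' @param symbol_map optional path to a 2-column TSV mapping input names
#'   to canonical identifiers; unmapped names are kept as-is with a warning.
#' @return A [ppa_network()] object.
#' @export
load_edge_list <- function(path, min_confidence = 0.7, symbol_map = NULL) {
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#") | !nzchar(trimws(lines))
  rows <- which(!is_comment)
  if (length(rows) == 0L) stop("edge-list file contains no data lines", call. = FALSE)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- rows[which(nf < 3L)[1L]]
    stop(sprintf("malformed edge-list line %d: expected >= 3 tab-separated fields", bad),
         call. = FALSE)
  }
  conf <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(conf)) {
    bad <- rows[which(is.na(conf))[1L]]
    stop(sprintf("malformed edge-list line %d: confidence is not numeric", bad),
         call. = FALSE)
  }
  if (any(conf < 0 | conf > 1)) {
    bad <- rows[which(conf < 0 | conf > 1)[1L]]
    stop(sprintf("edge-list line %d: confidence outside [0, 1]", bad), call. = FALSE)
  }
  ga <- vapply(parts, `[`, character(1), 1L)
  gb <- vapply(parts, `[`, character(1), 2L)
  if (!is.null(symbol_map)) {
    map <- utils::read.delim(symbol_map, header = FALSE, comment.char = "#",
                             colClasses = "character")
    lut <- stats::setNames(map[[2L]], map[[1L]])
    unmapped <- setdiff(c(ga, gb), names(lut))
    if (length(unmapped) > 0L) {
      warning(sprintf("%d gene name(s) missing from symbol map (kept as-is): %s",
                      length(unmapped),
                      paste(utils::head(unmapped, 5L), collapse = ", ")),
              call. = FALSE)
    }
    ga <- ifelse(ga %in% names(lut), lut[ga], ga)
    gb <- ifelse(gb %in% names(lut), lut[gb], gb)
  }
  ppa_network(data.frame(gene_a = ga, gene_b = gb, confidence = conf,
                         stringsAsFactors = FALSE),
              min_confidence = min_confidence)
}

#' Serialize a PPA network back to the edge-list TSV dialect
#'
#' Round-trips with [load_edge_list()]: loading the written file at the
#' same threshold reproduces the identical network.
#'
#' @param net a `ppa_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppa_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_a\tgene_b\tconfidence", con)
  writeLines(sprintf("%s\t%s\t%s", net$edges$gene_a, net$edges$gene_b,
                     format(net$edges$confidence, digits = 15, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

#' Read a seed gene list (one identifier per line, `#` comments allowed)
#'
#' @param path path to the list file.
#' @return character vector of gene identifiers.
#' @export
read_seed_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Build the column-normalized transition matrix of a PPA network
#'
#' The random walker's transition matrix W has `W[i, j] = A[i, j] /
#' sum(A[, j])`: the probability of stepping from gene j to gene i. By
#' default the adjacency A is binary (every retained association counts
#' equally); with `weighted = TRUE` the edge confidences weight the
#' adjacency instead, so the walker prefers higher-confidence partners.
#'
#' @param net a `ppa_network`.
#' @param weighted use edge confidences as adjacency weights (default
#'   `FALSE`: binary adjacency after thresholding).
#' @return An object of class `transition_matrix`: list with `W` (sparse
#'   column-stochastic matrix), `genes`, `n`, `weighted`.
#' @export
build_transition_matrix <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "ppa_network"))
  A <- if (weighted) net$confidence else net$adjacency
  cs <- Matrix::colSums(A)
  stopifnot(all(cs > 0))  # guaranteed: constructor drops isolated genes
  W <- A %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(W) <- list(net$genes, net$genes)
  structure(list(W = W, genes = net$genes, n = length(net$genes),
                 weighted = weighted),
            class = "transition_matrix")
}

#' Build a seed set (initial probability vector) over a network
#'
#' The walk starts from each member of the disease-gene family with equal
#' probability: `p0` is 1/m on each of the m seed genes present in the
#' network and 0 elsewhere. Requested genes absent from the network are
#' reported in the `missing` field (and via a warning), not silently
#' dropped.
#'
#' @param net a `ppa_network`.
#' @param genes character vector of seed gene identifiers (non-empty).
#' @return An object of class `seed_set`: list with `members`, `missing`,
#'   `p0` (named numeric of length n) and `m`.
#' @export
make_seed_set <- function(net, genes) {
  stopifnot(inherits(net, "ppa_network"))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("seed gene list is empty", call. = FALSE)
  members <- intersect(genes, net$genes)
  missing <- setdiff(genes, net$genes)
  if (length(members) == 0L) {
    stop("none of the requested seed genes are present in the network", call. = FALSE)
  }
  if (length(missing) > 0L) {
    warning(sprintf("%d seed gene(s) not in the network: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  p0 <- stats::setNames(numeric(length(net$genes)), net$genes)
  p0[members] <- 1 / length(members)
  structure(list(members = members, missing = missing, p0 = p0,
                 m = length(members)),
            class = "seed_set")
}

#' Enumerate short interaction paths from a candidate gene to the seeds
#'
#' Lists every simple path of length <= `max_len` (1 = direct
#' association, 2 = one intermediate gene) from `gene` to any seed
#' member, each with its edge confidences. This is the display evidence a
#' reviewer uses to eyeball why a candidate sits near the disease-gene
#' family. Deterministic order: by seed gene, then intermediate gene.
#'
#' @param net a `ppa_network`.
#' @param gene candidate gene identifier. Off-network candidates yield an
#'   empty list (candidates may legitimately be absent from the network).
#' @param seeds a `seed_set` or character vector of seed genes.
#' @param max_len 1 or 2.
#' @return list of paths; each path is a list with `seed`, `via` (NA for
#'   direct associations) and `confidences` (numeric, one per edge).
#' @export
neighbor_paths <- function(net, gene, seeds, max_len = 2L) {
  stopifnot(inherits(net, "ppa_network"), max_len %in% c(1L, 2L))
  members <- if (inherits(seeds, "seed_set")) seeds$members else
    intersect(as.character(seeds), net$genes)
  if (!gene %in% net$genes) return(list())
  A <- net$adjacency
  g <- net$index[[gene]]
  nb <- net$genes[A[, g] > 0]
  paths <- list()
  for (s in sort(intersect(nb, members))) {
    paths[[length(paths) + 1L]] <- list(
      seed = s, via = NA_character_,
      confidences = net$confidence[gene, s])
  }
  if (max_len == 2L) {
    for (s in sort(members)) {
      if (s == gene) next
      via <- sort(setdiff(intersect(nb, net$genes[A[, net$index[[s]]] > 0]),
                          c(gene, s)))
      for (v in via) {
        paths[[length(paths) + 1L]] <- list(
          seed = s, via = v,
          confidences = c(net$confidence[gene, v], net$confidence[v, s]))
      }
    }
  }
  paths
}

# Counts of length-1 / length-2 routes from each candidate to the seed set,
# computed in bulk on the sparse adjacency (A^2 entries count simple
# length-2 paths because the graph has no self-edges).
seed_path_counts <- function(net, candidates, members) {
  on_net <- candidates %in% net$genes
  direct <- integer(length(candidates))
  second <- integer(length(candidates))
  members <- intersect(members, net$genes)
  if (any(on_net) && length(members) > 0L) {
    A <- net$adjacency
    ci <- net$index[candidates[on_net]]
    si <- net$index[members]
    Asub <- A[ci, si, drop = FALSE]
    direct[on_net] <- as.integer(Matrix::rowSums(Asub))
    A2 <- A[ci, , drop = FALSE] %*% A[, si, drop = FALSE]
    second[on_net] <- as.integer(Matrix::rowSums(A2))
  }
  data.frame(gene = candidates, direct_seed_neighbors = direct,
             second_degree_paths = second, stringsAsFactors = FALSE)
}
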
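# Random walk with restart (RWR) over the PPA network.
#
# The walk p_{t+1} = (1 - r) W p_t + r p0 has fixed point
# p_inf = r (I - (1 - r) W)^{-1} p0, which we precompute once per
# (network, r) and then evaluate per seed set by summing the m seed
# columns of R (O(m n) instead of a full matrix-vector product).

#' RWR parameters
#'
#' @param r restart probability in (0, 1]: the chance per step of jumping
#'   back to the seed distribution. 0.7 (the default) keeps the walker
#'   close to the disease-gene family while still integrating over the
#'   global network structure.
#' @param tol L1 convergence tolerance for the iterative method.
#' @param max_iter iteration cap for the iterative method.
#' @return list of class `rwr_params`.
#' @export
rwr_params <- function(r = 0.7, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, r <= 1, tol > 0, max_iter >= 1)
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

#' Precompute the RWR resolvent matrix R = r (I - (1 - r) W)^(-1)
#'
#' Below `dense_threshold` genes the dense matrix R is formed explicitly,
#' so that each subsequent seed set costs only an O(m n) column sum. For
#' larger networks the sparse LU factorization of I - (1 - r) W is stored
#' instead and each profile is obtained by one back-substitution; the
#' result is identical.
#'
#' @param W a `transition_matrix`.
#' @param params an [rwr_params()] object.
#' @param dense_threshold network size above which the factorized form is
#'   kept instead of the explicit dense inverse (default 2000).
#' @return object of class `walk_matrix` with fields `mode`
#'   ("dense"/"factor"), `R` or `factor`, `r`, `genes`, `n`.
#' @export
precompute_walk_matrix <- function(W, params = rwr_params(),
                                   dense_threshold = 2000L) {
  stopifnot(inherits(W, "transition_matrix"), inherits(params, "rwr_params"))
  r <- params$r
  n <- W$n
  M <- Matrix::Diagonal(n) - (1 - r) * W$W
  if (n <= dense_threshold) {
    R <- tryCatch(r * solve(as.matrix(M)),
                  error = function(e) stop(
                    "RWR linear system reported singular (should be impossible for r > 0 with a column-stochastic W): ",
                    conditionMessage(e), call. = FALSE))
    dimnames(R) <- list(W$genes, W$genes)
    cs <- colSums(R)
    stopifnot(max(abs(cs - 1)) < 1e-10)  # columns of R are probability vectors
    out <- list(mode = "dense", R = R, r = r, genes = W$genes, n = n)
  } else {
    f <- Matrix::lu(methods::as(M, "CsparseMatrix"))
    out <- list(mode = "factor", factor = f, r = r, genes = W$genes, n = n)
  }
  structure(out, class = "walk_matrix")
}

new_walk_profile <- function(p, seeds, r) {
  stopifnot(abs(sum(p) - 1) < 1e-10)
  p <- pmax(p, 0)  # clip sub-roundoff negatives from the linear solve
  structure(list(p = p, seeds = seeds, r = r), class = "walk_profile")
}

#' Steady-state RWR profile via the precomputed closed form
#'
#' For a seed set of m genes the steady state is the average of the m
#' seed columns of R: `p_inf[i] = (1/m) * sum_j R[i, j]` over seed
#' columns j, i.e. R p0 evaluated without touching the zero entries of
#' p0.
#'
#' @param R a `walk_matrix` from [precompute_walk_matrix()].
#' @param seeds a `seed_set` on the same network.
#' @return object of class `walk_profile` with `p` (named steady-state
#'   probability vector summing to 1), `seeds`, `r`.
#' @export
rwr_closed_form <- function(R, seeds) {
  stopifnot(inherits(R, "walk_matrix"), inherits(seeds, "seed_set"))
  if (seeds$m == 0L) stop("empty seed set", call. = FALSE)
  if (!identical(names(seeds$p0), R$genes)) {
    stop("seed set and walk matrix come from different networks", call. = FALSE)
  }
  if (R$mode == "dense") {
    j <- match(seeds$members, R$genes)
    p <- rowSums(R$R[, j, drop = FALSE]) / seeds$m
  } else {
    p <- as.numeric(Matrix::solve(R$factor, R$r * seeds$p0))
  }
  new_walk_profile(stats::setNames(p, R$genes), seeds, R$r)
}

#' Steady-state RWR profile by direct iteration of the walk
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p0` from p0 until the L1 change
#' drops below `params$tol`. Kept primarily as an independent oracle for
#' the closed-form solve and as a fallback for very large networks.
#'
#' @param W a `transition_matrix`.
#' @param seeds a `seed_set`.
#' @param params an [rwr_params()].
#' @return a `walk_profile`.
#' @export
rwr_iterative <- function(W, seeds, params = rwr_params()) {
  stopifnot(inherits(W, "transition_matrix"), inherits(seeds, "seed_set"))
  r <- params$r
  p0 <- seeds$p0
  p <- p0
  for (it in seq_len(params$max_iter)) {
    p_new <- as.numeric((1 - r) * (W$W %*% p) + r * p0)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < params$tol) {
      return(new_walk_profile(stats::setNames(p / sum(p), W$genes), seeds, r))
    }
  }
  stop(sprintf("RWR iteration did not converge in %d steps (last L1 residual %.3g)",
               params$max_iter, delta), call. = FALSE)
}

#' Look up walk scores for candidate genes
#'
#' Candidates absent from the network receive walk score 0 and are
#' flagged `off_network`; they stay in the ranking through their variant
#' score.
#'
#' @param profile a `walk_profile`.
#' @param candidates character vector of gene identifiers.
#' @return tibble with columns `gene`, `walk_score`, `walk_percentile`
#'   (percentile of the gene's steady-state probability among all network
#'   genes; 0 for off-network genes), `off_network`.
#' @export
walk_scores <- function(profile, candidates) {
  stopifnot(inherits(profile, "walk_profile"))
  candidates <- as.character(candidates)
  # round below solver precision so analytically tied probabilities
  # (e.g. structurally symmetric genes) share an averaged percentile
  pct_all <- rank(signif(profile$p, 12L), ties.method = "average") /
    length(profile$p)
  hit <- match(candidates, names(profile$p))
  off <- is.na(hit)
  tibble::tibble(
    gene = candidates,
    walk_score = unname(ifelse(off, 0, profile$p[hit])),
    walk_percentile = unname(ifelse(off, 0, pct_all[hit])),
    off_network = off)
}
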
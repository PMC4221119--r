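# Logistic fusion of the gene variant score and the walk score into the
# final combined score, trained by k-fold cross-validation with the fold
# models averaged.

#' Train the score-fusion logistic model
#'
#' Fits one L2-regularized logistic regression per cross-validation fold
#' on `(variant_score, walk_score) -> label` and averages the fold
#' models' coefficients into the final model (per-fold held-out AUCs are
#' reported alongside). The small fixed ridge penalty guarantees finite
#' coefficients even on perfectly separable data.
#'
#' The walk feature is expected on the scale named by `walk_transform`:
#' `"PERCENTILE"` (default) means the caller supplies the gene's
#' percentile among all network genes' steady-state probabilities (raw
#' steady-state magnitudes scale as 1/n and are not comparable across
#' networks); `"RAW"` uses the probabilities directly.
#'
#' @param examples tibble/data.frame with numeric `variant_score`,
#'   `walk_score` and `label` in `{"DISEASE", "BENIGN"}`.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed governing the fold assignment; the trained model
#'   is deterministic given (examples, folds, seed).
#' @param lambda ridge penalty (default 1e-3).
#' @param walk_transform `"PERCENTILE"` or `"RAW"` (metadata recorded in
#'   the model; [combine()] expects its walk input on this scale).
#' @param average `"coefficients"` (default) averages fold coefficients
#'   into one linear model; `"predictions"` keeps all fold models and
#'   averages their predicted probabilities at scoring time.
#' @return object of class `combiner_model`: `intercept`, `w_variant`,
#'   `w_walk`, `walk_transform`, `average`, `fold_coefs`, `fold_auc`,
#'   `mean_auc`, `provenance` (n_pos, n_neg, folds, seed, lambda).
#' @export
train_combiner <- function(examples, folds = 10L, seed = 1L, lambda = 1e-3,
                           walk_transform = c("PERCENTILE", "RAW"),
                           average = c("coefficients", "predictions")) {
  walk_transform <- match.arg(walk_transform)
  average <- match.arg(average)
  stopifnot(folds >= 2L)
  lab <- as.character(examples$label)
  if (!all(lab %in% c("DISEASE", "BENIGN"))) {
    stop('labels must be "DISEASE" or "BENIGN"', call. = FALSE)
  }
  if (length(unique(lab)) < 2L) {
    stop("both classes must be present to train the fusion model", call. = FALSE)
  }
  x <- as.matrix(examples[, c("variant_score", "walk_score")])
  stopifnot(all(is.finite(x)))
  y <- as.integer(lab == "DISEASE")
  n <- length(y)
  if (n < folds) stop("fewer examples than folds", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  fold_coefs <- matrix(NA_real_, nrow = folds, ncol = 3L,
                       dimnames = list(NULL, c("intercept", "w_variant", "w_walk")))
  fold_auc <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE)
    co <- as.numeric(stats::coef(fit))
    fold_coefs[k, ] <- co
    held <- !tr
    if (length(unique(y[held])) == 2L) {
      pred <- stats::plogis(co[1L] + x[held, , drop = FALSE] %*% co[2:3])
      fold_auc[k] <- binary_auc(y[held], as.numeric(pred))
    }
  }
  mean_coef <- colMeans(fold_coefs)
  structure(list(
    intercept = unname(mean_coef[1L]),
    w_variant = unname(mean_coef[2L]),
    w_walk = unname(mean_coef[3L]),
    walk_transform = walk_transform,
    average = average,
    fold_coefs = fold_coefs,
    fold_auc = fold_auc,
    mean_auc = mean(fold_auc, na.rm = TRUE),
    provenance = list(n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                      folds = folds, seed = seed, lambda = lambda),
    schema_version = 1L), class = "combiner_model")
}

# AUC of a binary classifier (0/1 truth vs numeric score), via pROC.
binary_auc <- function(truth, score) {
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fuse a gene's variant and walk scores into the combined score
#'
#' `sigmoid(intercept + w_variant * v + w_walk * w)`, vectorized; the
#' walk input must be on the model's `walk_transform` scale (the
#' percentile from [walk_scores()] by default). Under
#' `average = "predictions"` the fold models' probabilities are averaged
#' instead of using the averaged coefficients.
#'
#' @param gene_variant_score numeric vector in \[0,1\].
#' @param walk_score numeric vector (same length), on the model's
#'   transform scale.
#' @param model a trained `combiner_model`.
#' @return numeric vector of combined scores in (0,1).
#' @export
combine <- function(gene_variant_score, walk_score, model) {
  if (!inherits(model, "combiner_model")) {
    stop("`model` must be a trained combiner_model", call. = FALSE)
  }
  if (identical(model$average, "predictions")) {
    preds <- apply(model$fold_coefs, 1L, function(co)
      stats::plogis(co[1L] + co[2L] * gene_variant_score + co[3L] * walk_score))
    if (is.null(dim(preds))) return(mean(preds))
    return(rowMeans(preds))
  }
  stats::plogis(model$intercept + model$w_variant * gene_variant_score +
                  model$w_walk * walk_score)
}

#' @export
print.combiner_model <- function(x, ...) {
  cat(sprintf(paste0("Score-fusion logistic model (%s-fold CV average)\n",
                     "  intercept %.4f, w_variant %.4f, w_walk %.4f\n",
                     "  walk transform: %s; mean held-out AUC %.3f\n"),
              x$provenance$folds, x$intercept, x$w_variant, x$w_walk,
              x$walk_transform, x$mean_auc))
  invisible(x)
}

#' Save / load a fusion model as JSON
#'
#' Flat key-value schema with coefficients, transform and training
#' provenance; round-trips losslessly.
#'
#' @param model a `combiner_model`.
#' @param path file path.
#' @export
write_combiner_model <- function(model, path) {
  stopifnot(inherits(model, "combiner_model"))
  obj <- unclass(model)
  obj$fold_coefs <- as.data.frame(obj$fold_coefs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_combiner_model
#' @export
read_combiner_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$fold_coefs <- as.matrix(obj$fold_coefs)
  structure(obj, class = "combiner_model")
}

.combiner_cache <- new.env(parent = emptyenv())

#' Default fusion model trained on the synthetic labeled generator
#'
#' The original tool was trained on a large catalogue of known disease
#' variants against benign ones; that resource is external and licensed,
#' so the packaged default is a clearly-labeled surrogate: a model
#' trained on [generate_labeled_variants()] (2000 + 2000 examples,
#' effect size 1, seed 20140730) with 10-fold CV. Deterministic, cached
#' per session.
#'
#' @return a `combiner_model`.
#' @export
default_combiner_model <- function() {
  if (is.null(.combiner_cache$model)) {
    ex <- generate_labeled_variants(n_pos = 2000L, n_neg = 2000L,
                                    effect_size = 1, seed = 20140730L)
    .combiner_cache$model <- train_combiner(ex, folds = 10L, seed = 20140730L)
  }
  .combiner_cache$model
}
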
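# Per-variant filtering and scoring: rarity (frequency score),
# predicted pathogenicity, and their product (the variant score).

#' Frequency score from the minor allele frequency
#'
#' Maps a population MAF to a rarity score between 1 and 0 for MAFs
#' between 0 and 2%: linear `1 - maf/0.02` on \[0, 0.02\], 0 for more
#' common variants. A variant with no reported frequency in any source
#' (novel variant) scores 1: absence of frequency data is what makes a
#' variant candidate-worthy.
#'
#' @param maf numeric vector of MAFs in \[0,1\]; `NA` for absent.
#' @param maf_cap frequency above which the score is 0 (default 0.02).
#' @return numeric vector of scores in \[0,1\].
#' @export
frequency_score <- function(maf, maf_cap = 0.02) {
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) {
    stop("MAF outside [0, 1]", call. = FALSE)
  }
  s <- pmax(0, 1 - maf / maf_cap)
  s[is.na(maf)] <- 1
  s
}

#' Default pathogenicity scores for non-missense coding effect classes
#'
#' Protein-truncating and splice-disrupting classes carry fixed prior
#' scores (the three in-silico predictors only cover amino-acid
#' substitutions). Configurable: pass a modified copy to
#' [pathogenicity_score()].
#' @export
default_class_pathogenicity <- c(NONSENSE = 0.95, FRAMESHIFT = 0.95,
                                 SPLICE_SITE = 0.90, INFRAME_INDEL = 0.85)

#' Predicted pathogenicity of a variant
#'
#' Missense variants take the most deleterious of the available
#' predictions: SIFT is a tolerance score so it enters as `1 - sift`;
#' PolyPhen-2 and MutationTaster probabilities are used as-is. When all
#' three predictions are absent a prior of 0.6 is assigned — a compromise
#' between treating novel substitutions as benign or as fully pathogenic.
#' Other coding/splice classes use the fixed class table; off-target
#' classes score 0.
#'
#' @param variants annotated variant tibble (or any data.frame with
#'   `effect`, `sift`, `polyphen`, `mutation_taster`).
#' @param class_defaults named numeric, pathogenicity by non-missense
#'   effect class (see [default_class_pathogenicity]).
#' @param missing_default score when a missense variant has no available
#'   prediction (default 0.6).
#' @return numeric vector of pathogenicity scores in \[0,1\].
#' @export
pathogenicity_score <- function(variants,
                                class_defaults = default_class_pathogenicity,
                                missing_default = 0.6) {
  eff <- variants$effect
  n <- length(eff)
  out <- numeric(n)
  miss <- eff == "MISSENSE"
  if (any(miss, na.rm = TRUE)) {
    miss[is.na(miss)] <- FALSE
    dm <- cbind(1 - variants$sift[miss],
                variants$polyphen[miss],
                variants$mutation_taster[miss])
    best <- suppressWarnings(apply(dm, 1L, max, na.rm = TRUE))
    best[!is.finite(best)] <- missing_default  # all three predictions absent
    out[miss] <- best
  }
  for (cls in names(class_defaults)) {
    out[!is.na(eff) & eff == cls] <- class_defaults[[cls]]
  }
  out[!is.na(eff) & eff %in% ew_offtarget_classes] <- 0
  out
}

#' Filter variants on target region, rarity and genotype
#'
#' Removes, in order of precedence: (i) off-target effect classes
#' (`OFF_TARGET`), (ii) variants whose known MAF exceeds `max_maf`
#' (`COMMON`; variants with no frequency data cannot be excluded on
#' frequency and are kept), (iii) reference-homozygous or missing
#' genotypes (`NO_ALT_GENOTYPE`). Input order of kept variants is
#' preserved, and kept + removed partition the input exactly.
#'
#' @param variants annotated variant tibble.
#' @param max_maf exclusion threshold on known MAF (default 0.01: common
#'   variants above 1% are excluded).
#' @return list with `kept` (tibble), `removed` (tibble with an extra
#'   `reason` column) and `reason_counts` (named table).
#' @export
filter_variants <- function(variants, max_maf = 0.01) {
  stopifnot(max_maf >= 0, max_maf <= 1)
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  off <- !is.na(variants$effect) & variants$effect %in% ew_offtarget_classes
  common <- !is.na(variants$maf) & variants$maf > max_maf
  no_alt <- variants$genotype %in% c("HOM_REF", "MISSING")
  reason[no_alt] <- "NO_ALT_GENOTYPE"
  reason[common] <- "COMMON"
  reason[off] <- "OFF_TARGET"
  keep <- is.na(reason)
  removed <- variants[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = variants[keep, , drop = FALSE],
       removed = removed,
       reason_counts = table(removed$reason))
}

#' Score variants: frequency x pathogenicity
#'
#' Attaches `frequency_score`, `pathogenicity_score` and their product
#' `variant_score` (all in \[0,1\]) to each variant. Intended to run on
#' the `kept` output of [filter_variants()]; off-target classes would
#' score 0 anyway.
#'
#' @param variants annotated variant tibble.
#' @inheritParams pathogenicity_score
#' @return the input tibble with the three score columns appended.
#' @export
score_variant <- function(variants,
                          class_defaults = default_class_pathogenicity,
                          missing_default = 0.6) {
  variants$frequency_score <- frequency_score(variants$maf)
  variants$pathogenicity_score <- pathogenicity_score(
    variants, class_defaults = class_defaults, missing_default = missing_default)
  variants$variant_score <- variants$frequency_score * variants$pathogenicity_score
  variants
}
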
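# Reading annotated exome variants: VCF (via vcfR) plus either a sidecar
# annotation TSV keyed on chrom:pos:ref:alt or INFO tags
# (EWGENE/EWEFFECT/EWMAF/EWSIFT/EWPPH/EWMT). Annotation (transcript
# mapping, prediction tools) is consumed, never computed here.

#' Effect classes recognized by the pipeline
#'
#' Off-target classes (not in protein-coding sequence or a splice site)
#' score zero pathogenicity and are removed during filtering.
#' @export
ew_effect_classes <- c("MISSENSE", "NONSENSE", "FRAMESHIFT", "SPLICE_SITE",
                       "INFRAME_INDEL", "SYNONYMOUS", "NONCODING",
                       "INTRONIC", "INTERGENIC", "UTR")

#' @rdname ew_effect_classes
#' @export
ew_offtarget_classes <- c("SYNONYMOUS", "NONCODING", "INTRONIC",
                          "INTERGENIC", "UTR")

dot_to_na <- function(x) {
  x[x %in% c(".", "", "NA")] <- NA_character_
  x
}

genotype_from_gt <- function(gt, alt_index) {
  # GT strings like 0/1, 1|1, ./., 1/2; classify w.r.t. one ALT allele.
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return("MISSING")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("MISSING")
  n_alt <- sum(alleles == as.character(alt_index))
  if (n_alt == 0L) "HOM_REF" else if (n_alt >= 2L) "HOM_ALT" else "HET"
}

#' Read a single-sample exome VCF with its annotations
#'
#' Parses VCF v4.x through `vcfR`, splits multi-allelic records into
#' bi-allelic variants (1-based VCF coordinates preserved) and attaches
#' per-variant annotations: gene, effect class, population MAF and the
#' three pathogenicity predictions (SIFT, PolyPhen-2, MutationTaster).
#'
#' Annotations come from a sidecar TSV (columns `chrom pos ref alt gene
#' effect maf_* sift polyphen mutation_taster`, `.` for absent) keyed on
#' chrom:pos:ref:alt, or, when `annotations` is `NULL`, from the INFO
#' tags `EWGENE, EWEFFECT, EWMAF, EWSIFT, EWPPH, EWMT`. When several
#' `maf_*` frequency columns are present the variant's MAF is the maximum
#' reported frequency across sources; `maf_exclude` names sources (column
#' names) to ignore, e.g. to withhold one panel's frequencies.
#'
#' @param vcf_path path to a VCF file.
#' @param annotations optional path to the sidecar annotation TSV.
#' @param sample which sample column to use (index or name), default 1.
#' @param maf_exclude character vector of `maf_*` sidecar columns to
#'   ignore when computing the maximal population frequency.
#' @return tibble of annotated variants: `chrom, pos, ref, alt, genotype,
#'   gene, effect, maf, sift, polyphen, mutation_taster`.
#' @export
read_variants <- function(vcf_path, annotations = NULL, sample = 1L,
                          maf_exclude = character()) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(empty_variants())
  }
  gt_mat <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                     error = function(e) NULL)
  gt_col <- if (!is.null(gt_mat)) gt_mat[, sample] else rep(NA_character_, nrow(fix))

  # split multi-allelic records
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  out <- tibble::tibble(
    chrom = as.character(fix[rec, "CHROM"]),
    pos = as.integer(fix[rec, "POS"]),
    ref = as.character(fix[rec, "REF"]),
    alt = unlist(alts, use.names = FALSE),
    genotype = mapply(genotype_from_gt, gt_col[rec], alt_idx,
                      USE.NAMES = FALSE))

  if (!is.null(annotations)) {
    out <- join_sidecar(out, annotations, maf_exclude)
  } else {
    info <- function(tag) dot_to_na(vcfR::extract.info(vcf, element = tag))
    num <- function(x) suppressWarnings(as.numeric(x))
    out$gene <- dot_to_na(as.character(info("EWGENE")))[rec]
    out$effect <- toupper(as.character(info("EWEFFECT")))[rec]
    out$maf <- num(info("EWMAF"))[rec]
    out$sift <- num(info("EWSIFT"))[rec]
    out$polyphen <- num(info("EWPPH"))[rec]
    out$mutation_taster <- num(info("EWMT"))[rec]
  }
  validate_variants(out)
  out
}

join_sidecar <- function(out, annotations, maf_exclude = character()) {
  ann <- utils::read.delim(annotations, comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  if (!all(required %in% names(ann))) {
    stop("annotation sidecar must contain columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  key <- function(c_, p_, r_, a_) paste(c_, p_, r_, a_, sep = ":")
  ann_key <- key(ann$chrom, ann$pos, ann$ref, ann$alt)
  hit <- match(key(out$chrom, out$pos, out$ref, out$alt), ann_key)
  num <- function(col) suppressWarnings(as.numeric(dot_to_na(col)))
  maf_cols <- setdiff(grep("^maf", names(ann), value = TRUE), maf_exclude)
  maf <- if (length(maf_cols) > 0L) {
    m <- vapply(maf_cols, function(cl) num(ann[[cl]]), numeric(nrow(ann)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(ann))
    suppressWarnings(apply(m, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)))
  } else rep(NA_real_, nrow(ann))
  out$gene <- dot_to_na(ann$gene)[hit]
  out$effect <- toupper(dot_to_na(ann$effect))[hit]
  out$maf <- maf[hit]
  out$sift <- if ("sift" %in% names(ann)) num(ann$sift)[hit] else NA_real_
  out$polyphen <- if ("polyphen" %in% names(ann)) num(ann$polyphen)[hit] else NA_real_
  out$mutation_taster <- if ("mutation_taster" %in% names(ann)) num(ann$mutation_taster)[hit] else NA_real_
  out
}

empty_variants <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), genotype = character(), gene = character(),
                 effect = character(), maf = numeric(), sift = numeric(),
                 polyphen = numeric(), mutation_taster = numeric())
}

validate_variants <- function(v) {
  stopifnot(all(v$pos >= 1L, na.rm = TRUE))
  bad_gt <- setdiff(unique(v$genotype), c("HET", "HOM_ALT", "HOM_REF", "MISSING"))
  if (length(bad_gt) > 0L) stop("malformed genotype value(s): ",
                                paste(bad_gt, collapse = ", "), call. = FALSE)
  bad_eff <- setdiff(stats::na.omit(unique(v$effect)), ew_effect_classes)
  if (length(bad_eff) > 0L) stop("unknown effect class(es): ",
                                 paste(bad_eff, collapse = ", "), call. = FALSE)
  for (col in c("maf", "sift", "polyphen", "mutation_taster")) {
    x <- v[[col]]
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      stop(sprintf("%s outside [0, 1]", col), call. = FALSE)
    }
  }
  invisible(v)
}

#' Write annotated variants as a VCF plus sidecar annotation TSV
#'
#' Emits plain-text VCF v4.2 (coordinate-sorted) and the matching
#' annotation sidecar in the dialect [read_variants()] consumes. Used by
#' the exome generator and the spike-in harness.
#'
#' @param variants annotated variant tibble.
#' @param vcf_path output VCF path.
#' @param sidecar_path optional output sidecar TSV path.
#' @param sample_name sample column name in the VCF.
#' @export
write_variants <- function(variants, vcf_path, sidecar_path = NULL,
                           sample_name = "SAMPLE") {
  v <- variants[order(variants$chrom, variants$pos, variants$ref, variants$alt), ]
  gt <- c(HET = "0/1", HOM_ALT = "1/1", HOM_REF = "0/0", MISSING = "./.")[v$genotype]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exomewalker-fixtures",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  v$chrom, v$pos, v$ref, v$alt, gt)
  writeLines(c(header, body), vcf_path)
  if (!is.null(sidecar_path)) {
    fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 10, trim = TRUE,
                                                    scientific = FALSE))
    sidecar <- data.frame(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      gene = ifelse(is.na(v$gene), ".", v$gene),
      effect = v$effect,
      maf_population = fmt(v$maf),
      sift = fmt(v$sift), polyphen = fmt(v$polyphen),
      mutation_taster = fmt(v$mutation_taster),
      stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(sidecar, sidecar_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(vcf_path)
}
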
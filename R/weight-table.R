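#' Construct a PRS weight table
#'
#' A weight table holds one published polygenic score: one row per scoring
#' variant with its effect allele and per-allele weight.  Positions are
#' 1-based and chromosome names are normalized to the `"chr"`-prefixed
#' GRCh38 convention.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele` (may be `NA`), `weight`.
#' @param score_id accession or label of the score (e.g. a PGS Catalog id).
#' @param genome_build genome build the coordinates refer to.
#' @param n_raw_rows,n_dropped_rows bookkeeping counts from parsing; used by
#'   the row-count audit `surviving + dropped = raw`.
#' @return object of class `weight_table` (a data.frame).
#' @examples
#' wt <- weight_table(
#'   data.frame(chrom = "chr1", pos = c(100L, 200L),
#'              effect_allele = c("G", "T"), other_allele = c("A", "C"),
#'              weight = c(0.5, -0.2)),
#'   score_id = "TOY1", genome_build = "GRCh38")
#' nrow(wt)
#' @export
weight_table <- function(variants, score_id = "score", genome_build = "GRCh38",
                         n_raw_rows = nrow(variants), n_dropped_rows = 0L) {
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "effect_allele", "weight")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L)
    stop("weight_table: missing column(s): ", paste(miss, collapse = ", "))
  if (!"other_allele" %in% names(variants))
    variants$other_allele <- NA_character_
  variants <- variants[, c("chrom", "pos", "effect_allele", "other_allele", "weight")]
  variants$chrom <- normalize_chrom(as.character(variants$chrom))
  variants$pos <- as.integer(variants$pos)
  variants$effect_allele <- toupper(as.character(variants$effect_allele))
  variants$other_allele <- toupper(as.character(variants$other_allele))
  variants$weight <- as.numeric(variants$weight)
  rownames(variants) <- NULL
  wt <- structure(variants,
    score_id = score_id, genome_build = genome_build,
    n_raw_rows = as.integer(n_raw_rows),
    n_dropped_rows = as.integer(n_dropped_rows),
    class = c("weight_table", "data.frame"))
  validate_weight_table(wt)
  wt
}

#' @rdname weight_table
#' @param wt a `weight_table`.
#' @export
validate_weight_table <- function(wt) {
  stopifnot(inherits(wt, "weight_table"))
  if (nrow(wt) > 0L) {
    if (any(is.na(wt$pos)) || any(wt$pos < 1L))
      stop("weight_table: positions must be integers >= 1")
    if (any(is.na(wt$effect_allele)) || any(!nzchar(wt$effect_allele)))
      stop("weight_table: effect_allele must be non-empty")
    if (any(grepl("[^ACGT]", wt$effect_allele)))
      stop("weight_table: effect_allele must be over {A,C,G,T}")
    if (any(!is.finite(wt$weight)))
      stop("weight_table: weights must be finite")
    has_other <- !is.na(wt$other_allele)
    if (any(wt$effect_allele[has_other] == wt$other_allele[has_other]))
      stop("weight_table: effect_allele must differ from other_allele")
    key <- paste(wt$chrom, wt$pos, wt$effect_allele, wt$other_allele)
    if (anyDuplicated(key))
      stop("weight_table: duplicate (chrom, pos, effect, other) keys")
  }
  invisible(wt)
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %s (%s): %d variants (%d raw rows, %d dropped)\n",
              attr(x, "score_id"), attr(x, "genome_build"), nrow(x),
              attr(x, "n_raw_rows"), attr(x, "n_dropped_rows")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Construct a variant annotation table
#'
#' Minimal stand-in for a cohort-level variant annotation resource: a lookup
#' from variant key `(chrom, pos, ref, alt)` to a QC-pass flag and an allele
#' frequency, used to restrict scoring to high-quality variants.
#'
#' @param chrom,pos,ref,alt variant key vectors (pos 1-based).
#' @param passed_qc logical QC flag per key.
#' @param allele_freq allele frequency in \[0, 1\] per key.
#' @return object of class `annotation_table` (a data.frame).
#' @examples
#' annotation_table("chr1", 100L, "A", "G", TRUE, 0.2)
#' @export
annotation_table <- function(chrom, pos, ref, alt, passed_qc, allele_freq) {
  ann <- data.frame(
    chrom = normalize_chrom(as.character(chrom)),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    passed_qc = as.logical(passed_qc),
    allele_freq = as.numeric(allele_freq),
    stringsAsFactors = FALSE)
  if (nrow(ann) > 0L) {
    if (any(is.na(ann$allele_freq)) || any(ann$allele_freq < 0) || any(ann$allele_freq > 1))
      stop("annotation_table: allele_freq must be in [0, 1]")
    if (anyDuplicated(paste(ann$chrom, ann$pos, ann$ref, ann$alt)))
      stop("annotation_table: duplicate variant keys")
  }
  structure(ann, class = c("annotation_table", "data.frame"))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d variants, %d passed QC\n",
              nrow(x), sum(x$passed_qc)))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# "1" -> "chr1"; leaves "chrX" etc. alone
normalize_chrom <- function(chrom) {
  ifelse(is.na(chrom) | startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}
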
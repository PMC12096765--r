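#' Construct a dense genotype matrix
#'
#' Dense samples-by-variants store: every sample/variant cell holds an
#' explicit unphased diploid call, encoded as a pair of allele indices
#' (0 = REF, k = k-th ALT) in two integer matrices aligned to the variant
#' rows.  A missing call is `NA` in both matrices.  Variants are kept
#' sorted by `(chrom, pos)`.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multiallelic sites).
#' @param allele_a,allele_b integer matrices, `nrow(variants)` x
#'   `length(sample_ids)`, of allele indices; `NA` means missing (both must
#'   be `NA` together — diploid, unphased).
#' @return object of class `dense_genotype_matrix`.
#' @export
dense_genotype_matrix <- function(sample_ids, variants, allele_a, allele_b) {
  sample_ids <- as.character(sample_ids)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- data.frame(chrom = normalize_chrom(as.character(variants$chrom)),
                         pos = as.integer(variants$pos),
                         ref = toupper(as.character(variants$ref)),
                         alt = toupper(as.character(variants$alt)),
                         stringsAsFactors = FALSE)
  allele_a <- matrix(as.integer(allele_a), nrow = nrow(variants))
  allele_b <- matrix(as.integer(allele_b), nrow = nrow(variants))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (ncol(allele_a) != length(sample_ids) || ncol(allele_b) != length(sample_ids))
    stop("allele matrices must have one column per sample")
  if (nrow(variants) > 0L) {
    if (any(is.na(variants$pos)) || any(variants$pos < 1L))
      stop("positions must be >= 1")
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
      stop("ref and alt must be non-empty")
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    rownames(variants) <- NULL
    allele_a <- allele_a[o, , drop = FALSE]
    allele_b <- allele_b[o, , drop = FALSE]
    if (!identical(is.na(allele_a), is.na(allele_b)))
      stop("half-missing calls are not allowed (diploid, unphased)")
    n_alt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
    bad <- which(apply_rows_exceed(allele_a, n_alt) | apply_rows_exceed(allele_b, n_alt))
    if (length(bad) > 0L)
      stop("allele index out of range at variant row ", bad[1L])
  }
  structure(list(sample_ids = sample_ids, variants = variants,
                 allele_a = allele_a, allele_b = allele_b),
            class = "dense_genotype_matrix")
}

apply_rows_exceed <- function(m, n_alt) {
  if (nrow(m) == 0L) return(logical(0))
  bad <- m > n_alt | m < 0L       # recycles n_alt down columns
  bad[is.na(bad)] <- FALSE
  rowSums(bad) > 0L
}

#' @export
print.dense_genotype_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$allele_a))
  cat(sprintf("<dense_genotype_matrix> %d samples x %d variants (%d missing calls)\n",
              length(x$sample_ids), nrow(x$variants), n_missing))
  invisible(x)
}

#' Split comma-joined ALT field into a character vector
#' @noRd
alt_vector <- function(alt) strsplit(alt, ",", fixed = TRUE)

#' Read genotypes from a VCF file into a dense matrix
#'
#' Uses `vcfR` for the container format and parses the GT field itself:
#' `/` and `|` separators are equivalent (phase is ignored), `.` and `./.`
#' become missing calls, and an allele index exceeding the site's ALT count
#' is a parse error naming the record.  Only the GT subfield is consulted.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @return a [dense_genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_var <- nrow(fix)
  if (n_var == 0L) stop("VCF contains no variant records: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_var)
  sample_ids <- colnames(gt)

  tokens <- sub("\\|", "/", gt)
  tokens[is.na(tokens) | tokens == "." | tokens == "./."] <- NA_character_
  parts <- strsplit(tokens, "/", fixed = TRUE)
  bad_len <- !is.na(tokens) & lengths(parts) != 2L
  a <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) == 2L) p[1L] else NA_character_, "")))
  b <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) == 2L) p[2L] else NA_character_, "")))
  # "./1"-style half calls and non-numeric tokens are malformed
  malformed <- bad_len | (!is.na(tokens) & (is.na(a) | is.na(b)))
  if (any(malformed)) {
    idx <- which(malformed)[1L]
    rec <- ((idx - 1L) %% n_var) + 1L
    stop(sprintf("malformed GT token '%s' at VCF record %d (%s:%s)",
                 gt[idx], rec, fix[rec, "CHROM"], fix[rec, "POS"]))
  }
  A <- matrix(a, nrow = n_var)
  B <- matrix(b, nrow = n_var)
  n_alt <- lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE))
  over <- which(apply_rows_exceed(A, n_alt) | apply_rows_exceed(B, n_alt))
  if (length(over) > 0L)
    stop(sprintf("GT allele index out of range at VCF record %d (%s:%s)",
                 over[1L], fix[over[1L], "CHROM"], fix[over[1L], "POS"]))
  dense_genotype_matrix(
    sample_ids,
    data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE),
    A, B)
}

#' Write a dense genotype matrix as minimal VCF 4.2
#'
#' Emits a sites+GT VCF sufficient to round-trip through [read_vcf()].
#'
#' @param dense a [dense_genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dense, path) {
  stopifnot(inherits(dense, "dense_genotype_matrix"))
  v <- dense$variants
  gt <- matrix(paste0(dense$allele_a, "/", dense$allele_b),
               nrow = nrow(v))
  gt[is.na(dense$allele_a)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=prsdual",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", dense$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(v) == 0L) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
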
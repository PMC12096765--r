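#' Read a PGS Catalog scoring file
#'
#' Parses the tab-separated PGS Catalog dialect: `#`-prefixed metadata lines
#' (e.g. `#pgs_id=`, `#genome_build=`, `#HmPOS_build=`), then a header row
#' and one data row per scoring variant.  Harmonized coordinates
#' (`hm_chr`/`hm_pos`) are preferred over author-reported ones
#' (`chr_name`/`chr_position`) when both are present, since the harmonized
#' columns are the build-correct ones for GRCh38 cohorts.  Rows whose weight
#' or position fails to parse are dropped and counted; duplicate variant
#' keys keep the first occurrence with a warning.  Transparently reads
#' gzip-compressed files.
#'
#' @param path path to the scoring file (plain or gzipped).
#' @param expected_build genome build the caller intends to score against;
#'   a mismatch with the file's metadata raises a warning, not an error.
#' @return a [weight_table()]; attributes `n_raw_rows` and `n_dropped_rows`
#'   audit the parse (`nrow + dropped == raw`).
#' @seealso [write_pgs_scoring_file()], [filter_weights_by_annotation()]
#' @export
read_pgs_scoring_file <- function(path, expected_build = "GRCh38") {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  if (length(body) < 1L)
    stop("scoring file format error: no header row in ", path)

  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^#", key, "="), "", hit[1L])
  }
  score_id <- get_meta("pgs_id")
  hm_build <- get_meta("HmPOS_build")
  raw_build <- get_meta("genome_build")

  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  cols <- names(tab)
  if (!all(c("effect_allele", "effect_weight") %in% cols))
    stop("scoring file format error: missing effect_allele/effect_weight column in ", path)
  harmonized <- all(c("hm_chr", "hm_pos") %in% cols)
  if (!harmonized && !all(c("chr_name", "chr_position") %in% cols))
    stop("scoring file format error: no position columns (hm_chr/hm_pos or chr_name/chr_position) in ", path)

  chrom_raw <- if (harmonized) tab$hm_chr else tab$chr_name
  pos_raw <- if (harmonized) tab$hm_pos else tab$chr_position
  build <- if (harmonized && !is.na(hm_build)) hm_build else raw_build
  if (is.na(score_id)) score_id <- "unknown_score"
  if (is.na(build)) build <- "unknown"
  if (!is.null(expected_build) && !is.na(build) && build != "unknown" &&
      !identical(build, expected_build))
    warning(sprintf("scoring file %s declares build %s, expected %s",
                    basename(path), build, expected_build))

  n_raw <- nrow(tab)
  pos <- suppressWarnings(as.integer(pos_raw))
  wgt <- suppressWarnings(as.numeric(tab$effect_weight))
  effect <- toupper(trimws(tab$effect_allele))
  other <- if ("other_allele" %in% cols) toupper(trimws(tab$other_allele)) else rep(NA_character_, n_raw)
  other[!is.na(other) & !nzchar(other)] <- NA_character_

  keep <- !is.na(pos) & pos >= 1L & is.finite(wgt) &
    !is.na(chrom_raw) & nzchar(chrom_raw) &
    !is.na(effect) & nzchar(effect) & !grepl("[^ACGT]", effect) &
    (is.na(other) | other != effect)
  n_dropped <- sum(!keep)

  chrom <- normalize_chrom(chrom_raw[keep])
  key <- paste(chrom, pos[keep], effect[keep], other[keep])
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate weight row(s) in %s; keeping first occurrence",
                    sum(dup), basename(path)))
    n_dropped <- n_dropped + sum(dup)
  }
  sel <- which(keep)[!dup]
  if (length(sel) == 0L)
    stop("scoring file ", path, " yielded zero usable weight rows")

  weight_table(
    data.frame(chrom = normalize_chrom(chrom_raw[sel]), pos = pos[sel],
               effect_allele = effect[sel], other_allele = other[sel],
               weight = wgt[sel], stringsAsFactors = FALSE),
    score_id = score_id, genome_build = build,
    n_raw_rows = n_raw, n_dropped_rows = n_dropped)
}

#' Write a weight table in the PGS Catalog dialect
#'
#' Serializes with `#`-prefixed metadata (`#pgs_id=`, `#HmPOS_build=`) and
#' harmonized `hm_chr`/`hm_pos` coordinate columns; weights are written at
#' full double precision so that read-after-write reproduces the table
#' field-for-field.
#'
#' @param wt a [weight_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgs_scoring_file <- function(wt, path) {
  validate_weight_table(wt)
  header <- c(
    "###PGS CATALOG SCORING FILE###",
    paste0("#pgs_id=", attr(wt, "score_id")),
    paste0("#HmPOS_build=", attr(wt, "genome_build")),
    paste("effect_allele", "other_allele", "effect_weight", "hm_chr", "hm_pos",
          sep = "\t"))
  rows <- sprintf("%s\t%s\t%s\t%s\t%d",
                  wt$effect_allele,
                  ifelse(is.na(wt$other_allele), "", wt$other_allele),
                  sprintf("%.17g", wt$weight),
                  wt$chrom, wt$pos)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Restrict a weight table to QC-passed variants
#'
#' Keeps exactly the weight rows whose variant key is flagged `passed_qc` in
#' the annotation table.  Because the annotation's key orientation (which
#' allele is REF) need not match the weight file's effect/other orientation,
#' both `(other as ref, effect as alt)` and the swapped orientation are
#' tried.  Rows lacking an `other_allele` cannot form a complete key and are
#' removed.  The number of removed variants is reported via a message and
#' the `n_filtered_out` attribute of the result.
#'
#' @param wt a [weight_table()].
#' @param ann an [annotation_table()].
#' @return the filtered `weight_table` (a subset of `wt`, original order).
#' @export
filter_weights_by_annotation <- function(wt, ann) {
  validate_weight_table(wt)
  stopifnot(inherits(ann, "annotation_table"))
  if (nrow(wt) == 0L) return(wt)
  passed <- ann[ann$passed_qc, , drop = FALSE]
  ann_key <- paste(passed$chrom, passed$pos, passed$ref, passed$alt)
  k_fwd <- paste(wt$chrom, wt$pos, wt$other_allele, wt$effect_allele)
  k_rev <- paste(wt$chrom, wt$pos, wt$effect_allele, wt$other_allele)
  keep <- (k_fwd %in% ann_key) | (k_rev %in% ann_key)
  keep[is.na(wt$other_allele)] <- FALSE
  n_removed <- sum(!keep)
  out <- weight_table(as.data.frame(wt)[keep, , drop = FALSE],
                      score_id = attr(wt, "score_id"),
                      genome_build = attr(wt, "genome_build"),
                      n_raw_rows = attr(wt, "n_raw_rows"),
                      n_dropped_rows = attr(wt, "n_dropped_rows"))
  attr(out, "n_filtered_out") <- n_removed
  message(sprintf("annotation filter: %d of %d weight variants removed (QC fail or unannotated)",
                  n_removed, nrow(wt)))
  if (nrow(out) == 0L)
    warning("annotation filter removed every weight variant")
  out
}

#' Read / write the two-column annotation TSV
#'
#' Plain TSV with columns `chrom`, `pos`, `ref`, `alt`, `passed_qc`
#' (`TRUE`/`FALSE`), `allele_freq`.
#'
#' @param path file path.
#' @return [annotation_table()] for the reader; `path` invisibly for the writer.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "passed_qc", "allele_freq")
  if (!all(req %in% names(tab)))
    stop("annotation file format error: need columns ", paste(req, collapse = ", "))
  annotation_table(tab$chrom, tab$pos, tab$ref, tab$alt,
                   tab$passed_qc, tab$allele_freq)
}

#' @rdname read_annotation_table
#' @param ann an [annotation_table()].
#' @export
write_annotation_table <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_table"))
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
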
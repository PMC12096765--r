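#' Construct a sparse variant dataset
#'
#' Sparse genotype store in the reference-block style used by scalable
#' cohort formats: per sample, only non-reference calls are stored as
#' variant entries, and homozygous-reference stretches are encoded as
#' half-open reference blocks `[start, end)`.  A position covered by
#' neither an entry nor a block is *missing* for that sample — whether
#' missing is later interpreted as hom-ref is a scoring-time policy
#' ([score_sparse()]), not a storage property.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param entries data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt` (comma-separated alts), `a`, `b` (allele indices).  No
#'   entry may be hom-ref `(0, 0)` or missing.
#' @param blocks data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end` (half-open, 1-based), `min_quality`.  Per sample and chromosome
#'   the blocks must be sorted and non-overlapping, and must not cover the
#'   position of any stored entry for that sample.
#' @return object of class `sparse_variant_dataset`.
#' @export
sparse_variant_dataset <- function(sample_ids, entries, blocks) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  e_req <- c("sample_id", "chrom", "pos", "ref", "alt", "a", "b")
  b_req <- c("sample_id", "chrom", "start", "end", "min_quality")
  stopifnot(all(e_req %in% names(entries)), all(b_req %in% names(blocks)))
  entries <- entries[e_req]
  blocks <- blocks[b_req]
  entries$pos <- as.integer(entries$pos)
  entries$a <- as.integer(entries$a)
  entries$b <- as.integer(entries$b)
  blocks$start <- as.integer(blocks$start)
  blocks$end <- as.integer(blocks$end)
  blocks$min_quality <- as.integer(blocks$min_quality)

  if (nrow(entries) > 0L) {
    if (!all(entries$sample_id %in% sample_ids))
      stop("entry for unknown sample id")
    if (any(is.na(entries$a)) || any(is.na(entries$b)))
      stop("sparse entries cannot hold missing calls")
    if (any(entries$a == 0L & entries$b == 0L))
      stop("sparse entries cannot be homozygous reference")
    key <- paste(entries$sample_id, entries$chrom, entries$pos)
    if (anyDuplicated(key)) stop("duplicate entry at one sample/position")
    site <- unique(entries[c("chrom", "pos", "ref", "alt")])
    if (anyDuplicated(paste(site$chrom, site$pos)))
      stop("inconsistent ref/alt context at one position")
  }
  if (nrow(blocks) > 0L) {
    if (!all(blocks$sample_id %in% sample_ids))
      stop("block for unknown sample id")
    if (any(blocks$start >= blocks$end))
      stop("reference blocks must satisfy start < end")
    bd <- data.table::as.data.table(blocks)
    data.table::setorder(bd, sample_id, chrom, start)
    overlap <- bd[, if (.N > 1L) any(start[-1L] < end[-.N]) else FALSE,
                  by = .(sample_id, chrom)]
    if (any(overlap$V1)) stop("overlapping reference blocks within a sample")
    blocks <- as.data.frame(bd)
    if (nrow(entries) > 0L) {
      ed <- data.table::as.data.table(entries[c("sample_id", "chrom", "pos")])
      ed[, `:=`(p2 = pos)]
      hit <- data.table::as.data.table(blocks)[
        ed, on = .(sample_id, chrom, start <= pos, end > p2), nomatch = NULL]
      if (nrow(hit) > 0L)
        stop("reference block overlaps a stored variant entry")
    }
  }
  rownames(entries) <- rownames(blocks) <- NULL
  structure(list(sample_ids = sample_ids, entries = entries, blocks = blocks),
            class = "sparse_variant_dataset")
}

#' @export
print.sparse_variant_dataset <- function(x, ...) {
  cat(sprintf("<sparse_variant_dataset> %d samples, %d variant entries, %d reference blocks\n",
              length(x$sample_ids), nrow(x$entries), nrow(x$blocks)))
  invisible(x)
}

#' Convert a dense genotype matrix to the sparse representation
#'
#' Hom-ref calls `(0,0)` are dropped and replaced, per sample, by maximal
#' reference blocks covering exactly the hom-ref positions (runs of
#' consecutive covered positions merge into one block).  Non-reference and
#' heterozygous calls become variant entries.  Missing calls are covered by
#' neither entries nor blocks, so the distinction between "observed
#' hom-ref" and "no data" survives the conversion.
#'
#' @param dense a [dense_genotype_matrix()].
#' @param min_quality quality annotation stored on the emitted blocks
#'   (carried by the format, not consulted by scoring).
#' @return a [sparse_variant_dataset()] over the same samples.
#' @export
sparsify <- function(dense, min_quality = 30L) {
  stopifnot(inherits(dense, "dense_genotype_matrix"))
  v <- dense$variants
  A <- dense$allele_a
  B <- dense$allele_b
  n_s <- length(dense$sample_ids)

  nonref <- which(!is.na(A) & (A != 0L | B != 0L), arr.ind = TRUE)
  entries <- data.frame(
    sample_id = dense$sample_ids[nonref[, 2L]],
    chrom = v$chrom[nonref[, 1L]],
    pos = v$pos[nonref[, 1L]],
    ref = v$ref[nonref[, 1L]],
    alt = v$alt[nonref[, 1L]],
    a = A[nonref],
    b = B[nonref],
    stringsAsFactors = FALSE)

  homref <- which(!is.na(A) & A == 0L & B == 0L, arr.ind = TRUE)
  if (nrow(homref) > 0L) {
    hd <- data.table::data.table(
      sample_id = dense$sample_ids[homref[, 2L]],
      chrom = v$chrom[homref[, 1L]],
      pos = v$pos[homref[, 1L]])
    data.table::setorder(hd, sample_id, chrom, pos)
    hd[, run := cumsum(c(1L, diff(pos) != 1L)), by = .(sample_id, chrom)]
    blocks <- hd[, .(start = pos[1L], end = pos[.N] + 1L), by = .(sample_id, chrom, run)]
    blocks[, run := NULL]
    blocks <- as.data.frame(blocks)
    blocks$min_quality <- as.integer(min_quality)
  } else {
    blocks <- data.frame(sample_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         min_quality = integer(0), stringsAsFactors = FALSE)
  }
  sparse_variant_dataset(dense$sample_ids, entries, blocks)
}

#' Query a sparse dataset at given loci (densification)
#'
#' Interval semantics of scalable sparse stores: for each sample and locus,
#' the stored variant entry wins; otherwise a covering reference block
#' yields hom-ref `(0,0)`; otherwise the call is missing.  Positions use
#' half-open lookup `[pos, pos+1)`.
#'
#' @param vds a [sparse_variant_dataset()].
#' @param loci data.frame with `chrom` and `pos` columns (any order; output
#'   rows align to input rows).
#' @return list with `variants` (data.frame `chrom`, `pos`, `ref`, `alt`;
#'   `ref`/`alt` are `NA` for loci with no stored entry in any sample) and
#'   integer matrices `allele_a`, `allele_b` of dim `nrow(loci)` x
#'   `n_samples` (`NA` = missing).
#' @export
densify_at <- function(vds, loci) {
  stopifnot(inherits(vds, "sparse_variant_dataset"))
  loci <- data.frame(chrom = normalize_chrom(as.character(loci$chrom)),
                     pos = as.integer(loci$pos), stringsAsFactors = FALSE)
  n_l <- nrow(loci)
  n_s <- length(vds$sample_ids)
  A <- matrix(NA_integer_, n_l, n_s)
  B <- matrix(NA_integer_, n_l, n_s)
  ref <- rep(NA_character_, n_l)
  alt <- rep(NA_character_, n_l)
  if (n_l == 0L || n_s == 0L)
    return(list(variants = cbind(loci, ref = ref, alt = alt),
                allele_a = A, allele_b = B))

  samp_idx <- stats::setNames(seq_len(n_s), vds$sample_ids)
  locus_key <- paste(loci$chrom, loci$pos)

  # hom-ref fill from covering blocks
  if (nrow(vds$blocks) > 0L) {
    bd <- data.table::as.data.table(vds$blocks)
    ld <- data.table::data.table(chrom = loci$chrom, pos = loci$pos,
                                 p2 = loci$pos, row = seq_len(n_l))
    cov <- bd[ld, on = .(chrom, start <= pos, end > p2), nomatch = NULL,
              .(sample_id = x.sample_id, row = i.row)]
    if (nrow(cov) > 0L) {
      idx <- cbind(cov$row, samp_idx[cov$sample_id])
      A[idx] <- 0L
      B[idx] <- 0L
    }
  }

  # stored entries override
  if (nrow(vds$entries) > 0L) {
    e <- vds$entries
    row_of <- match(paste(e$chrom, e$pos), locus_key)
    hit <- which(!is.na(row_of))
    if (length(hit) > 0L) {
      idx <- cbind(row_of[hit], samp_idx[e$sample_id[hit]])
      A[idx] <- e$a[hit]
      B[idx] <- e$b[hit]
      ref[row_of[hit]] <- e$ref[hit]
      alt[row_of[hit]] <- e$alt[hit]
    }
  }
  list(variants = cbind(loci, ref = ref, alt = alt, stringsAsFactors = FALSE),
       allele_a = A, allele_b = B)
}

SPARSE_MAGIC <- "#prsdual_sparse_v1"

#' Read / write the line-delimited sparse format
#'
#' Plain-text schema (tab-separated, gz-transparent):
#' \preformatted{
#' #prsdual_sparse_v1
#' #samples=S1,S2,...
#' E  sample_id  chrom  pos  ref  alt  a  b     (one non-ref call)
#' B  sample_id  chrom  start  end  min_quality (one reference block)
#' }
#' Reading enforces all dataset invariants (no hom-ref entries, sorted
#' non-overlapping blocks, no block/entry overlap); `read_sparse(write_sparse(x))`
#' is the identity.
#'
#' @param vds a [sparse_variant_dataset()].
#' @param path file path (plain or gzipped).
#' @return the dataset for the reader; `path` invisibly for the writer.
#' @export
write_sparse <- function(vds, path) {
  stopifnot(inherits(vds, "sparse_variant_dataset"))
  e <- vds$entries
  b <- vds$blocks
  lines <- c(
    SPARSE_MAGIC,
    paste0("#samples=", paste(vds$sample_ids, collapse = ",")),
    if (nrow(e) > 0L)
      sprintf("E\t%s\t%s\t%d\t%s\t%s\t%d\t%d",
              e$sample_id, e$chrom, e$pos, e$ref, e$alt, e$a, e$b),
    if (nrow(b) > 0L)
      sprintf("B\t%s\t%s\t%d\t%d\t%d",
              b$sample_id, b$chrom, b$start, b$end, b$min_quality))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparse
#' @export
read_sparse <- function(path) {
  if (!file.exists(path)) stop("sparse dataset file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != SPARSE_MAGIC)
    stop("not a prsdual sparse dataset (bad magic line): ", path)
  samp_line <- grep("^#samples=", lines, value = TRUE)
  if (length(samp_line) != 1L)
    stop("sparse format error: need exactly one #samples= line")
  samples <- strsplit(sub("^#samples=", "", samp_line), ",", fixed = TRUE)[[1L]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  tag <- substr(body, 1L, 1L)
  if (any(!tag %in% c("E", "B")))
    stop("sparse format error: unknown record tag at line: ",
         body[which(!tag %in% c("E", "B"))[1L]])
  parse_rows <- function(rows, n_fields) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(parts) != n_fields))
      stop("sparse format error: wrong field count in record: ",
           rows[which(lengths(parts) != n_fields)[1L]])
    do.call(rbind, parts)
  }
  e_rows <- body[tag == "E"]
  b_rows <- body[tag == "B"]
  entries <- if (length(e_rows) > 0L) {
    m <- parse_rows(e_rows, 8L)
    data.frame(sample_id = m[, 2L], chrom = m[, 3L], pos = as.integer(m[, 4L]),
               ref = m[, 5L], alt = m[, 6L], a = as.integer(m[, 7L]),
               b = as.integer(m[, 8L]), stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0), alt = character(0),
                    a = integer(0), b = integer(0), stringsAsFactors = FALSE)
  blocks <- if (length(b_rows) > 0L) {
    m <- parse_rows(b_rows, 6L)
    data.frame(sample_id = m[, 2L], chrom = m[, 3L], start = as.integer(m[, 4L]),
               end = as.integer(m[, 5L]), min_quality = as.integer(m[, 6L]),
               stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    min_quality = integer(0), stringsAsFactors = FALSE)
  if (anyNA(entries$pos) || anyNA(blocks$start) || anyNA(blocks$end))
    stop("sparse format error: non-integer coordinate field")
  sparse_variant_dataset(samples, entries, blocks)
}
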
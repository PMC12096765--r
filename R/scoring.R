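#' Match a weight row's effect allele against a variant key
#'
#' Determines which allele of a site the weight applies to: `REF_EFFECT`
#' when the effect allele equals the site's REF, `ALT_EFFECT` (with the
#' 1-based ALT index) when it equals one of the ALTs, and `UNMATCHED`
#' otherwise.  When the weight row carries an `other_allele` that matches
#' neither REF nor any ALT, the role degrades to `UNMATCHED` — an
#' allele-pair consistency check against mis-mapped weight rows.
#'
#' @param ref site REF allele.
#' @param alts character vector of ALT alleles.
#' @param effect_allele,other_allele alleles from the weight row
#'   (`other_allele` may be `NA`).
#' @return list with `kind` (one of `"REF_EFFECT"`, `"ALT_EFFECT"`,
#'   `"UNMATCHED"`) and `allele_index` (0 for REF, k for the k-th ALT, `NA`
#'   when unmatched).
#' @examples
#' match_effect_allele("A", "G", "G", "A")  # ALT_EFFECT, index 1
#' match_effect_allele("A", "G", "A", "G")  # REF_EFFECT, index 0
#' match_effect_allele("A", "G", "T")       # UNMATCHED
#' @export
match_effect_allele <- function(ref, alts, effect_allele, other_allele = NA_character_) {
  if (!is.na(other_allele)) {
    if (other_allele != ref && !(other_allele %in% alts))
      return(list(kind = "UNMATCHED", allele_index = NA_integer_))
  }
  if (effect_allele == ref)
    return(list(kind = "REF_EFFECT", allele_index = 0L))
  k <- match(effect_allele, alts)
  if (!is.na(k))
    return(list(kind = "ALT_EFFECT", allele_index = k))
  list(kind = "UNMATCHED", allele_index = NA_integer_)
}

#' Effect-allele dosage of one genotype call
#'
#' Counts how many of the call's two alleles equal the effect allele
#' (homozygous other = 0, heterozygous = 1, homozygous effect = 2).  A
#' missing call is skipped (`NA` returned) under the `"exclude"` policy, or
#' treated as homozygous reference under `"hom_ref"` — dosage 2 when the
#' effect allele is REF, 0 when it is an ALT.
#'
#' @param allele_a,allele_b allele indices of the call (`NA` = missing).
#' @param role result of [match_effect_allele()]; must not be `UNMATCHED`.
#' @param policy `"exclude"` or `"hom_ref"`.
#' @return integer dosage in 0..2, or `NA` for a skipped call.
#' @export
effect_dosage <- function(allele_a, allele_b, role, policy = c("exclude", "hom_ref")) {
  policy <- match.arg(policy)
  if (identical(role$kind, "UNMATCHED"))
    stop("effect_dosage: role must not be UNMATCHED")
  e <- role$allele_index
  if (is.na(allele_a) || is.na(allele_b)) {
    if (policy == "exclude") return(NA_integer_)
    return(if (e == 0L) 2L else 0L)
  }
  as.integer(allele_a == e) + as.integer(allele_b == e)
}

# Vectorized core shared by both scoring paths.
#
# wt: weight_table; keys: data.frame chrom,pos,ref,alt aligned 1:1 with wt
# rows (ref NA => locus unseen in the store; role falls back to weight-row
# orientation: other_allele as REF, effect allele as sole ALT).
# present: logical per wt row, FALSE => variant absent (contributes nothing,
# not "found").  A, B: allele-index matrices n_wt x n_samples (NA=missing).
score_core <- function(wt, keys, present, A, B, sample_ids, policy,
                       contributions = FALSE) {
  n_w <- nrow(wt)
  n_s <- length(sample_ids)
  prs <- numeric(n_s)
  found <- integer(n_s)
  n_unmatched <- 0L
  n_absent <- sum(!present)
  contrib <- if (contributions) vector("list", n_w) else NULL

  for (i in seq_len(n_w)) {
    if (!present[i]) next
    if (!is.na(keys$ref[i])) {
      role <- match_effect_allele(keys$ref[i],
                                  strsplit(keys$alt[i], ",", fixed = TRUE)[[1L]],
                                  wt$effect_allele[i], wt$other_allele[i])
    } else {
      # locus unseen anywhere in a sparse store: orient from the weight row
      role <- list(kind = "ALT_EFFECT", allele_index = 1L)
    }
    if (role$kind == "UNMATCHED") {
      n_unmatched <- n_unmatched + 1L
      next
    }
    e <- role$allele_index
    a <- A[i, ]
    b <- B[i, ]
    dose <- (a == e) + (b == e)          # NA propagates for missing calls
    miss <- is.na(dose)
    if (policy == "hom_ref") {
      dose[miss] <- if (e == 0L) 2L else 0L
      used <- rep(TRUE, n_s)
    } else {
      dose[miss] <- 0L
      used <- !miss
    }
    prs <- prs + dose * wt$weight[i]
    found <- found + as.integer(used)
    if (contributions) {
      keep <- which(used)
      if (length(keep) > 0L)
        contrib[[i]] <- data.frame(
          sample_id = sample_ids[keep], chrom = wt$chrom[i], pos = wt$pos[i],
          effect_allele = wt$effect_allele[i], dosage = as.integer(dose[keep]),
          weight = wt$weight[i], product = dose[keep] * wt$weight[i],
          stringsAsFactors = FALSE)
    }
  }

  res <- data.frame(sample_id = sample_ids, prs_sum = prs,
                    n_variants_found = found, stringsAsFactors = FALSE)
  structure(res,
            n_variants_in_score = n_w,
            n_absent = n_absent,
            n_unmatched = n_unmatched,
            contributions = if (contributions)
              do.call(rbind, c(contrib, list(make.row.names = FALSE))) else NULL,
            class = c("score_result", "data.frame"))
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %d samples; score has %d variants (%d absent, %d unmatched)\n",
              nrow(x), attr(x, "n_variants_in_score"), attr(x, "n_absent"),
              attr(x, "n_unmatched")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Score a dense genotype matrix against a weight table
#'
#' For every sample, sums `dosage x weight` over the weight-table variants
#' located in the matrix whose effect allele matches the site's REF or an
#' ALT.  Weight variants absent from the matrix, or whose alleles match
#' nothing at the site, contribute nothing and are tallied in the result's
#' `n_absent` / `n_unmatched` attributes.  Missing genotype calls follow
#' `policy`: excluded from the sum and from that sample's
#' `n_variants_found` (`"exclude"`, the default for explicit dense data),
#' or imputed as homozygous reference (`"hom_ref"`).
#'
#' @param dense a [dense_genotype_matrix()].
#' @param wt a non-empty [weight_table()].
#' @param policy missing-call policy, `"exclude"` or `"hom_ref"`.
#' @param contributions if `TRUE`, attach a per-sample, per-variant
#'   contribution table (attribute `"contributions"`) whose `product`
#'   column sums to `prs_sum` per sample.
#' @return a `score_result` data.frame: `sample_id`, `prs_sum`,
#'   `n_variants_found`; attribute `n_variants_in_score`.
#' @export
score_dense <- function(dense, wt, policy = c("exclude", "hom_ref"),
                        contributions = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(dense, "dense_genotype_matrix"))
  validate_weight_table(wt)
  if (nrow(wt) == 0L) stop("empty weight table")
  v <- dense$variants
  row_of <- match(paste(wt$chrom, wt$pos), paste(v$chrom, v$pos))
  present <- !is.na(row_of)
  n_w <- nrow(wt)
  n_s <- length(dense$sample_ids)
  A <- matrix(NA_integer_, n_w, n_s)
  B <- matrix(NA_integer_, n_w, n_s)
  keys <- data.frame(ref = rep(NA_character_, n_w), alt = rep(NA_character_, n_w),
                     stringsAsFactors = FALSE)
  hit <- which(present)
  if (length(hit) > 0L) {
    A[hit, ] <- dense$allele_a[row_of[hit], , drop = FALSE]
    B[hit, ] <- dense$allele_b[row_of[hit], , drop = FALSE]
    keys$ref[hit] <- v$ref[row_of[hit]]
    keys$alt[hit] <- v$alt[row_of[hit]]
  }
  score_core(wt, keys, present, A, B, dense$sample_ids, policy, contributions)
}

#' Score a sparse variant dataset against a weight table
#'
#' The sparse-path workflow: optionally restrict the weight table to
#' QC-passed variants ([filter_weights_by_annotation()]), densify the store
#' at the (filtered) weight loci by interval query ([densify_at()]), then
#' score as in [score_dense()].  The default `"hom_ref"` policy imputes
#' calls absent from the store — not covered by any entry or reference
#' block — as homozygous reference, the assumption sparse cohort stores are
#' scored under; `n_variants_found` is then constant across samples.
#'
#' @param vds a [sparse_variant_dataset()].
#' @param wt a non-empty [weight_table()].
#' @param ann optional [annotation_table()] applied as a QC pre-filter.
#' @param policy missing-call policy; default `"hom_ref"`.
#' @inheritParams score_dense
#' @return a `score_result` data.frame (see [score_dense()]).
#' @export
score_sparse <- function(vds, wt, ann = NULL, policy = c("hom_ref", "exclude"),
                         contributions = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(vds, "sparse_variant_dataset"))
  validate_weight_table(wt)
  if (nrow(wt) == 0L) stop("empty weight table")
  if (!is.null(ann)) wt <- filter_weights_by_annotation(wt, ann)
  if (nrow(wt) == 0L) stop("no weight variants left after annotation filter")
  d <- densify_at(vds, wt[, c("chrom", "pos")])
  keys <- d$variants[, c("ref", "alt")]
  present <- rep(TRUE, nrow(wt))
  score_core(wt, keys, present, d$allele_a, d$allele_b, vds$sample_ids,
             policy, contributions)
}

#' Export score results as TSV
#'
#' Writes `sample_id`, `prs_sum`, `n_variants_found` (one row per sample,
#' `prs_sum` at fixed 6-decimal precision); with
#' `include_contributions = TRUE` a companion `<path>.contributions.tsv`
#' lists every counted variant per sample with its dosage, weight and
#' `product = dosage x weight`.
#'
#' @param results a `score_result` from [score_dense()]/[score_sparse()]
#'   (scored with `contributions = TRUE` if exporting contributions).
#' @param path output TSV path.
#' @param include_contributions also write the per-variant table.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path, include_contributions = FALSE) {
  stopifnot(inherits(results, "score_result"))
  lines <- c("sample_id\tprs_sum\tn_variants_found",
             sprintf("%s\t%.6f\t%d", results$sample_id, results$prs_sum,
                     results$n_variants_found))
  writeLines(lines, path)
  if (include_contributions) {
    cb <- attr(results, "contributions")
    if (is.null(cb))
      stop("results carry no contributions; score with contributions = TRUE")
    clines <- c("sample_id\tchrom\tpos\teffect_allele\tdosage\tweight\tproduct",
                sprintf("%s\t%s\t%d\t%s\t%d\t%.6f\t%.6f",
                        cb$sample_id, cb$chrom, cb$pos, cb$effect_allele,
                        cb$dosage, cb$weight, cb$product))
    writeLines(clines, paste0(path, ".contributions.tsv"))
  }
  invisible(path)
}

#' Read a score-result TSV written by [export_results()]
#' @param path TSV path.
#' @return a `score_result` data.frame.
#' @export
read_score_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "prs_sum", "n_variants_found")
  if (!all(req %in% names(tab)))
    stop("results file format error: need columns ", paste(req, collapse = ", "))
  structure(tab[req],
            n_variants_in_score = NA_integer_, n_absent = NA_integer_,
            n_unmatched = NA_integer_, contributions = NULL,
            class = c("score_result", "data.frame"))
}
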
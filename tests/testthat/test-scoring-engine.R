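test_that("effect-allele matching distinguishes REF, ALT and unmatched roles", {
  expect_identical(match_effect_allele("A", "G", "G", "A"),
                   list(kind = "ALT_EFFECT", allele_index = 1L))
  expect_identical(match_effect_allele("A", "G", "A", "G"),
                   list(kind = "REF_EFFECT", allele_index = 0L))
  expect_identical(match_effect_allele("A", "G", "T")$kind, "UNMATCHED")
  expect_identical(match_effect_allele("A", c("G", "T"), "T", "A"),
                   list(kind = "ALT_EFFECT", allele_index = 2L))
  # allele-pair consistency: other_allele matching nothing degrades the role
  expect_identical(match_effect_allele("A", "G", "G", "C")$kind, "UNMATCHED")
  # missing other_allele skips the consistency check
  expect_identical(match_effect_allele("A", "G", "G", NA)$kind, "ALT_EFFECT")
})

test_that("effect dosage counts alleles and applies the missing-call policy", {
  alt1 <- list(kind = "ALT_EFFECT", allele_index = 1L)
  ref0 <- list(kind = "REF_EFFECT", allele_index = 0L)
  expect_identical(effect_dosage(0L, 1L, alt1, "exclude"), 1L)
  expect_identical(effect_dosage(1L, 1L, alt1, "exclude"), 2L)
  expect_identical(effect_dosage(0L, 0L, ref0, "exclude"), 2L)
  expect_identical(effect_dosage(NA, NA, alt1, "exclude"), NA_integer_)
  # hom-ref imputation: missing treated as (0,0)
  expect_identical(effect_dosage(NA, NA, ref0, "hom_ref"), 2L)
  expect_identical(effect_dosage(NA, NA, alt1, "hom_ref"), 0L)
  expect_error(effect_dosage(0L, 1L, list(kind = "UNMATCHED", allele_index = NA),
                             "exclude"), "UNMATCHED")
})

test_that("dense scoring sums dosage x weight and tallies absent/unmatched variants", {
  d <- dense_genotype_matrix(
    "S1", data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "G"),
    matrix(c(0L, 1L), ncol = 1L), matrix(c(1L, 1L), ncol = 1L))
  wt <- weight_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 200L),
    effect_allele = c("G", "G", "G", "T"),
    other_allele = c("A", "A", "A", "C"),
    weight = c(0.5, -0.2, 99, 99)), score_id = "T")
  res <- score_dense(d, wt)
  expect_equal(res$prs_sum, 1 * 0.5 + 2 * -0.2)     # dosages (1, 2)
  expect_identical(res$n_variants_found, 2L)
  expect_identical(attr(res, "n_variants_in_score"), 4L)
  expect_identical(attr(res, "n_absent"), 1L)       # pos 300 not in matrix
  expect_identical(attr(res, "n_unmatched"), 1L)    # T/C row matches nothing
  expect_error(score_dense(d, wt[0, ]), "empty|weight_table")
})

test_that("dense scoring matches an independent nested-loop oracle exactly", {
  d <- rand_dense(100, 500, missing_rate = 0.03, seed = 21)
  wt <- wt_for_dense(d, seed = 22)
  for (policy in c("exclude", "hom_ref")) {
    oracle <- brute_force_prs(d, wt, policy)
    res <- score_dense(d, wt, policy = policy)
    expect_identical(res$sample_id, d$sample_ids)
    expect_equal(res$prs_sum, oracle$prs, tolerance = 1e-12)
    expect_identical(res$n_variants_found, oracle$found)
  }
})

test_that("sparse scoring equals dense scoring when no calls are missing", {
  d <- rand_dense(60, 300, missing_rate = 0, seed = 5)
  wt <- wt_for_dense(d, seed = 6)
  v <- sparsify(d)
  for (policy in c("exclude", "hom_ref")) {
    rd <- score_dense(d, wt, policy = policy)
    rs <- score_sparse(v, wt, policy = policy)
    expect_identical(rs$prs_sum, rd$prs_sum)        # bitwise, same arithmetic
    expect_identical(rs$n_variants_found, rd$n_variants_found)
  }
})

test_that("sparse scoring with REF-effect weights uses stored site keys", {
  # effect allele = REF for every other weight row; all sites carry at least
  # one non-ref call so the sparse store retains every site key
  d <- rand_dense(50, 100, maf = c(0.3, 0.5), seed = 31)
  v0 <- d$variants
  flip <- seq_len(nrow(v0)) %% 2L == 0L
  wt <- weight_table(data.frame(
    chrom = v0$chrom, pos = v0$pos,
    effect_allele = ifelse(flip, v0$ref, v0$alt),
    other_allele = ifelse(flip, v0$alt, v0$ref),
    weight = rnorm(nrow(v0), 0, 0.1)), score_id = "FLIP")
  rd <- score_dense(d, wt)
  rs <- score_sparse(sparsify(d), wt)
  expect_identical(rs$prs_sum, rd$prs_sum)
})

test_that("annotation pre-filter shrinks the score before sparse scoring", {
  d <- rand_dense(10, 20, seed = 41)
  wt <- wt_for_dense(d, seed = 42)
  keep <- seq_len(20) <= 15
  ann <- annotation_table(d$variants$chrom, d$variants$pos, d$variants$ref,
                          d$variants$alt, keep, rep(0.2, 20))
  rs <- suppressMessages(score_sparse(sparsify(d), wt, ann = ann))
  expect_identical(attr(rs, "n_variants_in_score"), 15L)
  expect_identical(unique(rs$n_variants_found), 15L)
})

test_that("blocks covering every weight locus force the hom-ref score", {
  wt <- weight_table(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "G", "G"),      # first row: effect = REF
    other_allele = c("G", "A", "A"),
    weight = c(0.4, 0.3, -0.2)), score_id = "HR")
  # S2's entries establish every site key; S1 is one long reference block
  v <- sparse_variant_dataset(
    c("S1", "S2"),
    data.frame(sample_id = "S2", chrom = "chr1", pos = c(100L, 200L, 300L),
               ref = "A", alt = "G", a = 0L, b = 1L),
    data.frame(sample_id = "S1", chrom = "chr1", start = 50L, end = 400L,
               min_quality = 30L))
  rs <- score_sparse(v, wt, policy = "hom_ref")
  s1 <- rs$prs_sum[rs$sample_id == "S1"]
  # hom-ref fill: dosage 2 for the REF-effect variant, 0 for ALT-effect ones
  expect_equal(s1, 2 * 0.4)
  expect_identical(unique(rs$n_variants_found), 3L)
})

test_that("a weight locus unseen by the whole store falls back to weight-row orientation", {
  # no entry anywhere at pos 100: the effect allele is taken to be ALT, so a
  # block-covered sample contributes dosage 0 there regardless of orientation
  wt <- weight_table(data.frame(
    chrom = "chr1", pos = 100L, effect_allele = "A", other_allele = "G",
    weight = 0.4), score_id = "FB")
  v <- sparse_variant_dataset(
    "S1", data.frame(sample_id = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0), alt = character(0),
                     a = integer(0), b = integer(0)),
    data.frame(sample_id = "S1", chrom = "chr1", start = 50L, end = 400L,
               min_quality = 30L))
  rs <- score_sparse(v, wt, policy = "hom_ref")
  expect_equal(rs$prs_sum, 0)
  expect_identical(rs$n_variants_found, 1L)
})

test_that("contribution export conserves the score and round-trips through TSV", {
  d <- rand_dense(20, 50, missing_rate = 0.05, seed = 51)
  wt <- wt_for_dense(d, seed = 52)
  res <- score_dense(d, wt, contributions = TRUE)
  cb <- attr(res, "contributions")
  sums <- as.numeric(tapply(cb$product, cb$sample_id, sum)[res$sample_id])
  expect_lt(max(abs(sums - res$prs_sum) / pmax(abs(res$prs_sum), 1)), 1e-12)
  expect_identical(as.integer(table(cb$sample_id)[res$sample_id]),
                   res$n_variants_found)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_results(res, path, include_contributions = TRUE)
  back <- read_score_results(path)
  expect_identical(back$sample_id, res$sample_id)
  expect_lt(max(abs(back$prs_sum - res$prs_sum)), 1e-6)  # 6-decimal format
  ctab <- read.delim(paste0(path, ".contributions.tsv"))
  expect_identical(nrow(ctab), nrow(cb))
  csums <- as.numeric(tapply(ctab$product, ctab$sample_id, sum)[back$sample_id])
  expect_lt(max(abs(csums - back$prs_sum)), 1e-4)  # 6-decimal rounding bound

  # header-only file for an empty result set
  export_results(res[0, ], path)
  expect_identical(readLines(path), "sample_id\tprs_sum\tn_variants_found")
})

test_that("adding a positive-weight, positive-dosage variant never lowers the score", {
  d <- rand_dense(30, 40, seed = 61)
  wt <- wt_for_dense(d, weights = abs(rnorm(40, 0, 0.1)))
  for (k in c(10L, 20L, 40L)) {
    partial <- weight_table(as.data.frame(wt)[seq_len(k), ], score_id = "M")
    res_k <- score_dense(d, partial)
    if (k > 10L) expect_true(all(res_k$prs_sum >= res_prev$prs_sum - 1e-15))
    res_prev <- res_k
  }
})
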
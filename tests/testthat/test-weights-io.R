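test_that("PGS-dialect files parse in order, preferring harmonized coordinates", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_pgs(path, c(
    "rs1\t7\t999\tG\tA\t0.5\t7\t1000",
    "rs2\t7\t1999\tT\tC\t-0.25\t7\t2000"))
  wt <- read_pgs_scoring_file(path, expected_build = "GRCh38")
  expect_s3_class(wt, "weight_table")
  expect_identical(nrow(wt), 2L)
  expect_identical(wt$pos, c(1000L, 2000L))          # hm_pos, not chr_position
  expect_identical(wt$chrom, c("chr7", "chr7"))      # "chr" prefix added
  expect_identical(wt$effect_allele, c("G", "T"))    # input order preserved
  expect_equal(wt$weight, c(0.5, -0.25))
  expect_identical(attr(wt, "score_id"), "PGS_TOY")
  expect_identical(attr(wt, "genome_build"), "GRCh38")
})

test_that("raw coordinate columns are used when harmonized ones are absent, with build warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_pgs(path, "rs1\tchr3\t500\tA\tG\t0.1",
                header = "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
                meta = c("#pgs_id=PGS_RAW", "#genome_build=GRCh37"))
  expect_warning(wt <- read_pgs_scoring_file(path, expected_build = "GRCh38"),
                 "GRCh37")
  expect_identical(wt$pos, 500L)
  expect_identical(wt$chrom, "chr3")
})

test_that("bad rows are dropped and audited: surviving + dropped = raw rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_pgs(path, c(
    "rs1\t1\t100\tG\tA\t0.5\t1\t100",
    "rs2\t1\t200\tT\tC\tnot_a_number\t1\t200",   # unparseable weight
    "rs3\t1\t300\tA\tG\t0.2\t1\tNA",             # unparseable position
    "rs4\t1\t400\tN\tG\t0.3\t1\t400",            # non-ACGT effect allele
    "rs1\t1\t100\tG\tA\t0.9\t1\t100",            # duplicate key, kept-first
    "rs5\t1\t500\tC\tT\t-0.1\t1\t500"))
  expect_warning(wt <- read_pgs_scoring_file(path), "duplicate")
  expect_identical(nrow(wt), 2L)
  expect_identical(attr(wt, "n_raw_rows"), 6L)
  expect_identical(attr(wt, "n_dropped_rows"), 4L)
  expect_identical(nrow(wt) + attr(wt, "n_dropped_rows"), attr(wt, "n_raw_rows"))
  expect_equal(wt$weight[wt$pos == 100L], 0.5)   # first occurrence won
})

test_that("format violations raise errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_pgs(path, "rs1\t1\t100\tG\tA\t0.5\t1\t100",
                header = "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\thm_chr\thm_pos")
  expect_error(read_pgs_scoring_file(path), "effect_weight")
  write_toy_pgs(path, "rs1\t1\tbadpos\tG\tA\tbadweight\t1\tbadpos")
  expect_error(read_pgs_scoring_file(path), "zero usable")
  expect_error(read_pgs_scoring_file(tempfile()), "not found")
})

test_that("write/read round-trip is field-for-field idempotent, also via gzip", {
  wt <- weight_table(
    data.frame(chrom = c("chr1", "chr1", "chrX"), pos = c(101L, 202L, 303L),
               effect_allele = c("G", "T", "A"),
               other_allele = c("A", NA, "C"),
               weight = c(0.123456789012345, -1e-7, 2.5)),
    score_id = "RT1", genome_build = "GRCh38")
  path <- withr::local_tempfile(fileext = ".txt")
  write_pgs_scoring_file(wt, path)
  back <- read_pgs_scoring_file(path)
  expect_identical(as.data.frame(back), as.data.frame(wt))
  expect_identical(attr(back, "score_id"), "RT1")
  # second round trip reproduces the first exactly (idempotence)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_pgs_scoring_file(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # gz-transparent
  gz <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(gz, "wt"); writeLines(readLines(path), con); close(con)
  expect_identical(as.data.frame(read_pgs_scoring_file(gz)), as.data.frame(wt))
})

test_that("annotation filter retains exactly the QC-passed keys, either orientation", {
  wt <- weight_table(
    data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
               effect_allele = c("G", "G", "T", "A", "C"),
               other_allele = c("A", "A", "C", "G", "T"),
               weight = 1:5 / 10),
    score_id = "F1")
  ann <- annotation_table(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ref = c("A", "A", "T", "G"),            # pos 30: effect-as-ref orientation
    alt = c("G", "G", "C", "A"),
    passed_qc = c(TRUE, FALSE, TRUE, TRUE),
    allele_freq = c(0.1, 0.2, 0.3, 0.4))
  out <- suppressMessages(filter_weights_by_annotation(wt, ann))
  expect_identical(out$pos, c(10L, 30L, 40L))     # 20 fails QC, 50 unannotated
  expect_identical(attr(out, "n_filtered_out"), 2L)
  # output is a subset and the filter is idempotent
  expect_true(all(paste(out$chrom, out$pos) %in% paste(wt$chrom, wt$pos)))
  twice <- suppressMessages(filter_weights_by_annotation(out, ann))
  expect_identical(wt_df(twice), wt_df(out))
})

test_that("degenerate annotation filters behave as documented", {
  wt <- weight_table(data.frame(chrom = "chr1", pos = c(1L, 2L),
                                effect_allele = "G", other_allele = "A",
                                weight = 0.1), score_id = "D1")
  all_pass <- annotation_table("chr1", c(1L, 2L), "A", "G", TRUE, 0.5)
  out <- suppressMessages(filter_weights_by_annotation(wt, all_pass))
  expect_identical(wt_df(out), wt_df(wt))
  empty <- annotation_table(character(0), integer(0), character(0),
                            character(0), logical(0), numeric(0))
  expect_warning(suppressMessages(out0 <- filter_weights_by_annotation(wt, empty)),
                 "every weight variant")
  expect_identical(nrow(out0), 0L)
})

test_that("weight-table invariants are enforced", {
  expect_error(weight_table(data.frame(chrom = "1", pos = 0L,
                                       effect_allele = "G", weight = 1)),
               "pos")
  expect_error(weight_table(data.frame(chrom = "1", pos = 1L,
                                       effect_allele = "G",
                                       other_allele = "G", weight = 1)),
               "differ")
  expect_error(weight_table(data.frame(chrom = "1", pos = 1L,
                                       effect_allele = "G", weight = Inf)),
               "finite")
  expect_error(annotation_table("1", 1L, "A", "G", TRUE, 1.5), "allele_freq")
})
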
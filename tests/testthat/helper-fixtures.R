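# Shared fixture builders; everything is generated in code at test time.

# weight-table columns with bookkeeping attributes stripped, for equality
# comparisons of table content
wt_df <- function(w) {
  d <- as.data.frame(w)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

# random dense matrix with explicit ref/alt pairs; allele-index encoding
rand_dense <- function(n_samples, n_variants, maf = c(0.05, 0.45),
                       missing_rate = 0, seed = 1L) {
  set.seed(seed)
  p <- runif(n_variants, maf[1L], maf[2L])
  g <- matrix(rbinom(n_variants * n_samples, 2L, rep(p, n_samples)),
              nrow = n_variants)
  A <- matrix(as.integer(g >= 1L), nrow = n_variants)
  B <- matrix(as.integer(g == 2L), nrow = n_variants)
  if (missing_rate > 0) {
    miss <- matrix(runif(length(g)) < missing_rate, nrow = n_variants)
    A[miss] <- NA_integer_
    B[miss] <- NA_integer_
  }
  chrom <- rep(c("chr1", "chr2"), length.out = n_variants)
  chrom <- chrom[order(chrom)]
  pos <- unlist(lapply(split(seq_len(n_variants), chrom),
                       function(i) sort(sample.int(1e7, length(i)))),
                use.names = FALSE)
  dense_genotype_matrix(
    sprintf("S%03d", seq_len(n_samples)),
    data.frame(chrom = chrom, pos = pos,
               ref = rep("A", n_variants), alt = rep("G", n_variants)),
    A, B)
}

# weight table covering (a subset of) a dense matrix's variants, effect = ALT
wt_for_dense <- function(dense, weights = NULL, seed = 1L) {
  v <- dense$variants
  if (is.null(weights)) {
    set.seed(seed)
    weights <- rnorm(nrow(v), 0, 0.1)
  }
  weight_table(
    data.frame(chrom = v$chrom, pos = v$pos,
               effect_allele = vapply(strsplit(v$alt, ","), `[`, "", 1L),
               other_allele = v$ref, weight = weights),
    score_id = "TESTSCORE", genome_build = "GRCh38")
}

# write a small PGS-dialect scoring file; rows is a character vector of
# pre-formatted data lines under the given header columns
write_toy_pgs <- function(path, rows,
                          header = "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight\thm_chr\thm_pos",
                          meta = c("###PGS CATALOG SCORING FILE###",
                                   "#pgs_id=PGS_TOY",
                                   "#genome_build=GRCh37",
                                   "#HmPOS_build=GRCh38")) {
  writeLines(c(meta, header, rows), path)
  path
}

# independent nested-loop PRS oracle: plain string comparisons, no package
# scoring internals
brute_force_prs <- function(dense, wt, policy = "exclude") {
  v <- dense$variants
  n_s <- length(dense$sample_ids)
  prs <- numeric(n_s)
  found <- integer(n_s)
  for (i in seq_len(nrow(wt))) {
    r <- which(v$chrom == wt$chrom[i] & v$pos == wt$pos[i])[1L]
    if (is.na(r)) next
    alleles <- c(v$ref[r], strsplit(v$alt[r], ",", fixed = TRUE)[[1L]])
    oth <- wt$other_allele[i]
    if (!is.na(oth) && !(oth %in% alleles)) next
    e <- match(wt$effect_allele[i], alleles) - 1L   # 0 = ref
    if (is.na(e)) next
    for (s in seq_len(n_s)) {
      a <- dense$allele_a[r, s]
      b <- dense$allele_b[r, s]
      if (is.na(a)) {
        if (policy == "exclude") next
        d <- if (e == 0L) 2L else 0L
      } else {
        d <- sum(c(a, b) == e)
      }
      prs[s] <- prs[s] + d * wt$weight[i]
      found[s] <- found[s] + 1L
    }
  }
  list(prs = prs, found = found)
}
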
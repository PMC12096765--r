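#' Configuration for a synthetic biobank-style cohort
#'
#' Defines the generative model the scoring and evaluation paths assume:
#' independent Hardy–Weinberg variants with allele frequencies drawn
#' uniformly from `[maf_low, maf_high]`, per-allele weights drawn
#' `Normal(0, weight_sd^2)`, genotypes `Binomial(2, p)` per sample, calls
#' knocked out to missing at `missing_rate`, and a binary outcome from a
#' logistic model on the z-scored true PRS with slope `per_sd_log_or` and
#' intercept `qlogis(baseline_prevalence)`.  A `qc_fail_rate` fraction of
#' variants is flagged as QC-failed in the emitted annotation table.  No
#' linkage disequilibrium is simulated: LD does not affect the correctness
#' of scoring arithmetic or of association recovery, which is what the
#' cohorts exist to test.
#'
#' @param n_samples,n_variants cohort dimensions.
#' @param maf_low,maf_high minor-allele-frequency range, in (0, 0.5].
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param weight_sd SD of the per-allele weights (score units), > 0.
#' @param baseline_prevalence disease prevalence at average score, in (0, 1).
#' @param per_sd_log_or log odds ratio per SD of true score.
#' @param qc_fail_rate fraction of variants flagged as failing QC, in \[0, 1).
#' @param effect_orientation `"alt"` (every weight row's effect allele is
#'   the ALT allele) or `"random"` (each row's effect allele is REF or ALT
#'   with equal probability, exercising both match orientations).
#' @param seed integer seed; all randomness derives from it through named
#'   sub-streams so components are independently reproducible.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 1000L, n_variants = 500L,
                              maf_low = 0.01, maf_high = 0.49,
                              missing_rate = 0, weight_sd = 0.1,
                              baseline_prevalence = 0.1,
                              per_sd_log_or = log(1.8),
                              qc_fail_rate = 0.1,
                              effect_orientation = c("alt", "random"),
                              seed = 1L) {
  effect_orientation <- match.arg(effect_orientation)
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              maf_low = maf_low, maf_high = maf_high,
              missing_rate = missing_rate, weight_sd = weight_sd,
              baseline_prevalence = baseline_prevalence,
              per_sd_log_or = per_sd_log_or,
              qc_fail_rate = qc_fail_rate,
              effect_orientation = effect_orientation,
              seed = as.integer(seed))
  if (cfg$n_samples < 1L || cfg$n_variants < 1L)
    stop("cohort_sim_config: need at least one sample and one variant")
  if (!(cfg$maf_low > 0 && cfg$maf_low <= cfg$maf_high && cfg$maf_high <= 0.5))
    stop("cohort_sim_config: need 0 < maf_low <= maf_high <= 0.5")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("cohort_sim_config: missing_rate must be in [0, 1)")
  if (cfg$weight_sd <= 0) stop("cohort_sim_config: weight_sd must be > 0")
  if (cfg$baseline_prevalence <= 0 || cfg$baseline_prevalence >= 1)
    stop("cohort_sim_config: baseline_prevalence must be in (0, 1)")
  if (cfg$qc_fail_rate < 0 || cfg$qc_fail_rate >= 1)
    stop("cohort_sim_config: qc_fail_rate must be in [0, 1)")
  structure(cfg, class = "cohort_sim_config")
}

# deterministic per-component sub-seeds below 2^31
sim_substreams <- function(seed, n = 6L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a cohort with known scoring and association structure
#'
#' Draws the full object set the two scoring paths and the evaluation
#' battery consume: a dense genotype matrix, a matching weight table, an
#' annotation table with known QC flags and the drawn allele frequencies,
#' and a binary phenotype generated from the z-scored true PRS.  Variants
#' are split across two chromosomes at sorted unique positions.  The true
#' (complete-data) per-sample score and its z-score are returned so tests
#' can verify recovery; missingness is injected only after the truth is
#' computed.
#'
#' @param cfg a [cohort_sim_config()].
#' @return list of class `cohort_sim` with elements `dense`
#'   ([dense_genotype_matrix()]), `weights` ([weight_table()]),
#'   `annotation` ([annotation_table()]), `phenotype` (named 0/1 vector),
#'   and `truth` (list: `allele_freq`, `prs_true`, `prs_z`, `config`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  ss <- sim_substreams(cfg$seed)
  n_s <- cfg$n_samples
  n_v <- cfg$n_variants
  sample_ids <- sprintf("S%05d", seq_len(n_s))

  # variant scaffold: two chromosomes, sorted unique positions
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(ss[1L])
  chrom <- rep(c("chr1", "chr2"), length.out = n_v)
  chrom <- chrom[order(chrom)]
  pos <- unlist(lapply(split(seq_len(n_v), chrom), function(i)
    sort(sample.int(2.4e8, length(i)))), use.names = FALSE)
  p <- runif(n_v, cfg$maf_low, cfg$maf_high)
  base_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2L,
                       byrow = TRUE)
  pair <- base_pairs[sample.int(nrow(base_pairs), n_v, replace = TRUE), ,
                     drop = FALSE]
  ref <- pair[, 1L]
  alt <- pair[, 2L]

  set.seed(ss[2L])
  g <- matrix(rbinom(n_v * n_s, 2L, rep(p, n_s)), nrow = n_v)  # ALT dosage

  set.seed(ss[3L])
  w <- rnorm(n_v, 0, cfg$weight_sd)
  effect_is_alt <- if (cfg$effect_orientation == "alt") rep(TRUE, n_v) else
    runif(n_v) < 0.5

  # truth before missingness
  eff_dose <- g
  eff_dose[!effect_is_alt, ] <- 2L - g[!effect_is_alt, , drop = FALSE]
  prs_true <- as.numeric(crossprod(eff_dose, w))
  z <- (prs_true - mean(prs_true)) / stats::sd(prs_true)

  set.seed(ss[4L])
  alpha <- qlogis(cfg$baseline_prevalence)
  outcome <- rbinom(n_s, 1L, plogis(alpha + cfg$per_sd_log_or * z))

  A <- matrix(as.integer(g >= 1L), nrow = n_v)
  B <- matrix(as.integer(g == 2L), nrow = n_v)
  if (cfg$missing_rate > 0) {
    set.seed(ss[5L])
    miss <- matrix(runif(n_v * n_s) < cfg$missing_rate, nrow = n_v)
    A[miss] <- NA_integer_
    B[miss] <- NA_integer_
  }
  dense <- dense_genotype_matrix(
    sample_ids,
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    A, B)

  set.seed(ss[6L])
  qc_pass <- runif(n_v) >= cfg$qc_fail_rate
  ann <- annotation_table(chrom, pos, ref, alt, qc_pass, p)

  wt <- weight_table(
    data.frame(chrom = chrom, pos = pos,
               effect_allele = ifelse(effect_is_alt, alt, ref),
               other_allele = ifelse(effect_is_alt, ref, alt),
               weight = w, stringsAsFactors = FALSE),
    score_id = "SIMSCORE1", genome_build = "GRCh38")

  structure(list(
    dense = dense, weights = wt, annotation = ann,
    phenotype = stats::setNames(outcome, sample_ids),
    truth = list(allele_freq = p, prs_true = prs_true, prs_z = z,
                 effect_is_alt = effect_is_alt, config = cfg)),
    class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<cohort_sim> %d samples x %d variants (seed %d); prevalence %.3f, per-SD log OR %.3f\n",
              cfg$n_samples, cfg$n_variants, cfg$seed,
              mean(x$phenotype), cfg$per_sd_log_or))
  invisible(x)
}

#' Knock out genotype calls at random
#'
#' Sets each call of a dense matrix to missing independently with
#' probability `rate`; reports the number of newly missing calls via a
#' message and the `n_injected` attribute.
#'
#' @param dense a [dense_genotype_matrix()].
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return the modified matrix.
#' @export
inject_missingness <- function(dense, rate, seed = 1L) {
  stopifnot(inherits(dense, "dense_genotype_matrix"))
  if (rate < 0 || rate >= 1) stop("inject_missingness: rate must be in [0, 1)")
  if (rate == 0) {
    attr(dense, "n_injected") <- 0L
    return(dense)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  miss <- matrix(runif(length(dense$allele_a)) < rate,
                 nrow = nrow(dense$allele_a))
  n_new <- sum(miss & !is.na(dense$allele_a))
  dense$allele_a[miss] <- NA_integer_
  dense$allele_b[miss] <- NA_integer_
  message(sprintf("inject_missingness: %d call(s) newly missing", n_new))
  attr(dense, "n_injected") <- n_new
  dense
}

#' Write a simulated cohort to standard file formats
#'
#' Materializes every artifact the CLI consumes: `cohort.vcf` (dense path),
#' `cohort.sparse.tsv` (sparse path, via [sparsify()]), `weights.txt`
#' (PGS-dialect scoring file), `annotation.tsv`, and `phenotype.tsv`.
#'
#' @param sim a `cohort_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    sparse = file.path(dir, "cohort.sparse.tsv"),
    weights = file.path(dir, "weights.txt"),
    annotation = file.path(dir, "annotation.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"))
  write_vcf(sim$dense, paths[["vcf"]])
  write_sparse(sparsify(sim$dense), paths[["sparse"]])
  write_pgs_scoring_file(sim$weights, paths[["weights"]])
  write_annotation_table(sim$annotation, paths[["annotation"]])
  write_phenotype_table(sim$phenotype, paths[["phenotype"]])
  invisible(paths)
}
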
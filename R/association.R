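#' Lin's concordance correlation coefficient
#'
#' Quantifies agreement between two paired measurements, penalizing both
#' scatter (precision) and location/scale shifts (accuracy):
#' \deqn{\rho_c = \frac{2\rho\sigma_x\sigma_y}{\sigma_x^2 + \sigma_y^2 + (\mu_x-\mu_y)^2}}
#' Moments use denominator `n` (Lin's original definition); at cohort sizes
#' the difference from `n - 1` is negligible, but the choice is fixed and
#' tested.  CCC equals the Pearson correlation exactly when the two vectors
#' share mean and variance, and is strictly attenuated otherwise, so
#' `|ccc| <= |pearson_r|` always.
#'
#' @param x,y numeric vectors of equal length >= 2; at least one must have
#'   non-zero variance.
#' @return object of class `concordance_report`: `ccc`, `pearson_r`,
#'   `mean_x`, `mean_y`, `var_x`, `var_y` (denominator-`n` variances), `n`,
#'   and `ecdf_max_distance` (`NA` here; filled by [compare_score_sets()]).
#' @examples
#' x <- c(1, 2, 3, 4)
#' lin_ccc(x, x)$ccc        # 1
#' lin_ccc(x, x + 1)$ccc    # 2*var/(2*var + 1)
#' @export
lin_ccc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("lin_ccc: length mismatch")
  if (length(x) < 2L) stop("lin_ccc: need at least 2 paired values")
  if (anyNA(x) || anyNA(y)) stop("lin_ccc: NA values not allowed")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0)
    stop("lin_ccc: both vectors are constant; CCC undefined")
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  pearson_r <- if (vx > 0 && vy > 0) sxy / sqrt(vx * vy) else NA_real_
  structure(list(ccc = ccc, pearson_r = pearson_r,
                 mean_x = mx, mean_y = my, var_x = vx, var_y = vy,
                 n = n, ecdf_max_distance = NA_real_),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> n = %d\n  CCC      %.6f\n  Pearson  %.6f\n",
              x$n, x$ccc, x$pearson_r))
  cat(sprintf("  mean x/y %.6f / %.6f\n  var  x/y %.6f / %.6f\n",
              x$mean_x, x$mean_y, x$var_x, x$var_y))
  if (!is.na(x$ecdf_max_distance))
    cat(sprintf("  ECDF sup-distance %.6f\n", x$ecdf_max_distance))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney probability)
#'
#' Area under the ROC curve computed from midranks: the probability that a
#' randomly chosen case scores above a randomly chosen control, ties
#' counting one half.  Invariant under any strictly monotone transform of
#' the scores.
#'
#' @param scores numeric score vector.
#' @param labels binary outcome vector (0 = control, 1 = case); both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("auc_rank: length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("auc_rank: NA values not allowed")
  if (!all(labels %in% c(0L, 1L))) stop("auc_rank: labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auc_rank: need at least one case and one control")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic association of a PRS with a binary outcome
#'
#' Maximum-likelihood logistic fit with the PRS as sole predictor.  By
#' default the PRS is z-scored first so the odds ratio is per standard
#' deviation of score — the conventional reporting scale for polygenic
#' scores and the one that makes effects comparable across scores with
#' different weight magnitudes.  The 95\% CI is Wald:
#' `exp(beta +- 1.96 * SE)`.  Complete separation or a non-converged fit
#' raises an error rather than returning meaningless estimates.
#'
#' @param prs numeric score vector.
#' @param outcome binary vector (0/1), both classes present; `n >= 10`.
#' @param standardize z-score the PRS before fitting (default `TRUE`).
#' @return object of class `association_report`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `log_or`, `se`, `auc` (from [auc_rank()]), `n_cases`,
#'   `n_controls`, `standardized`.
#' @export
logistic_association <- function(prs, outcome, standardize = TRUE) {
  prs <- as.numeric(prs)
  outcome <- as.integer(outcome)
  if (length(prs) != length(outcome)) stop("logistic_association: length mismatch")
  if (length(prs) < 10L) stop("logistic_association: need n >= 10")
  if (anyNA(prs) || anyNA(outcome)) stop("logistic_association: NA values not allowed")
  if (!all(outcome %in% c(0L, 1L)) || length(unique(outcome)) < 2L)
    stop("logistic_association: outcome must contain both classes")
  x <- prs
  if (standardize) {
    s <- stats::sd(prs)
    if (s == 0) stop("logistic_association: constant PRS cannot be standardized")
    x <- (prs - mean(prs)) / s
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)["x"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["x"])
  if (sep_warn && (se > 10 || abs(beta) > 15 || !fit$converged))
    stop("logistic_association: complete or quasi-complete separation")
  if (!fit$converged)
    stop("logistic_association: fit did not converge")
  structure(list(
    odds_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    log_or = beta, se = se,
    auc = auc_rank(prs, outcome),
    n_cases = sum(outcome == 1L), n_controls = sum(outcome == 0L),
    standardized = isTRUE(standardize)),
    class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  unit <- if (x$standardized) "per SD of score" else "per score unit"
  cat(sprintf("<association_report> %d cases / %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  OR  %.4f [%.4f, %.4f] (%s, Wald 95%% CI)\n",
              x$odds_ratio, x$ci_low, x$ci_high, unit))
  cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}

#' Empirical CDF evaluation points
#'
#' Returns the right-continuous step function of the empirical CDF as a
#' table of `(value, cumulative fraction)` at the sorted unique values;
#' fractions lie in `(0, 1]`.
#'
#' @param x non-empty numeric vector.
#' @return data.frame with columns `value` and `fraction`.
#' @export
ecdf_points <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("ecdf_points: need non-empty, NA-free input")
  v <- sort(unique(x))
  data.frame(value = v, fraction = stats::ecdf(x)(v))
}

#' Supremum distance between two empirical CDFs
#'
#' The two-sample Kolmogorov–Smirnov statistic: the largest vertical gap
#' between the ECDFs of `x` and `y`, evaluated over the pooled values.
#' 0 for identical samples, 1 for fully disjoint supports.
#'
#' @param x,y non-empty numeric vectors.
#' @return distance in \[0, 1\].
#' @export
ecdf_max_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("ecdf_max_distance: empty input")
  if (anyNA(x) || anyNA(y)) stop("ecdf_max_distance: NA values not allowed")
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

#' Read / write the two-column phenotype TSV
#'
#' `sample_id` and binary `outcome` (0/1), tab-separated with header.
#'
#' @param path file path.
#' @return named integer vector (names = sample ids) for the reader;
#'   `path` invisibly for the writer.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "outcome") %in% names(tab)))
    stop("phenotype file format error: need sample_id and outcome columns")
  out <- as.integer(tab$outcome)
  if (anyNA(out) || !all(out %in% c(0L, 1L)))
    stop("phenotype outcomes must be 0/1")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in phenotype file")
  stats::setNames(out, tab$sample_id)
}

#' @rdname read_phenotype_table
#' @param phenotype named 0/1 vector as returned by the reader.
#' @export
write_phenotype_table <- function(phenotype, path) {
  writeLines(c("sample_id\toutcome",
               sprintf("%s\t%d", names(phenotype), as.integer(phenotype))),
             path)
  invisible(path)
}

#' Compare two score sets on one phenotype
#'
#' The full concordance battery for a pair of PRS vectors computed by two
#' different paths over the same cohort: Lin's CCC and the ECDF sup-distance
#' between the two score vectors, plus one logistic [association
#' report][logistic_association()] per vector against the shared binary
#' outcome.  Samples are joined on `sample_id`; the intersection of both
#' score sets and the phenotype must be non-empty.
#'
#' @param a,b `score_result` objects (or data.frames with `sample_id` and
#'   `prs_sum`).
#' @param phenotype named 0/1 vector ([read_phenotype_table()]).
#' @param standardize passed to [logistic_association()].
#' @return object of class `score_comparison`: `concordance` (a
#'   `concordance_report` with `ecdf_max_distance` filled), `assoc_a`,
#'   `assoc_b`, `n_joined`.
#' @export
compare_score_sets <- function(a, b, phenotype, standardize = TRUE) {
  ids <- intersect(intersect(a$sample_id, b$sample_id), names(phenotype))
  if (length(ids) == 0L)
    stop("compare_score_sets: no samples shared by both score sets and the phenotype")
  xa <- a$prs_sum[match(ids, a$sample_id)]
  xb <- b$prs_sum[match(ids, b$sample_id)]
  y <- phenotype[ids]
  conc <- lin_ccc(xa, xb)
  conc$ecdf_max_distance <- ecdf_max_distance(xa, xb)
  structure(list(
    concordance = conc,
    assoc_a = logistic_association(xa, y, standardize = standardize),
    assoc_b = logistic_association(xb, y, standardize = standardize),
    n_joined = length(ids)),
    class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat(sprintf("<score_comparison> %d joined samples\n", x$n_joined))
  cat(sprintf("  CCC %.6f | ECDF sup-distance %.6f\n",
              x$concordance$ccc, x$concordance$ecdf_max_distance))
  cat("  -- score set A --\n"); print(x$assoc_a)
  cat("  -- score set B --\n"); print(x$assoc_b)
  invisible(x)
}

#' Serialize a score comparison as TSV + text, optionally with an ECDF plot
#'
#' Writes `<prefix>.comparison.tsv` (one row of all statistics) and
#' `<prefix>.comparison.txt` (the pretty-printed report); with
#' `plot = TRUE` also `<prefix>.ecdf.png` overlaying the two ECDFs.
#'
#' @param cmp a `score_comparison`.
#' @param prefix output path prefix.
#' @param plot also write the ECDF overlay image.
#' @param scores_a,scores_b the score vectors (required when `plot = TRUE`).
#' @return character vector of the written paths, invisibly.
#' @export
write_comparison <- function(cmp, prefix, plot = FALSE,
                             scores_a = NULL, scores_b = NULL) {
  stopifnot(inherits(cmp, "score_comparison"))
  co <- cmp$concordance
  row <- c(n = cmp$n_joined, ccc = co$ccc, pearson_r = co$pearson_r,
           mean_a = co$mean_x, mean_b = co$mean_y,
           var_a = co$var_x, var_b = co$var_y,
           ecdf_max_distance = co$ecdf_max_distance,
           or_a = cmp$assoc_a$odds_ratio, ci_low_a = cmp$assoc_a$ci_low,
           ci_high_a = cmp$assoc_a$ci_high, auc_a = cmp$assoc_a$auc,
           or_b = cmp$assoc_b$odds_ratio, ci_low_b = cmp$assoc_b$ci_low,
           ci_high_b = cmp$assoc_b$ci_high, auc_b = cmp$assoc_b$auc)
  tsv <- paste0(prefix, ".comparison.tsv")
  writeLines(c(paste(names(row), collapse = "\t"),
               paste(sprintf("%.6f", row), collapse = "\t")), tsv)
  txt <- paste0(prefix, ".comparison.txt")
  con <- file(txt, "wt")
  sink(con); print(cmp); sink()
  close(con)
  paths <- c(tsv, txt)
  if (plot) {
    if (is.null(scores_a) || is.null(scores_b))
      stop("write_comparison: plotting needs scores_a and scores_b")
    png_path <- paste0(prefix, ".ecdf.png")
    grDevices::png(png_path, width = 720, height = 540)
    plot(stats::ecdf(scores_a), main = "PRS ECDF overlay",
         xlab = "PRS", ylab = "cumulative fraction", col = "black")
    graphics::lines(stats::ecdf(scores_b), col = "red")
    graphics::legend("bottomright", legend = c("score set A", "score set B"),
                     col = c("black", "red"), lty = 1)
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
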
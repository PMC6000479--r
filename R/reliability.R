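#' Two-way ANOVA decomposition of a subjects x occasions table
#'
#' Partitions the variance of a complete two-occasion score table into
#' between-subject (rows), between-occasion (columns), and residual mean
#' squares -- the ingredients of the absolute-agreement intraclass
#' correlation and of the standard error of measurement.
#'
#' @param pairs A 2-column matrix/data.frame (occasion 1, occasion 2) or a
#'   list of length-2 vectors; at least 3 complete pairs.
#' @return An `acs_vardecomp` list: `ms_rows`, `ms_cols`, `ms_error`,
#'   `n_subjects`, `k_occasions`.
#' @export
anova_decompose <- function(pairs) {
  x <- as_pair_matrix(pairs)
  n <- nrow(x)
  if (n < 3) stop("anova_decompose needs at least 3 complete pairs, got ", n)
  k <- ncol(x)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  resid <- x - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  ss_error <- sum(resid^2)
  structure(list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_error / ((n - 1) * (k - 1)),
    n_subjects = n, k_occasions = k
  ), class = "acs_vardecomp")
}

as_pair_matrix <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  x <- as.matrix(pairs)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop("pairs must have one column per occasion (>= 2)")
  x
}

#' Absolute-agreement single-measures intraclass correlation
#'
#' ICC(A,1): the two-way model ICC for absolute agreement of single
#' measurements,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#' Unlike the consistency-type ICC it charges systematic occasion shifts
#' (practice effects) to the error term. The value is whatever the formula
#' yields (bounded in `[-1, 1]` by the mathematics, never clipped).
#'
#' @param decomp An [anova_decompose()] result.
#' @return The ICC. If every score is identical (zero denominator) the
#'   agreement is perfect by definition: 1 is returned with a warning.
#' @export
icc_absolute_agreement <- function(decomp) {
  k <- decomp$k_occasions
  n <- decomp$n_subjects
  den <- decomp$ms_rows + (k - 1) * decomp$ms_error +
    (k / n) * (decomp$ms_cols - decomp$ms_error)
  if (den == 0) {
    warning("all scores identical; absolute agreement is perfect by definition")
    return(1)
  }
  (decomp$ms_rows - decomp$ms_error) / den
}

#' Paired test for practice effects
#'
#' Two-tailed paired t test of the occasion-2 vs occasion-1 scores. A
#' significant change (default alpha .05) is interpreted as a practice
#' effect and triggers the mean-difference adjustment in the group
#' smallest detectable change.
#'
#' @param pairs As in [anova_decompose()] (>= 2 complete pairs).
#' @param alpha Significance level for the practice-effect flag.
#' @return list(`t_stat`, `df`, `p_value`, `practice_effect`, `mean_diff`)
#'   where `mean_diff` is mean(occasion1) - mean(occasion2). With zero
#'   variance of the differences the p-value is undefined and
#'   `practice_effect` is `FALSE` with a warning.
#' @export
practice_test <- function(pairs, alpha = 0.05) {
  x <- as_pair_matrix(pairs)
  if (nrow(x) < 2) stop("practice_test needs at least 2 complete pairs")
  d <- x[, 1] - x[, 2]
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; practice-effect test undefined")
    return(list(t_stat = if (mean(d) == 0) 0 else NA_real_,
                df = length(d) - 1L, p_value = NA_real_,
                practice_effect = FALSE, mean_diff = mean(d)))
  }
  tt <- stats::t.test(x[, 1], x[, 2], paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       practice_effect = tt$p.value < alpha,
       mean_diff = mean(d))
}

#' Standard error of measurement from the ANOVA decomposition
#'
#' `SEM = sqrt(MS_residual)`, in raw measure units.
#'
#' @param decomp An [anova_decompose()] result.
#' @export
sem_from_decomp <- function(decomp) {
  sqrt(decomp$ms_error)
}

#' Smallest detectable change
#'
#' `SDC = 1.96 * sqrt(2) * SEM`: the magnitude an individual's change must
#' exceed to be distinguishable from measurement error with 95% confidence.
#'
#' @param sem Standard error of measurement (>= 0).
#' @export
sdc <- function(sem) {
  if (any(sem < 0)) stop("sem must be >= 0")
  1.96 * sqrt(2) * sem
}

#' Group-level smallest detectable change
#'
#' Averaging over a group shrinks measurement error, so the individual SDC
#' is divided by `sqrt(n)`. For measures with a significant practice
#' effect the absolute occasion mean difference is added to the SDC before
#' dividing, so that expected practice gains are not mistaken for real
#' group change:
#' `SDC_group = (1.96 sqrt(2) SEM + |mean1 - mean2| [practice]) / sqrt(n)`.
#'
#' @param sem Standard error of measurement (raw units).
#' @param n Group size (>= 1).
#' @param mean1,mean2 Occasion means (raw units); only used when
#'   `practice_effect` is `TRUE`.
#' @param practice_effect Whether a significant practice effect was found.
#' @return Group SDC in raw units.
#' @examples
#' sdc_group(4.76, 240, 34.83, 32.48, TRUE)   # 1.00
#' sdc_group(0.90, 242, practice_effect = FALSE)  # 0.16
#' @export
sdc_group <- function(sem, n, mean1 = NA_real_, mean2 = NA_real_,
                      practice_effect = FALSE) {
  if (n < 1) stop("n must be >= 1")
  adj <- if (isTRUE(practice_effect)) abs(mean1 - mean2) else 0
  (sdc(sem) + adj) / sqrt(n)
}

#' Test-retest correlation with automatic method choice
#'
#' Pearson r when both occasions look normal, Spearman rho otherwise
#' (Shapiro-Wilk at alpha = .05 on each occasion; for n > 5000 a
#' deterministic thinning to 5000 values is tested). The chosen type is
#' reported so that results remain comparable with published coefficients.
#'
#' @param pairs As in [anova_decompose()] (>= 3 complete pairs).
#' @param method `"auto"`, `"pearson"`, or `"spearman"`.
#' @return list(`corr`, `corr_type`). Zero variance on either occasion
#'   yields `corr = NA` with a warning.
#' @export
retest_correlation <- function(pairs, method = c("auto", "pearson",
                                                 "spearman")) {
  method <- match.arg(method)
  x <- as_pair_matrix(pairs)
  if (nrow(x) < 3) stop("retest_correlation needs at least 3 complete pairs")
  if (stats::sd(x[, 1]) == 0 || stats::sd(x[, 2]) == 0) {
    warning("zero variance on one occasion; correlation undefined")
    return(list(corr = NA_real_, corr_type = method))
  }
  if (method == "auto") {
    normal <- vapply(1:2, function(j) {
      v <- x[, j]
      if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
      stats::shapiro.test(v)$p.value >= 0.05
    }, TRUE)
    method <- if (all(normal)) "pearson" else "spearman"
  }
  list(corr = stats::cor(x[, 1], x[, 2], method = method),
       corr_type = method)
}

#' Per-measure test-retest reliability report
#'
#' For every measure with at least 3 participants scored and non-excluded
#' on both occasions: occasion means and SDs, paired practice-effect test,
#' absolute-agreement ICC, retest correlation, SEM, SDC, and group SDC
#' (practice-adjusted). All statistics are computed on raw scores. The
#' battery composite is treated as a derived measure: component z-scores
#' are standardized against occasion-1 reference constants, averaged
#' (complete cases), and the resulting total score analyzed like any other
#' measure.
#'
#' @param scores An `acs_scores` table containing both occasions.
#' @param battery An `acs_battery`.
#' @param alpha_corr Significance level used to annotate the retest
#'   correlation (default .01, two-tailed).
#' @param alpha_practice Significance level of the practice-effect test
#'   (default .05).
#' @param corr_method Correlation method (see [retest_correlation()]).
#' @param include_composite Compute the derived total score as well.
#' @param ref Optional frozen reference constants for the composite; by
#'   default computed from occasion 1 of `scores`.
#' @return data.frame of class `acs_reliability`, one row per measure:
#'   `measure`, `n_pairs`, `mean1`, `sd1`, `mean2`, `sd2`, `t_stat`, `df`,
#'   `p_value`, `practice_effect`, `sem`, `sdc`, `sdc_group`, `icc`,
#'   `corr`, `corr_type`, `corr_significant`.
#' @export
reliability_report <- function(scores, battery,
                               alpha_corr = 0.01, alpha_practice = 0.05,
                               corr_method = "auto",
                               include_composite = TRUE, ref = NULL) {
  scores <- score_table(scores)
  battery <- as_battery(battery)
  if (!all(c(1L, 2L) %in% scores$occasion)) {
    stop("reliability requires scores from both occasions")
  }
  work <- as.data.frame(scores)
  if (include_composite && any(battery$in_composite)) {
    z <- standardize_scores(scores, battery, ref = ref)
    total_name <- if (any(battery$derived)) battery$name[battery$derived][1]
      else "TotalScore"
    work <- rbind(work, composite_table(z, battery, name = total_name))
  }
  measures <- intersect(battery$name, unique(work$measure))
  rows <- lapply(measures, function(m) {
    sub <- work[work$measure == m & !work$excluded, ]
    s1 <- sub[sub$occasion == 1L, c("participant_id", "raw_score")]
    s2 <- sub[sub$occasion == 2L, c("participant_id", "raw_score")]
    ids <- intersect(s1$participant_id, s2$participant_id)
    if (length(ids) < 3) {
      warning("measure ", m, " has fewer than 3 complete pairs; skipped")
      return(NULL)
    }
    x <- cbind(s1$raw_score[match(ids, s1$participant_id)],
               s2$raw_score[match(ids, s2$participant_id)])
    decomp <- anova_decompose(x)
    pt <- practice_test(x, alpha = alpha_practice)
    sem <- sem_from_decomp(decomp)
    rc <- retest_correlation(x, method = corr_method)
    icc <- icc_absolute_agreement(decomp)
    corr_p <- if (is.na(rc$corr)) NA_real_ else
      stats::cor.test(x[, 1], x[, 2], method = rc$corr_type,
                      exact = FALSE)$p.value
    data.frame(
      measure = m, n_pairs = length(ids),
      mean1 = mean(x[, 1]), sd1 = stats::sd(x[, 1]),
      mean2 = mean(x[, 2]), sd2 = stats::sd(x[, 2]),
      t_stat = pt$t_stat, df = pt$df, p_value = pt$p_value,
      practice_effect = pt$practice_effect,
      sem = sem, sdc = sdc(sem),
      sdc_group = sdc_group(sem, length(ids), mean(x[, 1]), mean(x[, 2]),
                            pt$practice_effect),
      icc = icc,
      corr = rc$corr, corr_type = rc$corr_type,
      corr_significant = !is.na(corr_p) && corr_p < alpha_corr,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("acs_reliability", "data.frame")
  out
}
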
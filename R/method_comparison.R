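#' Percent relative error of a surface measurement
#'
#' `100 * (surf - surf_truth) / surf_truth`, signed.
#'
#' @param surf measured area.
#' @param surf_truth reference (true) area, same units, > 0.
#' @return Signed percent error (vectorised).
#' @export
percentRelativeError <- function(surf, surf_truth) {
  if (any(surf_truth <= 0)) stop("invalid truth", call. = FALSE)
  100 * (surf - surf_truth) / surf_truth
}

#' Summary of an accuracy-error distribution
#'
#' @param errors numeric vector of signed percent errors.
#' @return List with `median`, `min`, `max`, `mean` (exact order statistics;
#'   the median of an even count is the midpoint of the two middle values).
#' @export
accuracySummary <- function(errors) {
  if (length(errors) == 0) stop("no data", call. = FALSE)
  list(median = stats::median(errors), min = min(errors), max = max(errors),
       mean = mean(errors))
}

#' Bland-Altman analysis of paired measurements
#'
#' In proportional mode the per-pair difference is
#' `100 * (a - b) / ((a + b) / 2)` (percent of the pair mean, the standard
#' Bland-Altman transform for ratio data); in absolute mode it is `a - b`
#' untransformed. Bias is the mean difference, SD the sample (n-1) standard
#' deviation, and the limits of agreement are `bias +/- 1.96 * SD`. Optional
#' percentile bootstrap confidence intervals resample whole pairs.
#'
#' @param values_a,values_b paired measurements (equal length >= 2; strictly
#'   positive in proportional mode).
#' @param mode `"proportional"` or `"absolute"`.
#' @param denominator `"mean"` (default) or `"b"`: denominator of the
#'   proportional difference, switchable for sensitivity checks.
#' @param n_boot bootstrap replicates for CIs (0 = no CIs).
#' @param seed RNG seed for the bootstrap.
#' @return A [BlandAltmanResult-class].
#' @export
blandAltman <- function(values_a, values_b,
                        mode = c("proportional", "absolute"),
                        denominator = c("mean", "b"), n_boot = 0, seed = 1) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (length(values_a) != length(values_b))
    stop("insufficient pairs: lengths differ", call. = FALSE)
  n <- length(values_a)
  if (n < 2) stop("insufficient pairs", call. = FALSE)
  d <- .ba_diffs(values_a, values_b, mode, denominator)
  bias <- mean(d)
  sd_ <- stats::sd(d)
  ci_bias <- ci_sd <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci_bias <- bootstrapCI(values_a, values_b, statistic = "bias", mode = mode,
                           denominator = denominator, n_boot = n_boot,
                           seed = seed)
    ci_sd <- bootstrapCI(values_a, values_b, statistic = "sd", mode = mode,
                         denominator = denominator, n_boot = n_boot,
                         seed = seed)
  }
  new("BlandAltmanResult", bias_pct = bias, sd_pct = sd_,
      loa_low_pct = bias - 1.96 * sd_, loa_high_pct = bias + 1.96 * sd_,
      ci_bias = ci_bias, ci_sd = ci_sd, n = as.integer(n), mode = mode)
}

.ba_diffs <- function(a, b, mode, denominator = "mean") {
  if (mode == "proportional") {
    if (any(a <= 0) || any(b <= 0)) stop("invalid values", call. = FALSE)
    den <- if (denominator == "mean") (a + b) / 2 else b
    100 * (a - b) / den
  } else {
    a - b
  }
}

#' Percentile bootstrap CI for a Bland-Altman statistic
#'
#' Resamples whole pairs with replacement; 95% percentile interval.
#' Deterministic given `seed`.
#'
#' @param values_a,values_b paired measurements.
#' @param statistic `"bias"` or `"sd"`.
#' @param mode,denominator as in [blandAltman()].
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed.
#' @return Numeric length-2 interval.
#' @export
bootstrapCI <- function(values_a, values_b, statistic = c("bias", "sd"),
                        mode = "proportional", denominator = "mean",
                        n_boot = 2000, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(values_a) < 2) stop("insufficient pairs", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  d <- .ba_diffs(values_a, values_b, mode, denominator)
  f <- if (statistic == "bias") mean else stats::sd
  n <- length(d)
  stat <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n_boot)) stat[i] <- f(d[sample.int(n, n, replace = TRUE)])
  unname(stats::quantile(stat, c(0.025, 0.975), type = 7))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare two difference series (variance and bias)
#'
#' Two-sided F-test of the variance ratio (larger variance in the numerator)
#' and two-sided Welch t-test on the means, the standard comparison of two
#' inter-method difference series.
#'
#' @param diffs_a,diffs_b numeric difference series (each length >= 2).
#' @return List: `f_statistic`, `f_pvalue`, `t_statistic`, `t_pvalue`.
#' @export
compareMethods <- function(diffs_a, diffs_b) {
  if (length(diffs_a) < 2 || length(diffs_b) < 2)
    stop("insufficient pairs", call. = FALSE)
  va <- stats::var(diffs_a); vb <- stats::var(diffs_b)
  if (va == 0 && vb == 0) stop("degenerate", call. = FALSE)
  if (vb >= va) {
    ft <- stats::var.test(diffs_b, diffs_a)
  } else {
    ft <- stats::var.test(diffs_a, diffs_b)
  }
  tt <- stats::t.test(diffs_a, diffs_b, var.equal = FALSE)
  list(f_statistic = unname(ft$statistic), f_pvalue = ft$p.value,
       t_statistic = unname(tt$statistic), t_pvalue = tt$p.value)
}
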
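#' Paired measurement series
#'
#' Container for two measurement series of the same quantity on the same
#' cases (e.g. automated vs manual maximal aortic diameters).
#'
#' @param auto,manual numeric vectors of equal length (>= 3), finite.
#' @param labels optional case identifiers.
#' @return An `aq_paired` object.
#' @export
paired_measurements <- function(auto, manual, labels = NULL) {
  stopifnot(length(auto) == length(manual), length(auto) >= 3,
            all(is.finite(auto)), all(is.finite(manual)))
  structure(list(auto = as.numeric(auto), manual = as.numeric(manual),
                 labels = labels), class = "aq_paired")
}

.icc_bands <- function(icc) {
  if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good" else "excellent"
}

#' Two-way absolute-agreement single-rater ICC
#'
#' ICC(2,1): from the two-way ANOVA decomposition of the targets-by-raters
#' table, `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2
#' raters, where MSR/MSC/MSE are the mean squares for rows (targets),
#' columns (raters) and error. Interpreted as: below 0.5 poor, 0.5-0.75
#' moderate, 0.75-0.9 good, above 0.9 excellent agreement.
#'
#' @param p an `aq_paired` object.
#' @return List with `icc`, `band`, the mean squares, and a `degenerate`
#'   flag (zero total variance, where the ICC is defined as 1).
#' @export
icc_2_1 <- function(p) {
  stopifnot(inherits(p, "aq_paired"))
  m <- cbind(p$manual, p$auto)
  n <- nrow(m); k <- 2
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total < 1e-12)
    return(list(icc = 1, band = "excellent", degenerate = TRUE,
                msr = 0, msc = 0, mse = 0))
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, band = .icc_bands(icc), degenerate = FALSE,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman analysis
#'
#' Mean bias of `auto - manual` and 95% limits of agreement
#' `bias +/- 1.96 * SD` (sample SD, n - 1 denominator).
#'
#' @param p an `aq_paired` object.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(p) {
  stopifnot(inherits(p, "aq_paired"))
  d <- p$auto - p$manual
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s)
}

# Exact two-sided signed-rank p via the generating-function distribution of
# the positive-rank sum over all 2^n sign assignments. Mid-ranks doubled to
# integers so tied ranks stay exact.
.wilcoxon_exact_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  W2 <- sum(r2[d > 0])
  maxw <- sum(r2)
  dist <- numeric(maxw + 1)  # counts of achievable doubled rank sums
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(maxw + 1 - r)])
    dist <- dist + shifted
  }
  total <- 2^length(d)
  p_ge <- sum(dist[(W2 + 1):(maxw + 1)]) / total
  p_le <- sum(dist[1:(W2 + 1)]) / total
  min(1, 2 * min(p_ge, p_le))
}

#' Wilcoxon matched-pairs signed-rank test and Spearman correlation
#'
#' Zero differences are dropped (flagged); tied absolute differences get
#' mid-ranks. For up to `exact_n` remaining pairs the two-sided p-value is
#' exact over all 2^n sign assignments; beyond that a normal approximation
#' with tie correction and continuity correction is used. Spearman's rho is
#' the Pearson correlation of mid-ranks.
#'
#' @param p an `aq_paired` object.
#' @param exact_n largest n for the exact null distribution.
#' @return List with `wilcoxon_p`, `spearman_r`, `n_used`, `n_zero`,
#'   `all_zero` flag.
#' @export
paired_nonparametrics <- function(p, exact_n = 25) {
  stopifnot(inherits(p, "aq_paired"))
  d <- p$auto - p$manual
  rho <- suppressWarnings(cor(p$auto, p$manual, method = "spearman"))
  nz <- d[d != 0]
  n0 <- length(d) - length(nz)
  if (!length(nz))
    return(list(wilcoxon_p = 1, spearman_r = rho, n_used = 0, n_zero = n0,
                all_zero = TRUE))
  n <- length(nz)
  if (n <= exact_n) {
    pw <- .wilcoxon_exact_p(nz)
  } else {
    r <- rank(abs(nz))
    W <- sum(r[nz > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    pw <- 2 * stats::pnorm(-abs(z))
  }
  list(wilcoxon_p = pw, spearman_r = rho, n_used = n, n_zero = n0,
       all_zero = FALSE)
}

#' Absolute and systematic error summaries
#'
#' The systematic error is `auto - manual` (signed); the absolute error is
#' its magnitude. Both are summarized as median with interquartile range
#' (quartiles by linear interpolation). The differences are also tested
#' against a normal distribution with fitted mean/SD via the
#' Kolmogorov-Smirnov statistic (fitted parameters, so the p-value carries
#' the usual Lilliefors caveat, flagged in the output).
#'
#' @param p an `aq_paired` object.
#' @return List with `abs_error` / `sys_error` (each `median`, `q1`, `q3`),
#'   `normality_p` and `normality_note`.
#' @export
error_summary <- function(p) {
  stopifnot(inherits(p, "aq_paired"))
  d <- p$auto - p$manual
  summ <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3])
  }
  ksp <- tryCatch(
    suppressWarnings(ks.test(d, "pnorm", mean(d), sd(d))$p.value),
    error = function(e) NA_real_)
  list(abs_error = summ(abs(d)), sys_error = summ(d), normality_p = ksp,
       normality_note = "KS against normal with fitted parameters (Lilliefors caveat)")
}

#' Full method-agreement battery for a paired series
#'
#' Bundles [icc_2_1()], [bland_altman()], [paired_nonparametrics()] and
#' [error_summary()] into one `aq_agreement` object.
#'
#' @param p an `aq_paired` object.
#' @return An `aq_agreement` list.
#' @export
agreement_stats <- function(p) {
  icc <- icc_2_1(p)
  ba <- bland_altman(p)
  np <- paired_nonparametrics(p)
  es <- error_summary(p)
  structure(list(
    n = length(p$auto), icc = icc$icc, icc_band = icc$band,
    icc_degenerate = icc$degenerate,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    spearman_r = np$spearman_r, wilcoxon_p = np$wilcoxon_p,
    abs_error = es$abs_error, sys_error = es$sys_error,
    normality_p = es$normality_p), class = "aq_agreement")
}

#' @export
print.aq_agreement <- function(x, ...) {
  cat(sprintf("<aq_agreement> n=%d\n", x$n))
  cat(sprintf("  ICC(2,1) %.3f (%s); Spearman r %.3f; Wilcoxon p %.4g\n",
              x$icc, x$icc_band, x$spearman_r, x$wilcoxon_p))
  cat(sprintf("  bias %.2f mm, LoA [%.2f, %.2f] mm\n", x$bias, x$loa_low,
              x$loa_high))
  cat(sprintf("  abs error %.2f [%.2f-%.2f]; sys error %.2f [%.2f-%.2f] mm\n",
              x$abs_error$median, x$abs_error$q1, x$abs_error$q3,
              x$sys_error$median, x$sys_error$q1, x$sys_error$q3))
  invisible(x)
}

# Clopper-Pearson exact binomial interval.
.clopper_pearson <- function(x, n, alpha = 0.05) {
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic performance with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/total`, each with an exact (Clopper-Pearson) two-sided
#' confidence interval.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @param alpha two-sided error level (default 0.05 for 95% CIs).
#' @return An `aq_diagnostic` list: each metric has `estimate`, `lower`,
#'   `upper` (proportions), or is `NA` with a flag when its denominator is
#'   zero.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn, alpha = 0.05) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  one <- function(x, n) {
    if (n == 0)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  flag = "zero denominator"))
    ci <- .clopper_pearson(x, n, alpha)
    list(estimate = x / n, lower = ci[1], upper = ci[2])
  }
  structure(list(
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = one(tp, tp + fn),
    specificity = one(tn, tn + fp),
    accuracy = one(tp + tn, tp + fp + tn + fn),
    alpha = alpha), class = "aq_diagnostic")
}

#' @export
print.aq_diagnostic <- function(x, ...) {
  fmt <- function(nm) {
    e <- x[[nm]]
    if (is.na(e$estimate)) return(sprintf("  %-12s NA (%s)\n", nm, e$flag))
    sprintf("  %-12s %.1f%% (%.0f%% CI: %.1f-%.1f%%)\n", nm,
            100 * e$estimate, 100 * (1 - x$alpha), 100 * e$lower,
            100 * e$upper)
  }
  cat("<aq_diagnostic>\n", fmt("sensitivity"), fmt("specificity"),
      fmt("accuracy"), sep = "")
  invisible(x)
}
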
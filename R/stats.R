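#' Spearman rank correlation with average ranks and a two-sided p-value
#'
#' Ranks (ties averaged) are correlated with Pearson's formula; the
#' p-value uses the t approximation `t = r sqrt((n-2)/(1-r^2))` on n - 2
#' degrees of freedom (perfect correlations give p = 0).
#'
#' @param x,y paired numeric vectors, n >= 3, finite.
#' @return list `r`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman needs at least 3 finite pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for constant input")
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences `d = a - b`: bias is `mean(d)`, limits of agreement are
#' `bias +/- 1.96 sd(d)`, and a one-sample two-sided t-test reports
#' whether the bias differs from zero.
#'
#' @param a,b paired measurements (method A = candidate, B = reference).
#' @return list `bias`, `loa_low`, `loa_high`, `sd_diff`, `p`, `n`, and
#'   the `differences` / `means` vectors for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("bland_altman: mismatched lengths")
  if (length(a) < 2L) stop("bland_altman needs n >= 2")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  p <- if (s == 0) {
    if (bias == 0) 1 else 0   # degenerate: identical differences
  } else t.test(d)$p.value
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, p = p, n = length(d),
       differences = d, means = (a + b) / 2)
}

#' Mean absolute difference and mean absolute relative error
#'
#' The relative-error denominator is the reference (manual) value `b`;
#' pairs with a zero reference are excluded with a warning. 95% CIs use
#' the normal approximation of the mean and are `NA` for a single pair.
#'
#' @param a,b paired measurements (b = reference).
#' @return list `mean_abs_diff`, `mad_ci`, `mean_abs_rel_err_pct`,
#'   `mare_ci`, `n`, `n_excluded`.
#' @export
abs_error_summary <- function(a, b) {
  if (length(a) != length(b)) stop("abs_error_summary: mismatched lengths")
  d <- abs(a - b)
  zero_ref <- b == 0
  if (any(zero_ref))
    warning(sum(zero_ref), " pair(s) with zero reference excluded from ",
            "relative error")
  rel <- 100 * d[!zero_ref] / abs(b[!zero_ref])
  ci <- function(v) {
    if (length(v) < 2L) return(c(NA_real_, NA_real_))
    mean(v) + c(-1.96, 1.96) * sd(v) / sqrt(length(v))
  }
  list(mean_abs_diff = mean(d), mad_ci = ci(d),
       mean_abs_rel_err_pct = mean(rel), mare_ci = ci(rel),
       n = length(d), n_excluded = sum(zero_ref))
}

#' Per-group summaries and pairwise Mann-Whitney comparisons
#'
#' Reports median and IQR per quality group, pairwise two-sided
#' Mann-Whitney U tests (exact for small tie-free samples, normal
#' approximation with tie correction otherwise — `wilcox.test` defaults),
#' and a Lilliefors-corrected Kolmogorov-Smirnov normality screen per
#' group.
#'
#' @param records data.frame with a `quality_label` column.
#' @param variable column to compare (e.g. `"noise"`, `"snr"`).
#' @return list with `summary` (data.frame: group, n, median, q1, q3,
#'   ks_p) and `pairwise` (data.frame: group1, group2, statistic, p).
#' @export
group_compare <- function(records, variable) {
  stopifnot(variable %in% names(records))
  groups <- split(records[[variable]], records$quality_label)
  groups <- groups[order(match(names(groups), quality_levels))]
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty group")
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    ks_p <- if (length(v) >= 5L && sd(v) > 0)
      tryCatch(nortest::lillie.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(group = g, n = length(v), median = median(v),
               q1 = quantile(v, 0.25, names = FALSE),
               q3 = quantile(v, 0.75, names = FALSE), ks_p = ks_p,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(groups), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    wt <- suppressWarnings(wilcox.test(groups[[g1]], groups[[g2]]))
    data.frame(group1 = g1, group2 = g2,
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairwise = pairwise)
}

#' ROC analysis for detecting non-diagnostic studies
#'
#' AUC by the trapezoidal rule over all thresholds, DeLong 95% CI, and the
#' Youden-optimal cutoff with its sensitivity and specificity (delegated
#' to pROC). `direction` declares how the score relates to the positive
#' class: `"higher"` means larger scores indicate a positive
#' (non-diagnostic) study — appropriate for noise — while `"lower"` fits
#' SNR.
#'
#' @param records data.frame with `quality_label` and the score column.
#' @param variable score column name.
#' @param positive quality label treated as the positive class.
#' @param direction `"higher"` or `"lower"`.
#' @return A `roc_result`: `auc`, `auc_ci` (low, high), `cutoff`,
#'   `sensitivity`, `specificity`, `curve` (data.frame fpr/tpr/threshold),
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(records, variable, positive = "non_diagnostic",
                         direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(variable %in% names(records))
  y <- records$quality_label == positive
  x <- records[[variable]]
  ok <- is.finite(x) & !is.na(y)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2L)
    stop("both classes must be present for ROC analysis")
  r <- pROC::roc(response = y, predictor = x, quiet = TRUE,
                 direction = if (direction == "higher") "<" else ">",
                 levels = c(FALSE, TRUE))
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]   # ties: first Youden-optimal point
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_ci = c(low = ci[1], high = ci[3]),
                 cutoff = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 curve = data.frame(fpr = 1 - r$specificities,
                                    tpr = r$sensitivities,
                                    threshold = r$thresholds),
                 n_pos = sum(y), n_neg = sum(!y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.2f: sens %.0f%%, spec %.0f%% (%d pos / %d neg)\n",
              x$auc, x$auc_ci[["low"]], x$auc_ci[["high"]], x$cutoff,
              100 * x$sensitivity, 100 * x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' SNR implied by a pair of quality thresholds
#'
#' The quotient of an attenuation threshold and a noise threshold, to one
#' decimal: e.g. the conventional "attenuation > 400 HU and noise < 30 HU"
#' rule corresponds to SNR 13.3.
#'
#' @param attenuation_threshold_hu,noise_threshold_hu positive thresholds.
#' @return SNR rounded to one decimal.
#' @export
snr_from_thresholds <- function(attenuation_threshold_hu,
                                noise_threshold_hu) {
  if (noise_threshold_hu <= 0) stop("noise threshold must be positive")
  if (attenuation_threshold_hu <= 0)
    stop("attenuation threshold must be positive")
  round(attenuation_threshold_hu / noise_threshold_hu, 1)
}

#' Correlation of noise and SNR with excluded vessel length
#'
#' Within the `excluded_parts` group, Spearman correlations of the
#' measured noise and SNR against the excluded vessel length and against
#' the excluded fraction (excluded / total length). Records lacking
#' lengths are skipped with their count reported.
#'
#' @param records data.frame with `noise`, `snr`, `excluded_length_mm`,
#'   `total_length_mm` and `quality_label` columns.
#' @return list of `spearman` results (`noise_vs_length`,
#'   `snr_vs_length`, `noise_vs_fraction`, `snr_vs_fraction`), plus
#'   `n_used`, `n_skipped` and `scatter` data for plotting.
#' @export
excluded_fraction_correlation <- function(records) {
  sub <- records[records$quality_label == "excluded_parts" &
                   records$status == "ok", , drop = FALSE]
  has <- is.finite(sub$excluded_length_mm) & is.finite(sub$total_length_mm)
  n_skipped <- sum(!has)
  sub <- sub[has, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 records with excluded lengths")
  if (nrow(sub) < 10L)
    warning("only ", nrow(sub), " records; correlations are unstable")
  frac <- sub$excluded_length_mm / sub$total_length_mm
  list(noise_vs_length = spearman(sub$noise, sub$excluded_length_mm),
       snr_vs_length = spearman(sub$snr, sub$excluded_length_mm),
       noise_vs_fraction = spearman(sub$noise, frac),
       snr_vs_fraction = spearman(sub$snr, frac),
       n_used = nrow(sub), n_skipped = n_skipped,
       scatter = data.frame(snr = sub$snr, noise = sub$noise,
                            excluded_fraction = frac))
}

#' Method-agreement report between automatic and manual measurements
#'
#' For each shared variable (attenuation, noise, snr): Spearman
#' correlation, Bland-Altman bias and limits of agreement, and
#' mean-absolute / relative-error summaries with the manual measurement as
#' the reference.
#'
#' @param auto,manual data.frames with `attenuation`, `noise`, `snr`
#'   columns, paired row-wise.
#' @return named list per variable, each holding `spearman`,
#'   `bland_altman`, `abs_error`.
#' @export
agreement_report <- function(auto, manual) {
  vars <- c("attenuation", "noise", "snr")
  stopifnot(all(vars %in% names(auto)), all(vars %in% names(manual)),
            nrow(auto) == nrow(manual))
  out <- lapply(vars, function(v) {
    a <- auto[[v]]; b <- manual[[v]]
    ok <- is.finite(a) & is.finite(b)
    list(spearman = spearman(a[ok], b[ok]),
         bland_altman = bland_altman(a[ok], b[ok]),
         abs_error = abs_error_summary(a[ok], b[ok]))
  })
  names(out) <- vars
  out
}
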
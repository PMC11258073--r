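test_that("spearman matches rank-then-Pearson and handles extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman(x, x * 2 + 1)$r, 1)
  expect_equal(spearman(x, rev(x))$r, -1)
  expect_equal(spearman(x, x * 2)$p, 0)
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10) + a
  # independent oracle: explicit average ranks, then Pearson
  brute <- cor(rank(a, ties.method = "average"),
               rank(b, ties.method = "average"))
  expect_equal(spearman(a, b)$r, brute, tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 2:1), "at least 3")
})

test_that("bland_altman reproduces hand-computed limits of agreement", {
  a <- c(2, 4, 6, 8)
  expect_identical(bland_altman(a, a)$bias, 0)
  expect_identical(bland_altman(a, a)$loa_low, 0)
  # d = {1, 1, 1, 3}: bias 1.5, sd 1, LoA 1.5 -/+ 1.96
  b <- a - c(1, 1, 1, 3)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 1.5)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 1.5 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.5 + 1.96, tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  # constant offset: zero-width limits
  ba2 <- bland_altman(a + 3, a)
  expect_equal(ba2$bias, 3)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)
  expect_error(bland_altman(1:3, 1:4), "mismatched")
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(20)
  b <- rnorm(200, 35, 5)
  a <- b + rnorm(200, 1, 2)
  ba <- bland_altman(a, b)
  inside <- mean(ba$differences >= ba$loa_low &
                   ba$differences <= ba$loa_high)
  # binomial tolerance at n = 200: 3 sd of sqrt(.95*.05/200) ~ 0.046
  expect_gt(inside, 0.95 - 0.047)
})

test_that("absolute-error summaries follow their hand oracle", {
  ae <- abs_error_summary(c(11, 33), c(10, 30))
  expect_equal(ae$mean_abs_diff, 2)
  expect_equal(ae$mean_abs_rel_err_pct, 10)
  expect_identical(abs_error_summary(1:4, 1:4)$mean_abs_diff, 0)
  expect_true(all(is.na(abs_error_summary(5, 4)$mad_ci)))
  expect_warning(abs_error_summary(c(1, 2), c(0, 2)), "zero reference")
})

test_that("group comparisons report medians, IQRs and exact U tests", {
  rec <- data.frame(
    quality_label = rep(c("fully_diagnostic", "non_diagnostic"),
                        each = 3),
    noise = c(1, 2, 3, 11, 12, 13))
  gc <- group_compare(rec, "noise")
  expect_equal(gc$summary$median, c(2, 12))
  # complete separation at n = 3 vs 3: U = 0, exact two-sided p = 0.1
  expect_equal(gc$pairwise$statistic, 0)
  expect_equal(gc$pairwise$p, 2 / choose(6, 3), tolerance = 1e-12)

  rec2 <- data.frame(quality_label = rep(c("a", "b"), each = 20),
                     noise = rep(c(5, 5.5), 20))
  gc2 <- group_compare(rec2, "noise")
  expect_gt(gc2$pairwise$p, 0.5)   # near-identical groups
  expect_error(group_compare(rec[0, ], "noise"), "two groups")
})

test_that("null p-values are approximately uniform across seeds", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    wilcox.test(rnorm(30), rnorm(30), exact = FALSE)$p.value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))  # near-ties across seeds
  expect_gt(ks$p.value, 0.01)
})

test_that("AUC equals the concordant-pair fraction and CIs make sense", {
  rec <- data.frame(
    quality_label = rep(c("non_diagnostic", "fully_diagnostic"),
                        each = 6),
    noise = c(40, 44, 38, 35, 47, 41, 30, 34, 36, 29, 38, 33))
  r <- roc_analysis(rec, "noise", direction = "higher")
  # brute-force Mann-Whitney counting oracle (ties count 1/2)
  pos <- rec$noise[rec$quality_label == "non_diagnostic"]
  neg <- rec$noise[rec$quality_label != "non_diagnostic"]
  conc <- mean(outer(pos, neg, function(p, n)
    (p > n) + 0.5 * (p == n)))
  expect_equal(r$auc, conc, tolerance = 1e-9)
  expect_true(r$auc_ci[["low"]] <= r$auc && r$auc <= r$auc_ci[["high"]])

  # perfect separation: AUC 1 with sens/spec 100% at the Youden cutoff
  rec2 <- data.frame(quality_label = rep(c("non_diagnostic", "x"),
                                         each = 4),
                     noise = c(50, 51, 52, 53, 10, 11, 12, 13))
  # pROC warns that the DeLong CI of a perfect AUC is degenerate
  r2 <- suppressWarnings(roc_analysis(rec2, "noise", direction = "higher"))
  expect_equal(r2$auc, 1)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)

  # all scores equal: chance performance
  rec3 <- data.frame(quality_label = rep(c("non_diagnostic", "x"), 5),
                     noise = rep(7, 10))
  expect_equal(roc_analysis(rec3, "noise")$auc, 0.5)
  expect_error(roc_analysis(rec3[rec3$quality_label == "x", ], "noise"),
               "both classes")
})

test_that("flipping the score direction mirrors the AUC", {
  set.seed(5)
  rec <- data.frame(
    quality_label = sample(c("non_diagnostic", "fully_diagnostic"),
                           40, replace = TRUE),
    s = rnorm(40))
  up <- roc_analysis(rec, "s", direction = "higher")$auc
  down <- roc_analysis(rec, "s", direction = "lower")$auc
  expect_equal(up + down, 1, tolerance = 1e-12)
})

test_that("threshold arithmetic gives the conventional SNR values", {
  expect_identical(snr_from_thresholds(400, 30), 13.3)
  expect_identical(snr_from_thresholds(450, 30), 15)
  expect_identical(snr_from_thresholds(7, 7), 1)
  expect_error(snr_from_thresholds(400, 0), "positive")
})

test_that("excluded-fraction correlations recover the generator's signs", {
  coh <- generate_cohort(150, seed = 17, base_spec = toy_phantom_spec(),
                         label_proportions = c(0.2, 0.7, 0.1))
  recs <- run_cohort(coh)
  ec <- excluded_fraction_correlation(recs)
  expect_gt(ec$noise_vs_fraction$r, 0)
  expect_lt(ec$snr_vs_fraction$r, 0)
  expect_lt(ec$noise_vs_fraction$p, 0.05)
  expect_identical(ec$n_used + ec$n_skipped,
                   sum(recs$quality_label == "excluded_parts"))
})

test_that("agreement reports combine the three analyses per variable", {
  set.seed(9)
  manual <- data.frame(attenuation = rnorm(30, 500, 40),
                       noise = rnorm(30, 35, 5))
  manual$snr <- manual$attenuation / manual$noise
  auto <- manual
  auto$noise <- manual$noise + rnorm(30, 1, 1.5)
  auto$snr <- auto$attenuation / auto$noise
  rep <- agreement_report(auto, manual)
  expect_named(rep, c("attenuation", "noise", "snr"))
  expect_gt(rep$noise$spearman$r, 0.8)
  expect_equal(rep$attenuation$bland_altman$bias, 0)
  expect_gt(rep$noise$abs_error$mean_abs_rel_err_pct, 0)
})
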
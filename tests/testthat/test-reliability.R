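test_that("ANOVA decomposition matches definitional sums of squares", {
  x <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  d <- anova_decompose(x)
  o <- oracle_ms(x)
  expect_equal(d$ms_rows, o$msr, tolerance = 1e-12)
  expect_equal(d$ms_cols, o$msc, tolerance = 1e-12)
  expect_equal(d$ms_error, o$mse, tolerance = 1e-12)

  same <- cbind(1:5, 1:5)
  ds <- anova_decompose(same)
  expect_equal(ds$ms_cols, 0)
  expect_equal(ds$ms_error, 0)

  shifted <- cbind(1:5, 1:5 + 3)
  dsh <- anova_decompose(shifted)
  expect_equal(dsh$ms_error, 0)
  expect_gt(dsh$ms_cols, 0)

  expect_error(anova_decompose(cbind(1:2, 2:3)), "at least 3")
})

test_that("absolute-agreement ICC penalizes systematic shifts", {
  perfect <- anova_decompose(cbind(1:6, 1:6))
  expect_equal(icc_absolute_agreement(perfect), 1)

  shifted <- anova_decompose(cbind(1:6, 1:6 + 2))
  icc_abs <- icc_absolute_agreement(shifted)
  # consistency-type ICC ignores the column variance
  icc_cons <- with(shifted, (ms_rows - ms_error) / (ms_rows + ms_error))
  expect_lt(icc_abs, icc_cons)

  allsame <- anova_decompose(cbind(rep(2, 4), rep(2, 4)))
  expect_warning(v <- icc_absolute_agreement(allsame), "identical")
  expect_equal(v, 1)
})

test_that("paired practice test flags significant improvement", {
  same <- cbind(1:10, 1:10)
  expect_warning(pt <- practice_test(same), "zero variance")
  expect_equal(pt$t_stat, 0)
  expect_false(pt$practice_effect)

  set.seed(30)
  x1 <- rnorm(240, 34.8, 9.4)
  x2 <- x1 - 2.35 + rnorm(240, 0, 6)   # clear retest improvement
  pt2 <- practice_test(cbind(x1, x2))
  # closed-form paired t on the same numbers
  d <- x1 - x2
  expect_equal(pt2$t_stat, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
  expect_equal(pt2$df, 239)
  expect_true(pt2$practice_effect)

  # small shift relative to spread: no practice effect
  set.seed(31)
  y1 <- rnorm(240, 308.9, 44.6)
  y2 <- y1 + 1.6 + rnorm(240, 0, 36)
  expect_false(practice_test(cbind(y1, y2))$practice_effect)
})

test_that("SEM and SDC follow the measurement-error formulas", {
  d0 <- anova_decompose(cbind(1:5, 1:5))
  expect_equal(sem_from_decomp(d0), 0)

  d <- list(ms_error = 22.6576)
  expect_equal(sem_from_decomp(d), 4.76)

  x <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(sem_from_decomp(anova_decompose(x)), sqrt(oracle_ms(x)$mse))

  expect_equal(sdc(0), 0)
  expect_equal(sdc(0.90), 2.494672, tolerance = 1e-6)
  expect_equal(sdc(4.76), 13.19404, tolerance = 1e-5)
  expect_error(sdc(-1), ">= 0")
})

test_that("group SDC divides by sqrt(n) and adds practice-effect shifts", {
  expect_equal(round(sdc_group(0.90, 242, practice_effect = FALSE), 2), 0.16)
  expect_equal(round(sdc_group(4.76, 240, 34.83, 32.48, TRUE), 2), 1.00)
  expect_equal(sdc_group(0, 1, practice_effect = FALSE), 0)

  # decreasing in n, increasing in sem
  set.seed(41)
  for (i in 1:20) {
    s <- runif(1, 0.1, 10)
    n <- sample(2:500, 1)
    expect_gt(sdc_group(s, n), sdc_group(s, n + 10))
    expect_lt(sdc_group(s, n), sdc_group(s * 1.5, n))
  }
})

test_that("retest correlation picks the method from the distributions", {
  lin <- cbind(1:20, 2 * (1:20) + 3)
  expect_equal(retest_correlation(lin, "pearson")$corr, 1)
  expect_equal(retest_correlation(lin, "spearman")$corr, 1)

  x <- seq(-3, 3, length.out = 50)
  mono <- cbind(x, x^3)
  expect_equal(retest_correlation(mono, "spearman")$corr, 1)
  expect_lt(retest_correlation(mono, "pearson")$corr, 1)

  set.seed(52)
  z1 <- rnorm(2000)
  z2 <- 0.75 * z1 + sqrt(1 - 0.75^2) * rnorm(2000)
  est <- retest_correlation(cbind(z1, z2), "pearson")
  expect_equal(est$corr, 0.75, tolerance = 0.03)

  # heavily skewed scores push auto-selection to Spearman
  sk <- cbind(exp(rnorm(200)), exp(rnorm(200)))
  expect_equal(retest_correlation(sk, "auto")$corr_type, "spearman")

  expect_warning(r0 <- retest_correlation(cbind(rep(1, 5), 1:5)), "variance")
  expect_true(is.na(r0$corr))
})

test_that("SEM never exceeds the pooled occasion SD when ICC >= 0", {
  set.seed(60)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    rho <- runif(1)
    u <- rnorm(n)
    x <- cbind(sqrt(rho) * u + sqrt(1 - rho) * rnorm(n),
               sqrt(rho) * u + sqrt(1 - rho) * rnorm(n))
    d <- anova_decompose(x)
    if (icc_absolute_agreement(d) >= 0) {
      pooled <- sqrt((stats::var(x[, 1]) + stats::var(x[, 2])) / 2)
      expect_lte(sem_from_decomp(d), pooled + 1e-9)
    }
  }
})

test_that("reliability report uses pairwise-complete, raw-scale data", {
  co <- quick_cohort(n = 120, seed = 14, measure = "BoxTapping",
                     zero_score_rate = 0)
  bat <- default_acs_battery()
  tab <- co$scores
  # exclude one participant at occasion 2 only
  tab$excluded[tab$participant_id == "P0005" & tab$occasion == 2] <- TRUE
  tab$exclusion_reason[tab$participant_id == "P0005" &
                         tab$occasion == 2] <- "manual"
  rep1 <- reliability_report(tab, bat, include_composite = FALSE)
  expect_equal(rep1$n_pairs, 119)
  expect_equal(rep1$sdc, 1.96 * sqrt(2) * rep1$sem, tolerance = 1e-12)
  rep2 <- reliability_report(tab, bat, include_composite = FALSE)
  expect_identical(rep1, rep2)  # deterministic given input

  only1 <- tab[tab$occasion == 1, ]
  expect_error(reliability_report(only1, bat), "both occasions")
})
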
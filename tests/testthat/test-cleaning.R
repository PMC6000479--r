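test_that("mad_limits matches hand-computed limits and flags the outlier", {
  cfg <- outlier_config(mad_multiplier = 3.5, consistency_constant = 1)
  lim <- mad_limits(c(30, 31, 32, 33, 200), cfg)
  expect_equal(lim$median, 32)
  expect_equal(lim$mad, 1)
  expect_equal(lim$lower, 28.5)
  expect_equal(lim$upper, 35.5)
  expect_true(200 > lim$upper)
})

test_that("mad_limits handles degenerate and one-sided cases", {
  expect_warning(lim <- mad_limits(c(5, 5, 5, 5)), "MAD is zero")
  expect_equal(lim$lower, 5)
  expect_equal(lim$upper, 5)
  expect_true(lim$degenerate)

  expect_error(mad_limits(c(1, 2)), "at least 3")

  one <- mad_limits(c(1, 2, 3, 4, 100),
                    outlier_config(two_sided = FALSE))
  expect_identical(one$lower, -Inf)

  sym <- mad_limits(c(-3, -1, 0, 1, 3))
  expect_equal(sym$lower, -sym$upper)
})

make_clean_fixture <- function() {
  # 8 participants, two measures: TimeA (MAD rule), CountB (zero rule)
  demo <- demographics(sprintf("P%d", 1:8),
                       age = c(25, 30, 35, 38, 45, 50, 55, 62),
                       gender = rep(0:1, 4), education = rep(0L, 8))
  rows <- expand.grid(participant_id = sprintf("P%d", 1:8),
                      occasion = 1:2, measure = c("TimeA", "CountB"),
                      stringsAsFactors = FALSE)
  rows$raw_score <- ifelse(rows$measure == "TimeA", 30, 10) +
    seq_len(nrow(rows)) %% 5
  score_table(rows)
}

test_that("zero rule applies only to zero-is-invalid measures", {
  tab <- make_clean_fixture()
  tab$raw_score[tab$participant_id == "P1" & tab$measure == "CountB" &
                  tab$occasion == 1] <- 0
  tab$raw_score[tab$participant_id == "P2" & tab$measure == "TimeA" &
                  tab$occasion == 1] <- 0  # NOT zero rule: MAD territory
  demo <- demographics(sprintf("P%d", 1:8),
                       age = c(25, 30, 35, 38, 45, 50, 55, 62),
                       gender = rep(0:1, 4))
  res <- suppressWarnings(
    apply_outlier_rules(score_table(tab), demo, tiny_battery()))
  out <- res$scores
  expect_equal(out$exclusion_reason[out$participant_id == "P1" &
                 out$measure == "CountB" & out$occasion == 1], "zero_score")
  reason_p2 <- out$exclusion_reason[out$participant_id == "P2" &
                 out$measure == "TimeA" & out$occasion == 1]
  expect_false(reason_p2 == "zero_score")
})

test_that("participants without age stop the MAD rule with names", {
  tab <- make_clean_fixture()
  demo <- demographics(sprintf("P%d", 1:8), age = c(NA, 30, 35, 38, 45, 50,
                                                    55, 62),
                       gender = rep(0L, 8))
  expect_error(apply_outlier_rules(tab, demo, tiny_battery()), "P1")
})

test_that("MAD flags match a brute-force per-group oracle on random data", {
  set.seed(77)
  cfg <- outlier_config()
  bat <- tiny_battery()
  for (rep in 1:5) {
    n <- 40
    demo <- demographics(sprintf("P%d", 1:n),
                         age = runif(n, 18, 81), gender = rbinom(n, 1, .5))
    rows <- expand.grid(participant_id = demo$participant_id,
                        occasion = 1:2, measure = "TimeA",
                        stringsAsFactors = FALSE)
    rows$raw_score <- exp(rnorm(nrow(rows), 3.5, 0.3))  # skewed times
    tab <- score_table(rows)
    res <- suppressWarnings(apply_outlier_rules(tab, demo, bat, cfg))

    # oracle: recompute limits per occasion x age group by sorting and
    # direct median arithmetic
    grp <- cut(demo$age[match(rows$participant_id, demo$participant_id)],
               c(-Inf, 41, 60, Inf), right = FALSE)
    expected_flag <- rep(FALSE, nrow(rows))
    for (occ in 1:2) for (g in levels(grp)) {
      sel <- which(rows$occasion == occ & grp == g)
      if (length(sel) < 3) next
      v <- sort(rows$raw_score[sel])
      med <- stats::median(v)
      madv <- stats::median(sort(abs(v - med)))
      hw <- 3.5 * 1.4826 * madv
      expected_flag[sel] <- rows$raw_score[sel] < med - hw |
        rows$raw_score[sel] > med + hw
    }
    expect_equal(res$scores$excluded, expected_flag)
  }
})

test_that("cleaning is idempotent and monotone in the multiplier", {
  co <- quick_cohort(n = 150, seed = 3, measure = "ConnectTheDotsI",
                     outlier_rate = 0.03)
  bat <- default_acs_battery()
  res1 <- suppressWarnings(
    apply_outlier_rules(co$scores, co$demographics, bat))
  res2 <- suppressWarnings(
    apply_outlier_rules(res1$scores, co$demographics, bat))
  expect_identical(res1$scores$excluded, res2$scores$excluded)

  loose <- suppressWarnings(apply_outlier_rules(
    co$scores, co$demographics, bat, outlier_config(mad_multiplier = 5)))
  expect_lte(sum(loose$scores$excluded), sum(res1$scores$excluded))

  # raw values of flagged rows are preserved
  flagged <- res1$scores$excluded
  expect_identical(res1$scores$raw_score[flagged],
                   co$scores$raw_score[flagged])
})
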
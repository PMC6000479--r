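# shared fixtures and independent oracles, built in code

tiny_battery <- function() {
  as_battery(list(
    measure_spec("TimeA", "lower_is_better", "inverse", unit = "seconds",
                 in_composite = TRUE),
    measure_spec("CountB", "higher_is_better", "none", zero_is_invalid = TRUE,
                 in_composite = TRUE, unit = "words")
  ))
}

# brute-force two-way ANOVA mean squares from the definitional sums of
# squares, written as explicit loops (independent of the package's
# vectorized decomposition)
oracle_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(x[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(x[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  }
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)))
}

# a small wide-format CSV on disk; returns the path
write_wide_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "wide_scores.csv")
  writeLines(c(
    "participant_id,TimeA_1,TimeA_2,CountB_1,CountB_2",
    "P1,30.5,29.1,12,14",
    "P2,41.2,38.0,9,11"
  ), path)
  path
}

# quick single-measure cohort for pipeline tests
quick_cohort <- function(n = 200, seed = 1, measure = "BoxTapping",
                         target_icc = NULL, practice_shift = NULL,
                         outlier_rate = 0, zero_score_rate = 0, ...) {
  cfg <- simulation_config(
    n_participants = n, seed = seed,
    models = default_generating_models()[measure],
    target_icc = target_icc,
    practice_shift = practice_shift,
    outlier_rate = outlier_rate, zero_score_rate = zero_score_rate,
    calib_draws = 5e4, ...)
  simulate_cohort(cfg)
}
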
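test_that("predicted scores evaluate the published regression equations", {
  models <- acs_norm_models()
  ctd1 <- models$ConnectTheDotsI
  expect_equal(round(predicted_score(ctd1, data.frame(age = 55, gender = 0)),
                     2), -0.39)
  # at the centering age and reference categories, prediction = constant
  expect_equal(predicted_score(ctd1, data.frame(age = 49.19, gender = 0)),
               ctd1$coefficients$constant)
  tot <- models$TotalScore
  expect_equal(predicted_score(tot, data.frame(age = 49.19, gender = 1,
                                               education = 0)),
               0.068 + 0.120)
  expect_error(predicted_score(ctd1, data.frame(age = 55)), "gender")
  expect_error(predicted_score(tot, data.frame(age = NA, gender = 0,
                                               education = 0)), "age")
})

test_that("predicted_score is linear in each demographic input", {
  m <- acs_norm_models()$TotalScore
  base <- data.frame(age = 49.19, gender = 0, education = 0)
  for (fld in c("gender", "education")) {
    d0 <- base; d1 <- base; d2 <- base
    d1[[fld]] <- 1; d2[[fld]] <- 2
    p <- c(predicted_score(m, d0), predicted_score(m, d1),
           predicted_score(m, d2))
    expect_equal(p[3] - p[2], p[2] - p[1], tolerance = 1e-12)
  }
  # age enters linearly + quadratically; second differences are constant
  ages <- data.frame(age = c(30, 40, 50, 60), gender = 0, education = 0)
  p <- predicted_score(m, ages)
  expect_equal(diff(diff(p))[1], diff(diff(p))[2], tolerance = 1e-10)
})

test_that("norm_score reproduces the published worked example", {
  m <- acs_norm_models()$ConnectTheDotsI
  ns <- norm_score(m, 60, data.frame(age = 55, gender = 0))
  expect_equal(round(ns$z_actual, 2), -1.73)
  expect_equal(round(ns$z_predicted, 2), -0.39)
  # full-precision chain: (z_actual - z_predicted) / 0.819
  expect_equal(ns$norm, (ns$z_actual - ns$z_predicted) / 0.819,
               tolerance = 1e-12)
  expect_equal(ns$norm, -1.634677, tolerance = 1e-5)
  # the published report rounds each step to 2 decimals before chaining
  stepwise <- (round(ns$z_actual, 2) - round(ns$z_predicted, 2)) / 0.819
  expect_equal(round(stepwise, 2), -1.64)

  # a raw score sitting exactly at the demographic expectation norms to 0
  pred <- predicted_score(m, data.frame(age = 55, gender = 0))
  raw_at_pred <- 1 / (pred * m$ref_sd_transformed + m$ref_mean_transformed)
  ns0 <- norm_score(m, raw_at_pred, data.frame(age = 55, gender = 0))
  expect_equal(ns0$norm, 0, tolerance = 1e-9)

  # models without reference constants refuse to norm-score
  expect_error(norm_score(acs_norm_models()$BoxTapping, 9,
                          data.frame(age = 55, gender = 0)),
               "reference constants")
})

test_that("pruning removes noise predictors and keeps real ones", {
  set.seed(71)
  n <- 500
  demo <- demographics(sprintf("P%d", 1:n), age = runif(n, 18, 81),
                       gender = rbinom(n, 1, 0.4),
                       education = rbinom(n, 1, 0.3))
  spec <- list(name = "Noise", direction = "higher_is_better",
               transform = "none")
  # pure noise: everything pruned, residual SD ~ 1
  z <- rnorm(n)
  z <- (z - mean(z)) / sd(z)
  f <- fit_norm_model(z, demo, spec, config = fit_config())
  expect_equal(nrow(f$diagnostics$predictors), 0)
  expect_setequal(f$diagnostics$pruned,
                  c("age", "age_squared", "gender", "education"))
  expect_equal(f$model$sd_residual, 1, tolerance = 0.02)
  expect_named(f$model$coefficients, "constant")

  # quadratic age effect only
  agec <- demo$age - mean(demo$age)
  z2 <- -0.002 * agec^2 + rnorm(n, 0, 0.8)
  f2 <- fit_norm_model(z2, demo, spec, config = fit_config())
  kept <- f2$diagnostics$predictors$predictor
  expect_true("age_squared" %in% kept)
  expect_false(any(c("gender", "education") %in% kept))

  expect_error(fit_norm_model(rep(0.5, n), demo, spec), "constant")
  expect_error(fit_norm_model(z[1:20], demo[1:20, ], spec),
               "10 participants per candidate predictor")
})

test_that("norm models recover the generating demographic effects", {
  bat <- default_acs_battery()
  gen <- default_generating_models()$ConnectTheDotsI
  cfg <- simulation_config(n_participants = 2500, seed = 72,
                           models = default_generating_models()["ConnectTheDotsI"],
                           outlier_rate = 0, zero_score_rate = 0,
                           calib_draws = 5e4)
  co <- simulate_cohort(cfg)
  fitted <- fit_norm_models(co$scores, co$demographics, bat,
                            age_center = 49.19)
  m <- fitted$models$ConnectTheDotsI
  d <- fitted$diagnostics$ConnectTheDotsI$predictors
  for (nm in c("age", "gender")) {
    expect_lt(abs(m$coefficients[[nm]] - gen$coefficients[[nm]]),
              3 * d$se_beta[d$predictor == nm])
  }
  expect_equal(m$sd_residual, gen$sd_residual, tolerance = 0.08)
  expect_true(all(d$vif < 10))
  # age was centered, so the linear and quadratic terms stay independent
  expect_equal(m$age_center, 49.19)
})

test_that("score_battery scores measures and the composite together", {
  bat <- default_acs_battery()
  cfg <- simulation_config(n_participants = 300, seed = 73,
                           outlier_rate = 0, zero_score_rate = 0,
                           calib_draws = 4e4)
  co <- simulate_cohort(cfg)
  fitted <- fit_norm_models(co$scores, co$demographics, bat)
  demo1 <- co$demographics[1, , drop = FALSE]
  sub <- co$scores[co$scores$participant_id == demo1$participant_id &
                     co$scores$occasion == 1, ]
  raws <- stats::setNames(sub$raw_score, sub$measure)

  scored <- score_battery(fitted$models, raws, demo1, bat)
  expect_equal(nrow(scored), 12)  # 11 measures + derived total
  expect_true("TotalScore" %in% scored$measure)

  # drop one composite component: its norm and the total disappear
  scored2 <- score_battery(fitted$models, raws[names(raws) != "BoxTapping"],
                           demo1, bat)
  expect_false("TotalScore" %in% scored2$measure)
  expect_false("BoxTapping" %in% scored2$measure)
  expect_equal(nrow(scored2), 10)

  # unknown measure is reported, the rest still scored
  expect_warning(
    scored3 <- score_battery(fitted$models, c(raws, Mystery = 1), demo1, bat),
    "Mystery")
  expect_equal(nrow(scored3), 12)
})
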
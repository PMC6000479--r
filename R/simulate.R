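`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default generating models for the synthetic cohort
#'
#' One generating model per test measure: the published demographic
#' regression coefficients and residual SDs, the measure's transform, and
#' transformed-scale reference constants. Reference constants are
#' published only for Connect the Dots I; for all other measures the
#' constants here are synthetic, derived by the delta method from the
#' reference study's raw occasion-1 means and SDs so that simulated raw
#' scores land on a realistic scale. Wordlist Recognition, which has no
#' published demographic model (ceiling effect), is generated as
#' intercept-only with unit residual SD; its true ceiling/discreteness is
#' not emulated.
#'
#' @return Named list of `acs_norm_model` objects usable as generators.
#' @export
default_generating_models <- function() {
  models <- acs_norm_models()
  models$TotalScore <- NULL
  synth_ref <- list(
    # measure = c(ref_mean_transformed, ref_sd_transformed)  [synthetic]
    ConnectTheDotsII = c(-1.76380, 0.13800),
    WordlistLearning = c(52.02, 10.13),
    WordlistDelayedRecall = c(11.15, 2.71),
    ReactionSpeed = c(0.0032375, 0.0004672),
    PlaceTheBeads = c(-5.06260, 1.38560),
    BoxTapping = c(9.17, 2.26),
    FillTheGrid = c(0.0159770, 0.0032393),
    DigitSequencesI = c(10.40, 2.22),
    DigitSequencesII = c(8.50, 2.72),
    WordlistRecognition = c(44.17, 1.57)
  )
  models$WordlistRecognition <- norm_model(
    "WordlistRecognition", "higher_is_better", "none",
    ref_mean_transformed = NA_real_, ref_sd_transformed = NA_real_,
    age_center = 49.19, coefficients = list(constant = 0),
    sd_residual = 1, n_reference = 242L)
  for (m in names(synth_ref)) {
    models[[m]]$ref_mean_transformed <- synth_ref[[m]][1]
    models[[m]]$ref_sd_transformed <- synth_ref[[m]][2]
  }
  models
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a two-occasion
#' reference cohort of Dutch adults (default n = 250, ages normal with
#' mean 49.2 and SD 13 truncated to 18-81 years, 63.3% female, 71% high
#' education), scores following the demographic generating models with
#' their residual variance split into a stable person component and
#' occasion noise, occasion-2 practice shifts in raw units, and
#' measurement structure calibrated so that the population
#' absolute-agreement ICC of the (MAD-cleaned) raw scores matches each
#' measure's target.
#'
#' @param n_participants Cohort size (>= 2).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution.
#' @param p_female Probability of gender code 0.
#' @param p_high_education Probability of high education (Verhage 6-7).
#' @param models Named list of generating models
#'   (default [default_generating_models()]).
#' @param practice_shift Named raw-unit mean occasion-2 changes
#'   (occasion-2 mean minus occasion-1 mean); defaults to the reference
#'   study's observed shifts.
#' @param target_icc Named absolute-agreement ICC targets in (0, 1];
#'   defaults to the reference study's values.
#' @param outlier_rate Per-row probability of an injected extreme value on
#'   time-based measures.
#' @param zero_score_rate Per-row probability of an injected zero on
#'   zero-is-invalid measures.
#' @param outlier_displacement Injected outliers are displaced away from
#'   their age group's median by this many scaled MADs (default 5, beyond
#'   the default 3.5 limit).
#' @param calib_draws Monte Carlo size of the ICC calibration.
#' @param mad_config [outlier_config()] used both for calibration and for
#'   outlier injection geometry.
#' @param battery Battery definition.
#' @return An `acs_sim_config` list.
#' @export
simulation_config <- function(n_participants = 250, seed = NULL,
                              age_mean = 49.2, age_sd = 13,
                              age_range = c(18, 81),
                              p_female = 0.633, p_high_education = 0.71,
                              models = default_generating_models(),
                              practice_shift = NULL, target_icc = NULL,
                              outlier_rate = 0.02, zero_score_rate = 0.02,
                              outlier_displacement = 5,
                              calib_draws = 2e5,
                              mad_config = outlier_config(),
                              battery = default_acs_battery()) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (p_female < 0 || p_female > 1 || p_high_education < 0 ||
      p_high_education > 1) stop("probabilities must be in [0, 1]")
  if (age_range[1] >= age_range[2]) stop("degenerate age range")
  default_shift <- c(
    ConnectTheDotsI = -2.35, ConnectTheDotsII = -3.10,
    WordlistLearning = 6.09, WordlistDelayedRecall = 0.94,
    WordlistRecognition = 0.14, ReactionSpeed = 1.61,
    PlaceTheBeads = -4.09, BoxTapping = 0.53, FillTheGrid = -1.86,
    DigitSequencesI = 0.21, DigitSequencesII = 0.28)
  default_icc <- c(
    ConnectTheDotsI = 0.67, ConnectTheDotsII = 0.71,
    WordlistLearning = 0.59, WordlistDelayedRecall = 0.50,
    WordlistRecognition = 0.70, ReactionSpeed = 0.67,
    PlaceTheBeads = 0.45, BoxTapping = 0.49, FillTheGrid = 0.80,
    DigitSequencesI = 0.54, DigitSequencesII = 0.64)
  practice_shift <- practice_shift %||% default_shift
  target_icc <- target_icc %||% default_icc
  if (any(target_icc <= 0 | target_icc > 1)) {
    stop("target_icc values must be in (0, 1]")
  }
  structure(list(
    n_participants = as.integer(n_participants), seed = seed,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_female = p_female, p_high_education = p_high_education,
    models = models, practice_shift = practice_shift,
    target_icc = target_icc, outlier_rate = outlier_rate,
    zero_score_rate = zero_score_rate,
    outlier_displacement = outlier_displacement,
    calib_draws = calib_draws, mad_config = mad_config,
    battery = as_battery(battery)
  ), class = "acs_sim_config")
}

#' Simulate reference-cohort demographics
#'
#' Seeded, reproducible draws: truncated-normal ages (inverse-CDF
#' sampling), Bernoulli gender and education. Verhage codes are sampled
#' uniformly within the high (6-7) and medium (3-5) bands consistent with
#' the binary code.
#'
#' @param config An [simulation_config()].
#' @param .set_seed Internal; [simulate_cohort()] seeds once for the whole
#'   cohort and disables per-stage seeding.
#' @return An `acs_demographics` table.
#' @export
simulate_demographics <- function(config = simulation_config(),
                                  .set_seed = TRUE) {
  if (.set_seed && !is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  gender <- as.integer(stats::runif(n) >= config$p_female)
  high <- stats::runif(n) < config$p_high_education
  verhage <- ifelse(high, sample(6:7, n, replace = TRUE),
                    sample(3:5, n, replace = TRUE))
  demographics(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age, gender = gender, verhage = verhage,
    age_range = config$age_range)
}

# population absolute-agreement ICC of (optionally MAD-cleaned) raw pairs,
# as a function of the person-share lambda of the residual variance.
# Monte Carlo with common random numbers; monotone increasing in lambda.
calibrate_split <- function(pred, v, target, shift, gm, grp, config) {
  draws <- config$calib_draws
  idx <- rep_len(seq_along(pred), draws)
  zp <- stats::rnorm(draws)
  ze1 <- stats::rnorm(draws)
  ze2 <- stats::rnorm(draws)
  info <- as_measure_info(gm)
  spec_bat <- battery_row(config$battery, gm$measure)
  apply_mad <- isTRUE(spec_bat$time_based)
  g <- droplevels(grp[idx])

  pop_icc <- function(lambda) {
    u <- pred[idx] + sqrt(lambda * v) * zp
    t1 <- (u + sqrt((1 - lambda) * v) * ze1) * gm$ref_sd_transformed +
      gm$ref_mean_transformed
    t2 <- (u + sqrt((1 - lambda) * v) * ze2) * gm$ref_sd_transformed +
      gm$ref_mean_transformed
    ok <- transform_image_ok(t1, info) & transform_image_ok(t2, info)
    r1 <- inverse_transform(t1[ok], info)
    r2 <- clamp_raw(inverse_transform(t2[ok], info) + shift, info)
    gk <- g[ok]
    if (apply_mad) {
      keep <- rep(TRUE, length(r1))
      for (lev in levels(gk)) {
        sel <- which(gk == lev)
        if (length(sel) < 3) next
        for (r in list(r1, r2)) {
          lim <- suppressWarnings(mad_limits(r[sel], config$mad_config))
          if (!lim$degenerate) {
            keep[sel[r[sel] < lim$lower | r[sel] > lim$upper]] <- FALSE
          }
        }
      }
      r1 <- r1[keep]; r2 <- r2[keep]
    }
    icc_absolute_agreement(anova_decompose(cbind(r1, r2)))
  }

  f1 <- pop_icc(1)
  if (target >= f1) {
    if (target - f1 < 0.005) return(1)
    stop("target ICC ", target, " for ", gm$measure,
         " is infeasible with the requested practice shift; ",
         "maximum attainable is about ", round(f1, 3))
  }
  f0 <- pop_icc(0)
  if (target <= f0) {
    if (f0 - target < 0.005) return(0)
    stop("target ICC ", target, " for ", gm$measure,
         " is below the demographic-effect floor of about ", round(f0, 3))
  }
  stats::uniroot(function(l) pop_icc(l) - target, c(0, 1),
                 f.lower = f0 - target, f.upper = f1 - target,
                 tol = 1e-3)$root
}

# clamp practice-shifted raw scores to the measure's domain (a shift is a
# mean change; it cannot produce impossible raw values such as negative
# extra moves or non-positive completion times)
clamp_raw <- function(raw, info) {
  switch(info$transform,
    inverse = ,
    log10 = pmax(raw, .Machine$double.eps),
    sqrt = pmax(raw, 0),
    raw
  )
}

# is a transformed-scale value inside the image of the transform?
transform_image_ok <- function(value, info) {
  lower <- info$direction == "lower_is_better"
  switch(info$transform,
    inverse = value > 0,
    sqrt = if (lower) value <= 0 else value >= 0,
    rep(TRUE, length(value))
  )
}

#' Simulate two-occasion battery scores for a cohort
#'
#' For each measure, latent standardized scores are generated as the
#' demographic model prediction plus a stable person residual plus
#' independent occasion noise. The person/occasion split of the model's
#' residual variance is solved numerically so that the population
#' absolute-agreement ICC of the raw scores -- after MAD cleaning for
#' time-based measures, and including the systematic practice-shift
#' component -- equals the configured target. Raw scores are obtained by
#' de-standardizing and inverting the measure's transform (draws outside
#' the transform domain are rejected and redrawn); occasion-2 raw scores
#' are shifted by the configured practice effect. Finally extreme values
#' and zero scores are injected at the configured rates and recorded in
#' the ground truth.
#'
#' @param demo Demographics from [simulate_demographics()].
#' @param config An [simulation_config()].
#' @param .set_seed Internal; see [simulate_demographics()].
#' @return An `acs_cohort` list: `demographics`, `scores` (an
#'   `acs_scores` table), and `ground_truth` (person-level latent values,
#'   the injected-outlier and injected-zero registries, and the per-measure
#'   calibration record).
#' @export
simulate_scores <- function(demo, config = simulation_config(),
                            .set_seed = TRUE) {
  if (.set_seed && !is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(demo)
  grp <- age_groups(demo$age, config$mad_config)
  score_rows <- list()
  latent <- list()
  injected <- list()
  calib <- list()

  for (m in names(config$models)) {
    gm <- config$models[[m]]
    info <- as_measure_info(gm)
    spec_bat <- battery_row(config$battery, m)
    pred <- predicted_score(gm, demo)
    v <- gm$sd_residual^2
    shift <- unname(config$practice_shift[m])
    if (is.na(shift)) shift <- 0
    target <- unname(config$target_icc[m])
    if (is.na(target)) {
      stop("no target_icc configured for measure ", m)
    }
    lambda <- if (target == 1 && shift == 0) 1 else
      calibrate_split(pred, v, target, shift, gm, grp, config)

    u <- pred + sqrt(lambda * v) * stats::rnorm(n)
    sd_occ <- sqrt((1 - lambda) * v)
    raw_occ <- list()
    for (occ in 1:2) {
      e <- if (sd_occ > 0) stats::rnorm(n, 0, sd_occ) else numeric(n)
      tval <- (u + e) * gm$ref_sd_transformed + gm$ref_mean_transformed
      bad <- !transform_image_ok(tval, info)
      tries <- 0
      while (any(bad) && tries < 100) {
        e[bad] <- if (sd_occ > 0) stats::rnorm(sum(bad), 0, sd_occ) else 0
        tval[bad] <- (u[bad] + e[bad]) * gm$ref_sd_transformed +
          gm$ref_mean_transformed
        bad <- !transform_image_ok(tval, info)
        tries <- tries + 1
      }
      if (any(bad)) {
        # persons whose latent value itself sits outside the image: nudge
        # to the domain edge
        tval[bad] <- gm$ref_mean_transformed
      }
      raw <- inverse_transform(tval, info)
      if (occ == 2) raw <- clamp_raw(raw + shift, info)
      raw_occ[[occ]] <- raw
    }

    # outlier injection (time-based measures)
    if (isTRUE(spec_bat$time_based) && config$outlier_rate > 0) {
      cc <- config$mad_config$consistency_constant
      for (occ in 1:2) {
        hit <- which(stats::runif(n) < config$outlier_rate)
        for (i in hit) {
          sel <- which(as.integer(grp) == as.integer(grp)[i])
          med <- stats::median(raw_occ[[occ]][sel])
          madv <- stats::median(abs(raw_occ[[occ]][sel] - med))
          orig <- raw_occ[[occ]][i]
          s <- sign(orig - med)
          if (s == 0) s <- sample(c(-1, 1), 1)
          # place the artifact displacement scaled MADs from the group
          # median (displacement > mad_multiplier puts it beyond the
          # limits); fall back to the upper side when the domain forbids
          # a downward artifact
          val <- med + s * config$outlier_displacement * cc * madv
          if (spec_bat$transform %in% c("inverse", "log10") && val <= 0) {
            val <- med + config$outlier_displacement * cc * madv
          }
          raw_occ[[occ]][i] <- val
          injected[[length(injected) + 1L]] <- data.frame(
            participant_id = demo$participant_id[i], occasion = occ,
            measure = m, type = "outlier", original = orig, value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
    # zero-score injection (count measures with zero_is_invalid)
    if (isTRUE(spec_bat$zero_is_invalid) && config$zero_score_rate > 0) {
      for (occ in 1:2) {
        hit <- which(stats::runif(n) < config$zero_score_rate)
        for (i in hit) {
          injected[[length(injected) + 1L]] <- data.frame(
            participant_id = demo$participant_id[i], occasion = occ,
            measure = m, type = "zero", original = raw_occ[[occ]][i],
            value = 0, stringsAsFactors = FALSE)
          raw_occ[[occ]][i] <- 0
        }
      }
    }

    for (occ in 1:2) {
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        participant_id = demo$participant_id, occasion = occ, measure = m,
        raw_score = raw_occ[[occ]], stringsAsFactors = FALSE)
    }
    latent[[length(latent) + 1L]] <- data.frame(
      participant_id = demo$participant_id, measure = m,
      predicted = pred, person_value = u, stringsAsFactors = FALSE)
    calib[[length(calib) + 1L]] <- data.frame(
      measure = m, lambda = lambda,
      sigma_person = sqrt(lambda * v), sigma_occasion = sd_occ,
      target_icc = target, practice_shift = shift,
      stringsAsFactors = FALSE)
  }

  cohort <- list(
    demographics = demo,
    scores = score_table(do.call(rbind, score_rows)),
    ground_truth = list(
      latent = do.call(rbind, latent),
      injected = if (length(injected)) do.call(rbind, injected) else
        data.frame(participant_id = character(), occasion = integer(),
                   measure = character(), type = character(),
                   original = numeric(), value = numeric()),
      calibration = do.call(rbind, calib)),
    config = config)
  class(cohort) <- "acs_cohort"
  cohort
}

#' Simulate a complete two-occasion cohort
#'
#' Seeds once from `config$seed`, draws demographics, then scores; the
#' whole cohort is bit-identical across runs at a fixed seed.
#'
#' @param config An [simulation_config()].
#' @return An `acs_cohort`; see [simulate_scores()].
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_participants = 50, seed = 1))
#' cohort$scores
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  demo <- simulate_demographics(config, .set_seed = FALSE)
  simulate_scores(demo, config, .set_seed = FALSE)
}

#' @export
print.acs_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$demographics), "participants,",
      length(unique(x$scores$measure)), "measures x 2 occasions;",
      nrow(x$ground_truth$injected), "injected artifacts\n")
  invisible(x)
}
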
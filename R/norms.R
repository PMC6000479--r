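#' Configuration for demographic norm-model fitting
#'
#' @param predictors Candidate predictors, entered together and then
#'   pruned. Recognized names: `age`, `age_squared`, `gender`,
#'   `education`; anything else must exist as a numeric column of the
#'   demographics table (e.g. a computer-skills z-score named in
#'   `extra_covariates`).
#' @param alpha_prune Predictors with p above this are removed and the
#'   model refitted (default .05).
#' @param center_age Center age at the reference-sample mean before
#'   entering it (and its square), avoiding collinearity between the
#'   linear and quadratic terms (default `TRUE`).
#' @param extra_covariates Additional demographic columns to enter.
#' @param iterative If `TRUE`, backward elimination drops one predictor at
#'   a time (worst first); default is a single prune-and-refit pass.
#' @return An `acs_fit_config` list.
#' @export
fit_config <- function(predictors = c("age", "age_squared", "gender",
                                      "education"),
                       alpha_prune = 0.05, center_age = TRUE,
                       extra_covariates = character(), iterative = FALSE) {
  if (alpha_prune <= 0 || alpha_prune >= 1) stop("alpha_prune must be in (0,1)")
  structure(list(predictors = unique(c(predictors, extra_covariates)),
                 alpha_prune = alpha_prune, center_age = isTRUE(center_age),
                 iterative = isTRUE(iterative)),
            class = "acs_fit_config")
}

# build the regression design data.frame for the configured predictors
norm_design <- function(demo, config, age_center) {
  d <- data.frame(row.names = seq_len(nrow(demo)))
  for (p in config$predictors) {
    d[[p]] <- switch(p,
      age = demo$age - age_center,
      age_squared = (demo$age - age_center)^2,
      {
        if (is.null(demo[[p]])) {
          stop("demographics lack required predictor column '", p, "'")
        }
        as.numeric(demo[[p]])
      })
  }
  d
}

#' Fit a demographic norm model for one measure
#'
#' Ordinary least squares of the standardized (mean 0, SD 1) scores on the
#' demographic predictors, with age centered at the reference-sample mean.
#' Predictors with p above `alpha_prune` are removed and the model
#' refitted on the survivors; the final coefficients, residual SD, R
#' squared, and the measure's frozen transform/reference constants make up
#' the returned [norm_model()].
#'
#' @param z Standardized scores, one per participant (roughly mean 0,
#'   SD 1).
#' @param demo An `acs_demographics` table aligned with `z`.
#' @param spec The measure's specification (one-row battery subset or
#'   list with `name`, `direction`, `transform`).
#' @param ref_mean,ref_sd The transformed-scale reference constants that
#'   produced `z`, frozen into the model.
#' @param config An [fit_config()].
#' @param age_center Age-centering constant; defaults to the mean age of
#'   `demo` (the reference sample), frozen into the model.
#' @return list(`model` = `acs_norm_model`, `diagnostics` =
#'   `acs_fit_diagnostics`). Diagnostics carry per-predictor betas,
#'   standard errors, standardized betas, t and p values and VIFs, plus
#'   model-level R squared, residual SD, n, and advisory
#'   heteroscedasticity (Breusch-Pagan) and residual-normality
#'   (Shapiro-Wilk) flags; the advisory flags never block model export.
#' @export
fit_norm_model <- function(z, demo, spec, ref_mean = NA_real_,
                           ref_sd = NA_real_, config = fit_config(),
                           age_center = NULL) {
  info <- as_measure_info(spec)
  keep <- !is.na(z)
  z <- z[keep]
  demo <- demo[keep, , drop = FALSE]
  if (length(z) < 10 * length(config$predictors)) {
    stop("need at least 10 participants per candidate predictor (",
         length(config$predictors), " predictors, n = ", length(z), ")")
  }
  if (stats::sd(z) == 0) {
    stop("degenerate fit: z-scores for '", info$name, "' are constant")
  }
  if (is.null(age_center)) age_center <- mean(demo$age)
  if (!config$center_age) age_center <- 0
  X <- norm_design(demo, config, age_center)
  dat <- cbind(zscore = z, X)

  fit <- stats::lm(zscore ~ ., data = dat)
  active <- config$predictors
  repeat {
    p <- summary(fit)$coefficients[-1, 4, drop = TRUE]
    drop_set <- names(p)[p > config$alpha_prune]
    if (!length(drop_set) || !length(setdiff(active, drop_set))) {
      # stop when nothing to prune, or when pruning would empty the model
      if (length(drop_set) && length(setdiff(active, drop_set)) == 0) {
        active <- character()
        fit <- stats::lm(zscore ~ 1, data = dat)
      }
      break
    }
    if (config$iterative) drop_set <- names(which.max(p))
    active <- setdiff(active, drop_set)
    fit <- stats::lm(stats::reformulate(active, response = "zscore"),
                     data = dat)
    if (!config$iterative) break
  }

  smry <- summary(fit)
  coefs <- stats::coef(fit)
  vifs <- if (length(active) >= 2) car::vif(fit) else
    stats::setNames(rep(1, length(active)), active)
  if (any(vifs > 10)) {
    stop("variance inflation factor > 10 for: ",
         paste(names(vifs)[vifs > 10], collapse = ", "))
  }
  ct <- smry$coefficients
  std_beta <- if (length(active)) {
    vapply(active, function(p) {
      coefs[[p]] * stats::sd(dat[[p]]) / stats::sd(dat$zscore)
    }, numeric(1))
  } else numeric()
  resid_norm_p <- {
    r <- stats::residuals(fit)
    if (length(r) > 5000) r <- r[round(seq(1, length(r), length.out = 5000))]
    stats::shapiro.test(r)$p.value
  }
  bp_p <- if (length(active)) lmtest::bptest(fit)$p.value else NA_real_

  diagnostics <- structure(list(
    predictors = data.frame(
      predictor = active,
      beta = unname(coefs[active]),
      se_beta = unname(ct[active, 2]),
      standardized_beta = unname(std_beta),
      t = unname(ct[active, 3]),
      p = unname(ct[active, 4]),
      vif = unname(vifs[active]),
      stringsAsFactors = FALSE),
    r_squared = smry$r.squared,
    sd_residual = smry$sigma,
    n = length(z),
    heteroscedasticity_suspect = !is.na(bp_p) && bp_p < 0.05,
    nonnormal_residuals_suspect = resid_norm_p < 0.05,
    pruned = setdiff(config$predictors, active)
  ), class = "acs_fit_diagnostics")

  coef_list <- c(list(constant = unname(coefs[["(Intercept)"]])),
                 as.list(coefs[active]))
  model <- norm_model(
    measure = info$name, direction = info$direction,
    transform = info$transform,
    ref_mean_transformed = ref_mean, ref_sd_transformed = ref_sd,
    age_center = age_center, coefficients = coef_list,
    sd_residual = smry$sigma, r_squared = smry$r.squared,
    n_reference = length(z))
  list(model = model, diagnostics = diagnostics)
}

#' Fit norm models for every battery measure
#'
#' The batch pipeline: freeze occasion-1 reference constants from the
#' cleaned scores, standardize, fit one norm model per measure, and fit
#' the derived total score on the re-standardized composite.
#'
#' @param scores A cleaned `acs_scores` table (occasion 1 is used).
#' @param demo An `acs_demographics` table.
#' @param battery An `acs_battery`.
#' @param config An [fit_config()].
#' @param age_center Age-centering constant (default: mean reference age).
#' @return list(`models` = named list of `acs_norm_model`,
#'   `diagnostics` = named list of `acs_fit_diagnostics`,
#'   `reference` = the frozen reference-constants table).
#' @export
fit_norm_models <- function(scores, demo, battery, config = fit_config(),
                            age_center = NULL) {
  scores <- score_table(scores)
  battery <- as_battery(battery)
  if (is.null(age_center)) age_center <- mean(demo$age)
  ref <- reference_constants(scores, battery)
  z <- standardize_scores(scores, battery, ref)

  # derived total score: composite of z-scores, re-standardized
  total_name <- if (any(battery$derived)) battery$name[battery$derived][1]
    else NULL
  zdat <- as.data.frame(z)[z$occasion == 1L & !z$excluded,
                           c("participant_id", "measure", "z")]
  if (!is.null(total_name)) {
    comp <- composite_table(z[z$occasion == 1L, ], battery, name = total_name)
    if (nrow(comp)) {
      ref <- rbind(ref, data.frame(measure = total_name,
                                   ref_mean = mean(comp$raw_score),
                                   ref_sd = stats::sd(comp$raw_score),
                                   n = nrow(comp)))
      zdat <- rbind(zdat, data.frame(
        participant_id = comp$participant_id, measure = total_name,
        z = standardize(comp$raw_score,
                        ref$ref_mean[ref$measure == total_name],
                        ref$ref_sd[ref$measure == total_name])))
    }
  }

  models <- list()
  diags <- list()
  for (m in intersect(battery$name, unique(zdat$measure))) {
    sub <- zdat[zdat$measure == m, ]
    di <- match(sub$participant_id, demo$participant_id)
    if (anyNA(di)) {
      stop("participants without demographics for measure ", m)
    }
    spec <- battery_row(battery, m)
    r <- ref[ref$measure == m, ]
    fitted <- fit_norm_model(sub$z, demo[di, , drop = FALSE], spec,
                             ref_mean = r$ref_mean, ref_sd = r$ref_sd,
                             config = config, age_center = age_center)
    models[[m]] <- fitted$model
    diags[[m]] <- fitted$diagnostics
  }
  list(models = models, diagnostics = diags, reference = ref)
}

#' Demographically predicted standardized score
#'
#' Evaluates the norm model's regression equation for given demographics:
#' `constant + beta_age (age - age_center) + beta_age2 (age - age_center)^2
#' + beta_gender gender + beta_education education (+ covariates)`.
#' Pruned (absent) coefficients contribute nothing.
#'
#' @param model An `acs_norm_model`.
#' @param demo An `acs_demographics` table (or any data.frame with the
#'   needed columns); one prediction per row.
#' @return Numeric vector of predicted z-scores.
#' @examples
#' m <- acs_norm_models()$ConnectTheDotsI
#' predicted_score(m, data.frame(age = 55, gender = 0))  # about -0.39
#' @export
predicted_score <- function(model, demo) {
  cf <- model$coefficients
  out <- rep(cf$constant, nrow(demo))
  for (nm in setdiff(names(cf), "constant")) {
    x <- switch(nm,
      age = demo$age - model$age_center,
      age_squared = (demo$age - model$age_center)^2,
      demo[[nm]])
    if (is.null(x) || (nm %in% c("age", "age_squared") && is.null(demo$age))) {
      stop("demographics lack field '",
           if (nm == "age_squared") "age" else nm,
           "' required by the ", model$measure, " model")
    }
    if (anyNA(x)) {
      stop("missing values in demographic field '",
           if (nm == "age_squared") "age" else nm,
           "' required by the ", model$measure, " model")
    }
    out <- out + cf[[nm]] * as.numeric(x)
  }
  out
}

#' Demographically corrected norm score
#'
#' Converts a raw test score into a norm score: the raw score is
#' transformed and standardized with the model's frozen reference
#' constants (`z_actual`), the demographic expectation is computed
#' (`z_predicted`), and their difference is scaled by the model's residual
#' SD. Performance below the demographic expectation yields a negative
#' norm score.
#'
#' @param model An `acs_norm_model` with available reference constants.
#' @param raw_score Raw score(s) on the measure's original scale.
#' @param demo Demographics (one row, or one per raw score).
#' @return data.frame with `z_actual`, `z_predicted`, `norm`.
#' @examples
#' m <- acs_norm_models()$ConnectTheDotsI
#' norm_score(m, 60, data.frame(age = 55, gender = 0))  # norm about -1.63
#' @export
norm_score <- function(model, raw_score, demo) {
  if (is.na(model$ref_mean_transformed) || is.na(model$ref_sd_transformed)) {
    stop("model for ", model$measure, " has no reference constants; ",
         "fit one from reference data to compute norm scores")
  }
  z_actual <- standardize(transform_raw(raw_score, model),
                          model$ref_mean_transformed,
                          model$ref_sd_transformed)
  z_pred <- predicted_score(model, demo)
  data.frame(z_actual = z_actual, z_predicted = z_pred,
             norm = (z_actual - z_pred) / model$sd_residual)
}

#' Score a full battery for one individual
#'
#' Computes per-measure norm scores for every supplied raw score that has
#' a model, plus the composite norm when all composite components and a
#' total-score model (with reference constants) are available. Measures
#' without a model are reported with a warning and skipped; the rest are
#' still scored.
#'
#' @param models Named list of `acs_norm_model`s (e.g. from
#'   [fit_norm_models()]).
#' @param raw_scores Named numeric vector, names = measure names.
#' @param demo One-row demographics.
#' @param battery An `acs_battery` (defines the composite membership).
#' @return data.frame with one row per scored measure (and one for the
#'   total): `measure`, `raw_score`, `z_actual`, `z_predicted`, `norm`.
#' @export
score_battery <- function(models, raw_scores, demo,
                          battery = default_acs_battery()) {
  battery <- as_battery(battery)
  if (nrow(demo) != 1) stop("score_battery expects one individual")
  missing_models <- setdiff(names(raw_scores), names(models))
  if (length(missing_models)) {
    warning("no norm model for: ", paste(missing_models, collapse = ", "))
  }
  rows <- list()
  z_by_measure <- c()
  for (m in intersect(names(raw_scores), names(models))) {
    ns <- norm_score(models[[m]], raw_scores[[m]], demo)
    rows[[m]] <- cbind(data.frame(measure = m, raw_score = raw_scores[[m]],
                                  stringsAsFactors = FALSE), ns)
    z_by_measure[m] <- ns$z_actual
  }
  total_name <- if (any(battery$derived)) battery$name[battery$derived][1]
    else "TotalScore"
  comp <- composite_score(z_by_measure, battery)
  if (!is.na(comp) && total_name %in% names(models) &&
      !is.na(models[[total_name]]$ref_mean_transformed)) {
    ns <- norm_score(models[[total_name]], comp, demo)
    rows[[total_name]] <- cbind(
      data.frame(measure = total_name, raw_score = comp,
                 stringsAsFactors = FALSE), ns)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
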